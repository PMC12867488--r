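# Small, fast phantom used throughout the unit tests (~0.9M voxels).
tiny_spec <- function(seed = 1, noise_sigma = 0.1, vessel_count = 5,
                      lesion_contrast = 2, vessel_contrast = 3,
                      shrink_factors = c(1, 1, 1),
                      lesion_semiaxes_um = c(150, 140, 130),
                      lesion_center_um = c(0, 190, 0),
                      spacing_um = c(10, 10, 10),
                      brain_semiaxes_um = c(400, 520, 360)) {
  grid_shape <- ceiling(2 * (brain_semiaxes_um + 50) / spacing_um) + 1
  phantom_spec(grid_shape = grid_shape, spacing_um = spacing_um,
               brain_semiaxes_um = brain_semiaxes_um,
               lesion_center_um = lesion_center_um,
               lesion_semiaxes_um = lesion_semiaxes_um,
               lesion_contrast = lesion_contrast, vessel_count = vessel_count,
               vessel_diameter_um = 10, vessel_contrast = vessel_contrast,
               noise_sigma = noise_sigma, shrink_factors = shrink_factors,
               seed = seed)
}

# Threshold rule for a phantom: 99th percentile of the mirrored
# contralateral box, mapped to voxel indices of `grid` (default: its lsfm).
phantom_rule <- function(set, grid = set$lsfm, percentile = 99,
                         halfsize_um = c(150, 150, 150), perm = 1:3) {
  roi <- contralateral_roi(set, halfsize_um)
  threshold_rule(percentile,
                 roi_box_from_um(grid, roi$lo_um[perm], roi$hi_um[perm]))
}
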