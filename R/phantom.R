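#' Specification of a synthetic cleared-brain phantom
#'
#' Describes a deterministic synthetic ground truth: an ellipsoidal "brain"
#' of uniform background autofluorescence, a brighter contiguous ellipsoidal
#' lesion (the infarct core is brighter than healthy tissue), a set of bright
#' thin tubular vessels as distractors, additive Gaussian noise, and
#' per-dimension clearing shrinkage. Geometry fields describe the
#' pre-clearing brain; the generated volume is the post-clearing brain, i.e.
#' every length is multiplied by `shrink_factors` before voxelisation.
#'
#' @param grid_shape integer length-3, voxels along `(z, y, x)`.
#' @param spacing_um voxel spacing, micrometres along `(z, y, x)`.
#' @param brain_semiaxes_um pre-clearing brain ellipsoid semiaxes (um).
#' @param lesion_center_um pre-clearing lesion centre, um relative to the
#'   brain centre.
#' @param lesion_semiaxes_um pre-clearing lesion ellipsoid semiaxes (um).
#' @param lesion_contrast lesion mean intensity over background mean; must
#'   exceed 1 (the infarct is brighter than healthy tissue).
#' @param vessel_count number of straight tubular vessels (>= 0).
#' @param vessel_diameter_um vessel diameter (um).
#' @param vessel_contrast vessel mean over background mean; must exceed 1.
#' @param noise_sigma additive Gaussian noise SD as a fraction of the
#'   background mean.
#' @param shrink_factors post-clearing linear scale per axis, each in (0, 1].
#' @param seed integer RNG seed; identical specs give bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @seealso [default_phantom_spec()], [make_phantom()]
#' @export
phantom_spec <- function(grid_shape, spacing_um, brain_semiaxes_um,
                         lesion_center_um, lesion_semiaxes_um,
                         lesion_contrast = 2, vessel_count = 12,
                         vessel_diameter_um = 10, vessel_contrast = 3,
                         noise_sigma = 0.1, shrink_factors = c(1, 1, 1),
                         seed = 1) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  spacing_um <- check_spacing(spacing_um)
  stopifnot(length(brain_semiaxes_um) == 3, all(brain_semiaxes_um > 0),
            length(lesion_semiaxes_um) == 3, all(lesion_semiaxes_um > 0),
            length(lesion_center_um) == 3,
            lesion_contrast > 1, vessel_contrast > 1,
            vessel_count >= 0, vessel_diameter_um > 0, noise_sigma >= 0,
            length(shrink_factors) == 3,
            all(shrink_factors > 0), all(shrink_factors <= 1))
  spec <- structure(
    list(grid_shape = grid_shape, spacing_um = spacing_um,
         brain_semiaxes_um = as.numeric(brain_semiaxes_um),
         lesion_center_um = as.numeric(lesion_center_um),
         lesion_semiaxes_um = as.numeric(lesion_semiaxes_um),
         lesion_contrast = lesion_contrast, vessel_count = as.integer(vessel_count),
         vessel_diameter_um = vessel_diameter_um, vessel_contrast = vessel_contrast,
         noise_sigma = noise_sigma, shrink_factors = as.numeric(shrink_factors),
         seed = as.integer(seed)),
    class = "phantom_spec")
  if (!lesion_inside_brain(spec)) stop("lesion ellipsoid must lie inside the brain ellipsoid")
  spec
}

# Sampled containment check on the lesion surface (scaling by shrink_factors
# maps both ellipsoids identically, so pre-clearing geometry suffices).
lesion_inside_brain <- function(spec, n = 500) {
  i <- seq_len(n)
  phi <- acos(1 - 2 * (i - 0.5) / n)
  theta <- pi * (1 + sqrt(5)) * i
  u <- rbind(cos(phi), sin(phi) * sin(theta), sin(phi) * cos(theta))
  p <- spec$lesion_center_um + spec$lesion_semiaxes_um * u
  all(colSums((p / spec$brain_semiaxes_um)^2) <= 1 + 1e-9)
}

#' Phantom specification targeting a post-clearing lesion volume
#'
#' Builds a [phantom_spec] whose post-clearing (generated) lesion has the
#' requested analytic volume. The lesion is a mildly oblate ellipsoid
#' (semiaxis ratio 1 : 0.8 : 0.8) placed in the +y "hemisphere", leaving the
#' -y hemisphere free for the contralateral reference region; the brain
#' ellipsoid and the voxel grid are sized around it. Defaults emulate the
#' study conditions: 10 um isotropic voxels (a light-sheet axial step with
#' in-plane pitch binned to match), a 2x lesion-to-background contrast,
#' thin 10 um bright vessels, 10% additive noise, and anisotropic clearing
#' shrinkage of 15-25% per dimension.
#'
#' @param truth_volume_mm3 target post-clearing analytic lesion volume (mm^3).
#' @param seed RNG seed.
#' @param spacing_um voxel spacing (um), default 10 um isotropic.
#' @inheritParams phantom_spec
#' @return A [phantom_spec].
#' @export
default_phantom_spec <- function(truth_volume_mm3 = 0.4, seed = 1,
                                 spacing_um = c(10, 10, 10),
                                 lesion_contrast = 2, noise_sigma = 0.1,
                                 vessel_count = 12, vessel_diameter_um = 10,
                                 vessel_contrast = 3,
                                 shrink_factors = c(0.85, 0.80, 0.75)) {
  stopifnot(truth_volume_mm3 > 0)
  # post-clearing lesion semiaxes (s, 0.8 s, 0.8 s) with 4/3 pi a b c = V
  s <- (truth_volume_mm3 * 1e9 / (4 / 3 * pi * 0.64))^(1 / 3)
  les_post <- c(s, 0.8 * s, 0.8 * s)
  brain_post <- c(1.35 * les_post[1] + 150,
                  2.20 * les_post[2] + 250,
                  1.35 * les_post[3] + 150)
  center_post <- c(0, brain_post[2] - les_post[2] - 120, 0)
  pad <- 60
  grid_shape <- ceiling(2 * (brain_post + pad) / spacing_um) + 1
  phantom_spec(grid_shape = grid_shape, spacing_um = spacing_um,
               brain_semiaxes_um = brain_post / shrink_factors,
               lesion_center_um = center_post / shrink_factors,
               lesion_semiaxes_um = les_post / shrink_factors,
               lesion_contrast = lesion_contrast, vessel_count = vessel_count,
               vessel_diameter_um = vessel_diameter_um,
               vessel_contrast = vessel_contrast, noise_sigma = noise_sigma,
               shrink_factors = shrink_factors, seed = seed)
}

#' Generate a synthetic cleared-brain phantom
#'
#' Voxelises the post-clearing geometry of `spec` onto the grid and paints
#' intensities: background mean `b` (100 arbitrary units) inside the brain,
#' ~0 outside, `b * lesion_contrast` inside the lesion, `b * vessel_contrast`
#' along randomly placed straight tubes of the stated diameter (restricted to
#' brain tissue outside the lesion and a thin 25 um perilesional halo, so
#' the ground-truth lesion and vessel labels are disjoint and vessel
#' exclusion can be assessed unambiguously), plus additive Gaussian noise of
#' SD `noise_sigma * b`
#' everywhere. The RNG state of the caller is untouched; the same spec always
#' yields a bit-identical phantom.
#'
#' @param spec a [phantom_spec].
#' @return An object of class `phantom_set` with fields `lsfm` ([voxel_grid]),
#'   `truth_mask` and `vessel_mask` ([mask_grid]), `truth_volume_mm3` (voxel
#'   count times voxel volume), `truth_analytic_mm3` and
#'   `preshrink_analytic_mm3` (analytic ellipsoid volumes after/before
#'   shrinkage), `background` (the background mean), and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  sp <- spec$spacing_um
  origin <- -(dims - 1) / 2 * sp
  sk <- spec$shrink_factors
  brain_ax <- spec$brain_semiaxes_um * sk
  les_ax <- spec$lesion_semiaxes_um * sk
  les_c <- spec$lesion_center_um * sk

  brain <- ellipsoid_mask(dims, sp, origin, c(0, 0, 0), brain_ax)
  lesion <- ellipsoid_mask(dims, sp, origin, les_c, les_ax)
  if (any(lesion & !brain)) stop("voxelised lesion extends outside the brain")

  b <- 100
  img <- array(0, dim = dims)
  img[brain] <- b
  img[lesion] <- b * spec$lesion_contrast

  vessels <- array(FALSE, dim = dims)
  with_seed(spec$seed, {
    if (spec$vessel_count > 0) {
      k <- spec$vessel_count
      # random anchor inside the brain, isotropic random direction
      u <- matrix(rnorm(3 * k), 3)
      u <- sweep(u, 2, sqrt(colSums(u^2)), "/")
      r <- runif(k)^(1 / 3)
      anchor <- brain_ax * u * rep(r, each = 3)
      d <- matrix(rnorm(3 * k), 3)
      d <- sweep(d, 2, sqrt(colSums(d^2)), "/")
      # vessels spare the lesion and a thin perilesional halo so the truth
      # labels are disjoint and size-based exclusion can be assessed cleanly
      halo <- if (any(lesion)) ball_morph(lesion, sp, 25, FALSE) else lesion
      dom <- brain & !halo
      vessels <- array(
        .tube_mask3d(dims, sp, origin, anchor, d, spec$vessel_diameter_um / 2,
                     as.vector(dom)),
        dim = dims)
      img[vessels] <- b * spec$vessel_contrast
    }
    if (spec$noise_sigma > 0)
      img <- img + array(rnorm(length(img), 0, spec$noise_sigma * b), dim = dims)
  })

  voxvol <- prod(sp)
  structure(
    list(lsfm = voxel_grid(img, sp, origin_label = "dorsal", origin_um = origin),
         truth_mask = mask_grid(lesion, sp, origin_um = origin),
         vessel_mask = mask_grid(vessels, sp, origin_um = origin),
         truth_volume_mm3 = sum(lesion) * voxvol / 1e9,
         truth_analytic_mm3 = 4 / 3 * pi * prod(les_ax) / 1e9,
         preshrink_analytic_mm3 = 4 / 3 * pi * prod(spec$lesion_semiaxes_um) / 1e9,
         background = b, spec = spec),
    class = "phantom_set")
}

#' @export
print.phantom_set <- function(x, ...) {
  cat(sprintf("<phantom_set> grid %s, truth volume %.4f mm^3 (%d voxels), %d vessels\n",
              paste(dim(x$lsfm$data), collapse = " x "), x$truth_volume_mm3,
              sum(x$truth_mask$data), x$spec$vessel_count))
  invisible(x)
}

#' Contralateral reference region of a phantom
#'
#' The healthy-tissue reference for percentile thresholding: an axis-aligned
#' box mirrored from the lesion centre into the opposite (-y) hemisphere,
#' well inside the brain. Returned as a physical box in micrometres so it can
#' be mapped onto any resampled orientation of the same phantom with
#' [roi_box_from_um()].
#'
#' @param set a `phantom_set` (from [make_phantom()]).
#' @param halfsize_um box half-width per axis (um).
#' @return list with `lo_um` and `hi_um`, each length-3 `(z, y, x)`.
#' @export
contralateral_roi <- function(set, halfsize_um = c(200, 200, 200)) {
  stopifnot(inherits(set, "phantom_set"))
  lc <- set$spec$lesion_center_um * set$spec$shrink_factors
  ctr <- c(0, -abs(lc[2]), 0)  # mirrored across the midline, on-axis in z/x
  list(lo_um = ctr - halfsize_um, hi_um = ctr + halfsize_um)
}

#' Derive an MRI-like coarse hyperintense stack from a phantom
#'
#' Emulates T2-weighted imaging of the lesion: the hyperintense region is the
#' ground-truth lesion dilated by an edema halo of thickness
#' `edema_dilation_um` (vasogenic/cytotoxic edema makes early MRI overestimate
#' the infarct), then collapsed into coarse coronal slices of the given
#' thickness. Per-slice hyperintense areas use the partial-volume fraction
#' within each slab, so summing area x thickness reproduces the dilated
#' volume up to the slab discretisation at the lesion poles.
#'
#' @param set a `phantom_set` (from [make_phantom()]).
#' @param slice_thickness_mm slice thickness (mm); must be at least the
#'   source axial spacing.
#' @param edema_dilation_um edema halo thickness (um); 0 disables dilation.
#' @return list with `stack` (a coarse [voxel_grid], lesion+halo bright) and
#'   `slices` (a [slice_series] of hyperintense areas at that thickness).
#' @export
derive_mri <- function(set, slice_thickness_mm = 0.2, edema_dilation_um = 0) {
  stopifnot(inherits(set, "phantom_set"), edema_dilation_um >= 0)
  sp <- set$truth_mask$spacing_um
  t_um <- slice_thickness_mm * 1000
  if (!is.finite(t_um) || t_um <= 0) stop("slice thickness must be > 0")
  if (t_um < sp[1] - 1e-9)
    stop("slice thickness must be at least the source axial spacing")
  hyper <- set$truth_mask$data
  if (edema_dilation_um > 0 && any(hyper))
    hyper <- ball_morph(hyper, sp, edema_dilation_um, FALSE)
  dims <- dim(hyper)
  slab <- pmin(floor((seq_len(dims[1]) - 1) * sp[1] / t_um), 1e9)
  slab_ids <- sort(unique(slab))
  pix_mm2 <- sp[2] * sp[3] / 1e6
  nsl <- length(slab_ids)
  frac <- array(0, dim = c(nsl, dims[2], dims[3]))
  brain <- set$lsfm$data > set$background / 2  # noisy but adequate backdrop
  bfrac <- array(0, dim = c(nsl, dims[2], dims[3]))
  areas <- numeric(nsl)
  for (i in seq_len(nsl)) {
    pl <- which(slab == slab_ids[i])
    hp <- hyper[pl, , , drop = FALSE]
    frac[i, , ] <- colMeans(array(hp, c(length(pl), dims[2] * dims[3])))
    bfrac[i, , ] <- colMeans(array(brain[pl, , , drop = FALSE],
                                   c(length(pl), dims[2] * dims[3])))
    areas[i] <- sum(hp) / length(pl) * pix_mm2
  }
  stack <- voxel_grid(0.3 * bfrac + frac, c(t_um, sp[2], sp[3]),
                      origin_label = "mri")
  list(stack = stack, slices = slice_series(areas, slice_thickness_mm))
}

#' Derive a histology-like sparse slice series from a phantom
#'
#' Emulates serial cresyl-violet sectioning with sparse sampling: thin
#' physical sections are taken but only every `interval_mm` is measured, and
#' the slice-sum estimator multiplies areas by the inter-section interval.
#' The per-section area is the true lesion cross-section at the sampled
#' plane. A lesion thinner than the interval that falls between sampled
#' planes yields all-zero areas -- the documented undersampling failure mode
#' of sparse sectioning.
#'
#' @param set a `phantom_set` (from [make_phantom()]).
#' @param thickness_mm physical section thickness (mm); recorded for
#'   reference, must not exceed the interval.
#' @param interval_mm inter-section sampling interval (mm); the volume
#'   multiplier.
#' @param offset_mm position of the first sampled plane (mm from the first
#'   acquired plane).
#' @return A [slice_series] whose `thickness_mm` is `interval_mm`.
#' @export
derive_histology <- function(set, thickness_mm = 0.05, interval_mm = 0.2,
                             offset_mm = 0) {
  stopifnot(inherits(set, "phantom_set"))
  if (!is.finite(interval_mm) || interval_mm <= 0) stop("interval must be > 0")
  if (thickness_mm > interval_mm + 1e-12) stop("interval must be >= section thickness")
  sp <- set$truth_mask$spacing_um
  dims <- dim(set$truth_mask$data)
  extent_um <- (dims[1] - 1) * sp[1]
  pos <- seq(offset_mm * 1000, extent_um, by = interval_mm * 1000)
  idx <- round(pos / sp[1]) + 1
  idx <- idx[idx >= 1 & idx <= dims[1]]
  if (!length(idx)) stop("no sections fall inside the volume")
  pix_mm2 <- sp[2] * sp[3] / 1e6
  areas <- vapply(idx, function(i) sum(set$truth_mask$data[i, , ]) * pix_mm2,
                  numeric(1))
  slice_series(areas, interval_mm)
}

#' Derive baseline and post-stroke speckle stacks from a phantom
#'
#' Simulates laser speckle frames as ensemble-averaged fully developed
#' speckle: each pixel intensity is the average of `M` independent
#' exponentially distributed speckle realisations, i.e. Gamma(M, mean b),
#' whose contrast (SD/mean) is exactly `1/sqrt(M)`. The baseline stack uses
#' `M = 1/base_contrast^2` everywhere; in the post-stroke stack, pixels
#' inside the hypoperfused region use `M / contrast_ratio^2`, raising their
#' contrast by the factor `contrast_ratio` (stagnant flow blurs speckle
#' less). `base_contrast = 1` gives raw unfiltered exponential speckle.
#'
#' @param set a `phantom_set` (from [make_phantom()]).
#' @param n_frames frames per stack (>= 1).
#' @param stroke_area_px logical `(y, x)` matrix marking the hypoperfused
#'   region on the speckle frame grid, or `NULL` to use the lesion's dorsal
#'   footprint projected onto that grid.
#' @param contrast_ratio post/baseline speckle-contrast ratio inside the
#'   stroke region; must be >= 1.
#' @param frame_shape frame size `(y, x)` in pixels.
#' @param pixel_pitch_um speckle pixel pitch; `NULL` scales the field of view
#'   to cover the phantom in y/x.
#' @param base_contrast perfused-tissue speckle contrast (SD/mean).
#' @param frame_rate_hz nominal frame rate carried as metadata.
#' @return list with `baseline` and `post` ([speckle_stack]s) and
#'   `stroke_area_px` (the region mask actually used).
#' @export
derive_speckle <- function(set, n_frames = 100, stroke_area_px = NULL,
                           contrast_ratio = 1.5, frame_shape = c(128, 128),
                           pixel_pitch_um = NULL, base_contrast = 0.2,
                           frame_rate_hz = 10) {
  stopifnot(inherits(set, "phantom_set"), n_frames >= 1, contrast_ratio >= 1,
            base_contrast > 0, base_contrast <= 1)
  dims <- dim(set$truth_mask$data)
  sp <- set$truth_mask$spacing_um
  if (is.null(pixel_pitch_um))
    pixel_pitch_um <- max(dims[2] * sp[2] / frame_shape[1],
                          dims[3] * sp[3] / frame_shape[2])
  if (is.null(stroke_area_px)) {
    foot <- apply(set$truth_mask$data, c(2, 3), any)
    yi <- pmin(pmax(round((seq_len(frame_shape[1]) - 0.5) * pixel_pitch_um / sp[2]), 1), dims[2])
    xi <- pmin(pmax(round((seq_len(frame_shape[2]) - 0.5) * pixel_pitch_um / sp[3]), 1), dims[3])
    stroke_area_px <- foot[yi, xi, drop = FALSE]
  }
  stopifnot(is.logical(stroke_area_px), all(dim(stroke_area_px) == frame_shape))
  b <- set$background
  m_base <- 1 / base_contrast^2
  m_post <- m_base / contrast_ratio^2
  npx <- prod(frame_shape)
  inside <- as.vector(stroke_area_px)
  gen <- function(shape_map) {
    fr <- array(0, dim = c(n_frames, frame_shape))
    for (t in seq_len(n_frames)) {
      v <- numeric(npx)
      v[!inside] <- rgamma(sum(!inside), shape = shape_map[1], rate = shape_map[1] / b)
      if (any(inside))
        v[inside] <- rgamma(sum(inside), shape = shape_map[2], rate = shape_map[2] / b)
      fr[t, , ] <- v
    }
    fr
  }
  with_seed(set$spec$seed + 1000003L, {
    baseline <- gen(c(m_base, m_base))
    post <- gen(c(m_base, m_post))
  })
  list(baseline = speckle_stack(baseline, pixel_pitch_um, frame_rate_hz),
       post = speckle_stack(post, pixel_pitch_um, frame_rate_hz),
       stroke_area_px = stroke_area_px)
}
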