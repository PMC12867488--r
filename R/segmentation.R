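#' Axis-aligned region of interest in voxel indices
#'
#' Half-open 0-based index ranges per axis, matching how ROIs are passed on
#' a command line; axis `a` covers voxels `lo[a] .. hi[a]-1`.
#'
#' @param lo,hi integer length-3, `(z, y, x)`, `lo < hi` per axis.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(length(lo) == 3, length(hi) == 3, all(lo >= 0), all(lo < hi))
  structure(list(lo = lo, hi = hi), class = "roi_box")
}

#' Convert a physical box (micrometres) to a voxel-index ROI
#'
#' Selects the voxels whose centres fall inside the physical box, using the
#' grid's origin and spacing; this is how one ROI definition follows a
#' phantom through resampled orientations.
#'
#' @param grid a [voxel_grid].
#' @param lo_um,hi_um physical box corners, um along `(z, y, x)`.
#' @return A [roi_box], clamped to the grid.
#' @export
roi_box_from_um <- function(grid, lo_um, hi_um) {
  stopifnot(inherits(grid, "voxel_grid"))
  dims <- dim(grid$data)
  lo <- ceiling((lo_um - grid$origin_um) / grid$spacing_um - 1e-9)
  hi <- floor((hi_um - grid$origin_um) / grid$spacing_um + 1e-9) + 1
  lo <- pmax(lo, 0); hi <- pmin(hi, dims)
  if (any(lo >= hi)) stop("physical box contains no voxel centres")
  roi_box(lo, hi)
}

roi_values <- function(volume, roi) {
  dims <- dim(volume$data)
  if (any(roi$hi > dims)) stop("ROI exceeds volume bounds")
  volume$data[(roi$lo[1] + 1):roi$hi[1],
              (roi$lo[2] + 1):roi$hi[2],
              (roi$lo[3] + 1):roi$hi[3]]
}

#' Percentile thresholding rule
#'
#' A global threshold defined as an a-priori percentile of the intensity
#' histogram of a contralateral (healthy) cortical region. Fixing the
#' percentile per cohort, rather than eyeballing a threshold per sample, is
#' what makes the workflow operator-independent.
#'
#' @param percentile percentile in `(0, 100]`.
#' @param roi a [roi_box] placed over contralateral healthy tissue.
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(percentile, roi) {
  stopifnot(is.numeric(percentile), length(percentile) == 1,
            percentile > 0, percentile <= 100, inherits(roi, "roi_box"))
  structure(list(percentile = percentile, roi = roi), class = "threshold_rule")
}

#' Nearest-rank percentile of a sample
#'
#' The value at rank `ceiling(p/100 * n)` of the sorted sample: no
#' interpolation, so the result is always an observed intensity and is
#' reproducible across implementations. `p = 100` returns the maximum.
#'
#' @param x numeric vector.
#' @param p percentile in `(0, 100]`.
#' @return The nearest-rank percentile value.
#' @export
nearest_rank_percentile <- function(x, p) {
  stopifnot(length(x) >= 1, p > 0, p <= 100)
  sort(x)[ceiling(p / 100 * length(x))]
}

#' Threshold from a contralateral region
#'
#' Extracts the intensity multiset of the ROI and returns its nearest-rank
#' percentile, the global threshold for segmentation.
#'
#' @param volume a [voxel_grid].
#' @param rule a [threshold_rule].
#' @return The threshold intensity (scalar).
#' @export
contralateral_threshold <- function(volume, rule) {
  stopifnot(inherits(volume, "voxel_grid"), inherits(rule, "threshold_rule"))
  v <- roi_values(volume, rule$roi)
  if (!length(v)) stop("empty ROI")
  if (length(v) < 100)
    warning(sprintf("contralateral ROI has only %d voxels; percentile is unstable", length(v)))
  nearest_rank_percentile(as.vector(v), rule$percentile)
}

# Erosion/dilation by the discrete anisotropic Euclidean ball of physical
# radius radius_um, computed through a separable squared distance transform
# (O(n) regardless of radius). The volume border counts as background.
ball_morph <- function(mask, spacing_um, radius_um, erode) {
  dims <- dim(mask)
  if (radius_um < min(spacing_um)) return(mask)  # ball is a single voxel
  array(.ball_morph3d(as.vector(mask), dims, spacing_um, radius_um, erode),
        dim = dims)
}

#' Binarize a volume and exclude fine vascular structures
#'
#' Voxels at or above the threshold become foreground; a morphological
#' opening with a physical ball of diameter `detail_size_um` (anisotropic
#' voxel radii derived from the spacing) then removes structures thinner
#' than that feature size. Setting the feature size above the width of
#' individual vessels excludes the bright fine vasculature while leaving the
#' much larger infarct core intact; `detail_size_um = 0` skips the opening.
#'
#' @param volume a [voxel_grid].
#' @param threshold global intensity threshold.
#' @param detail_size_um opening diameter in micrometres (>= 0).
#' @return A [mask_grid]; empty masks are valid results.
#' @export
binarize_and_exclude_vessels <- function(volume, threshold, detail_size_um = 30) {
  stopifnot(inherits(volume, "voxel_grid"), detail_size_um >= 0)
  fg <- volume$data >= threshold
  if (detail_size_um > 0 && any(fg)) {
    r <- detail_size_um / 2
    fg <- ball_morph(ball_morph(fg, volume$spacing_um, r, TRUE),
                     volume$spacing_um, r, FALSE)
  }
  mask_grid(fg, volume$spacing_um, origin_label = volume$origin_label,
            origin_um = volume$origin_um)
}

#' Label connected components of a mask
#'
#' Components under 6-, 18- or 26-connectivity, summarised by voxel count and
#' physical centroid, sorted by descending size. Label ids are re-assigned in
#' that sorted order (ties broken by ascending centroid z, then by discovery
#' order), so id 1 is always the largest component and ids are stable across
#' runs.
#'
#' @param mask a [mask_grid].
#' @param connectivity 6, 18 or 26.
#' @return An object of class `component_set`: list with `summary` (data frame
#'   of id, voxels, volume_mm3, centroid um per axis), `labels` (integer array
#'   of per-voxel ids, 0 = background) and `connectivity`.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "mask_grid"))
  dims <- dim(mask$data)
  raw <- .cc_label3d(as.vector(mask$data), dims, as.integer(connectivity))
  n <- max(raw, 0L)
  if (n == 0) {
    return(structure(list(
      summary = data.frame(id = integer(), voxels = integer(),
                           volume_mm3 = numeric(), centroid_z_um = numeric(),
                           centroid_y_um = numeric(), centroid_x_um = numeric()),
      labels = array(0L, dim = dims), connectivity = connectivity,
      spacing_um = mask$spacing_um, origin_um = mask$origin_um),
      class = "component_set"))
  }
  counts <- tabulate(raw, nbins = n)
  idx <- which(raw > 0L)
  zi <- (idx - 1L) %% dims[1]
  yi <- ((idx - 1L) %/% dims[1]) %% dims[2]
  xi <- (idx - 1L) %/% (dims[1] * dims[2])
  lab <- raw[idx]
  cz <- vapply(split(zi, lab), mean, numeric(1)) * mask$spacing_um[1] + mask$origin_um[1]
  cy <- vapply(split(yi, lab), mean, numeric(1)) * mask$spacing_um[2] + mask$origin_um[2]
  cx <- vapply(split(xi, lab), mean, numeric(1)) * mask$spacing_um[3] + mask$origin_um[3]
  ord <- order(-counts, cz, seq_len(n))
  remap <- integer(n); remap[ord] <- seq_len(n)
  labels <- array(0L, dim = dims)
  labels[idx] <- remap[lab]
  summary <- data.frame(id = seq_len(n), voxels = counts[ord],
                        volume_mm3 = counts[ord] * prod(mask$spacing_um) / 1e9,
                        centroid_z_um = cz[ord], centroid_y_um = cy[ord],
                        centroid_x_um = cx[ord], row.names = NULL)
  structure(list(summary = summary, labels = labels, connectivity = connectivity,
                 spacing_um = mask$spacing_um, origin_um = mask$origin_um),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d components, connectivity %d\n",
              nrow(x$summary), x$connectivity))
  if (nrow(x$summary)) print(utils::head(x$summary, 10))
  invisible(x)
}

#' Select the infarct core among candidate components
#'
#' The scripted analogue of manually separating candidate surfaces and
#' retaining the infarct core: either take the largest component (ties are
#' already resolved deterministically by [label_components()]: smaller
#' centroid z, then discovery order), or take the component containing a
#' physical seed point.
#'
#' @param components a `component_set`.
#' @param strategy `"largest"`, or a length-3 numeric seed point in
#'   micrometres `(z, y, x)`.
#' @return The selected component id.
#' @export
select_core <- function(components, strategy = "largest") {
  stopifnot(inherits(components, "component_set"))
  if (identical(strategy, "largest")) {
    if (!nrow(components$summary)) stop("no components to select from")
    return(components$summary$id[1])
  }
  if (!is.numeric(strategy) || length(strategy) != 3)
    stop("strategy must be \"largest\" or a (z, y, x) seed point in um")
  dims <- dim(components$labels)
  idx <- round((strategy - components$origin_um) / components$spacing_um) + 1
  if (any(idx < 1) || any(idx > dims)) stop("seed point outside the volume")
  id <- components$labels[idx[1], idx[2], idx[3]]
  if (id == 0) stop("seed point falls in background, not in any component")
  id
}

new_lesion_segmentation <- function(mask, threshold, components, selected_id,
                                    params, found) {
  structure(list(mask = mask, threshold_value = threshold,
                 all_components = components$summary, selected_id = selected_id,
                 params = params, found = found),
            class = "lesion_segmentation")
}

#' @export
print.lesion_segmentation <- function(x, ...) {
  if (!x$found) {
    cat("<lesion_segmentation> no lesion found (no supra-threshold component)\n")
  } else {
    cat(sprintf("<lesion_segmentation> threshold %.4g, %d candidate component(s), selected id %d (%d voxels)\n",
                x$threshold_value, nrow(x$all_components), x$selected_id,
                sum(x$mask$data)))
  }
  invisible(x)
}

#' Rule-based lesion segmentation of an autofluorescence volume
#'
#' The full workflow: percentile threshold from the contralateral region,
#' global binarization, vessel exclusion by physical feature size, connected
#' component labelling, and infarct-core selection. Every parameter and the
#' realised threshold are recorded in `params` for provenance. A volume with
#' no supra-threshold voxels yields an explicit "no lesion found" result
#' (`found = FALSE`, empty mask) rather than an error.
#'
#' @param volume a [voxel_grid].
#' @param rule a [threshold_rule].
#' @param detail_size_um vessel-exclusion opening diameter (um).
#' @param connectivity component connectivity (6, 18 or 26).
#' @param strategy core selection: `"largest"` or a seed point (um).
#' @return A `lesion_segmentation`: the selected core [mask_grid], the
#'   threshold value, the component summary, the selected id, and the full
#'   parameter record.
#' @examples
#' set <- make_phantom(default_phantom_spec(0.2, seed = 7))
#' roi <- contralateral_roi(set)
#' rule <- threshold_rule(99, roi_box_from_um(set$lsfm, roi$lo_um, roi$hi_um))
#' seg <- segment_lesion(set$lsfm, rule)
#' mask_volume(seg$mask)$volume_mm3  # close to set$truth_volume_mm3
#' @export
segment_lesion <- function(volume, rule, detail_size_um = 30,
                           connectivity = 26, strategy = "largest") {
  stopifnot(inherits(volume, "voxel_grid"), inherits(rule, "threshold_rule"))
  thr <- contralateral_threshold(volume, rule)
  segment_at_threshold(volume, rule, thr, detail_size_um, connectivity,
                       strategy, delta_steps = 0L)
}

segment_at_threshold <- function(volume, rule, thr, detail_size_um,
                                 connectivity, strategy, delta_steps) {
  mask <- binarize_and_exclude_vessels(volume, thr, detail_size_um)
  comps <- label_components(mask, connectivity)
  params <- list(percentile = rule$percentile, roi = rule$roi,
                 detail_size_um = detail_size_um, connectivity = connectivity,
                 strategy = strategy, refine_delta_steps = delta_steps,
                 threshold = thr)
  if (!nrow(comps$summary)) {
    empty <- mask_grid(array(FALSE, dim = dim(volume$data)), volume$spacing_um,
                       origin_label = volume$origin_label,
                       origin_um = volume$origin_um)
    return(new_lesion_segmentation(empty, thr, comps, NA_integer_, params, FALSE))
  }
  sel <- select_core(comps, strategy)
  core <- mask_grid(comps$labels == sel, volume$spacing_um,
                    origin_label = volume$origin_label,
                    origin_um = volume$origin_um)
  new_lesion_segmentation(core, thr, comps, sel, params, TRUE)
}

#' Bounded threshold refinement
#'
#' The audited analogue of minutely adjusting the threshold after visual
#' inspection: the threshold moves by `delta_steps` steps of 1% of the
#' contralateral-ROI dynamic range, and the binarize/label/select stages are
#' re-run. The adjustment is recorded in `params`; `delta_steps = 0` is the
#' identity.
#'
#' @param volume the [voxel_grid] the segmentation came from.
#' @param segmentation a `lesion_segmentation` produced by [segment_lesion()].
#' @param delta_steps integer in `[-10, 10]`.
#' @return A refreshed `lesion_segmentation`.
#' @export
refine_threshold <- function(volume, segmentation, delta_steps) {
  stopifnot(inherits(segmentation, "lesion_segmentation"),
            abs(delta_steps) <= 10)
  p <- segmentation$params
  rule <- threshold_rule(p$percentile, p$roi)
  rng <- range(roi_values(volume, p$roi))
  step <- 0.01 * (rng[2] - rng[1])
  base_thr <- segmentation$threshold_value -
    segmentation$params$refine_delta_steps * step
  thr <- base_thr + delta_steps * step
  drng <- range(volume$data)
  if (thr < drng[1] || thr > drng[2])
    stop("refined threshold falls outside the volume intensity range")
  segment_at_threshold(volume, rule, thr, p$detail_size_um, p$connectivity,
                       p$strategy, delta_steps = as.integer(delta_steps))
}
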