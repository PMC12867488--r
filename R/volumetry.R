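#' Physical volume measurement
#'
#' Container for a lesion volume in cubic millimetres plus the method that
#' produced it (`"voxel"` counting of a 3D mask, or `"slice_sum"` of
#' per-section areas times thickness) and any shrinkage correction applied.
#'
#' @param volume_mm3 non-negative volume (mm^3).
#' @param method `"voxel"` or `"slice_sum"`.
#' @param correction optional length-3 linear factors that were divided out.
#' @return An object of class `volume_result`.
#' @export
volume_result <- function(volume_mm3, method = c("voxel", "slice_sum"),
                          correction = NULL) {
  method <- match.arg(method)
  stopifnot(is.numeric(volume_mm3), length(volume_mm3) == 1, volume_mm3 >= 0)
  if (!is.null(correction))
    stopifnot(length(correction) == 3, all(correction > 0), all(correction <= 10))
  structure(list(volume_mm3 = as.numeric(volume_mm3), method = method,
                 correction = correction),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("<volume_result> %.6g mm^3 (%s%s)\n", x$volume_mm3, x$method,
              if (is.null(x$correction)) "" else
                paste0(", shrinkage-corrected by ",
                       paste(format(x$correction), collapse = " x "))))
  invisible(x)
}

#' Volume of a binary mask by voxel counting
#'
#' Foreground voxel count times the physical voxel volume, converted from
#' cubic micrometres to cubic millimetres.
#'
#' @param mask a [mask_grid].
#' @return A [volume_result] with method `"voxel"`.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "mask_grid"))
  volume_result(sum(mask$data) * voxel_volume_um3(mask) / 1e9, "voxel")
}

#' Slice-based volume estimate
#'
#' The slice-sum estimator used for MRI and serial-section histology: the
#' infarct areas of all sections summed and multiplied by the section
#' thickness (or inter-section interval for subsampled series).
#'
#' @param series a [slice_series].
#' @return A [volume_result] with method `"slice_sum"`.
#' @export
slice_volume <- function(series) {
  stopifnot(inherits(series, "slice_series"))
  volume_result(sum(series$areas_mm2) * series$thickness_mm, "slice_sum")
}

#' Resample a volume into another acquisition orientation
#'
#' Reorders the axes by `axis_permutation` and resamples the intensities
#' along the new axial (first) axis to `new_axial_step_um` by linear
#' interpolation between planes, emulating re-mounting the specimen and
#' acquiring along a different direction with a coarser axial step. Only
#' intensities are ever resampled; segmentation must then be re-run on the
#' result (masks are never interpolated).
#'
#' @param volume a [voxel_grid].
#' @param axis_permutation permutation of `c(1, 2, 3)`: position `i` of the
#'   output takes input axis `axis_permutation[i]`.
#' @param new_axial_step_um axial step of the resampled grid; must be at
#'   least the native spacing along the new axial axis.
#' @param origin_label orientation tag for the result.
#' @return A [voxel_grid] on the permuted, axially resampled grid.
#' @export
resample_orientation <- function(volume, axis_permutation,
                                 new_axial_step_um = NULL,
                                 origin_label = volume$origin_label) {
  stopifnot(inherits(volume, "voxel_grid"),
            length(axis_permutation) == 3,
            setequal(axis_permutation, 1:3))
  a <- aperm(volume$data, axis_permutation)
  sp <- volume$spacing_um[axis_permutation]
  org <- volume$origin_um[axis_permutation]
  if (is.null(new_axial_step_um)) new_axial_step_um <- sp[1]
  if (new_axial_step_um < sp[1] - 1e-9)
    stop("new axial step must be at least the native spacing along that axis")
  if (abs(new_axial_step_um - sp[1]) > 1e-9) {
    n <- dim(a)[1]
    pos <- seq(0, (n - 1) * sp[1], by = new_axial_step_um)
    i0 <- pmin(floor(pos / sp[1]), n - 2)
    f <- pos / sp[1] - i0
    out <- array(0, dim = c(length(pos), dim(a)[2], dim(a)[3]))
    for (k in seq_along(pos))
      out[k, , ] <- (1 - f[k]) * a[i0[k] + 1, , ] + f[k] * a[i0[k] + 2, , ]
    a <- out
    sp[1] <- new_axial_step_um
  }
  voxel_grid(a, sp, origin_label = origin_label, origin_um = org)
}

#' Per-axis dimensional change from tissue clearing
#'
#' Percent change per axis, `(pre - post) / pre * 100`, as measured by
#' imaging brains on a calibration grid before and after clearing. Changes
#' of roughly 10-30% per dimension are typical of solvent-based clearing;
#' the result carries a `consistent_with_clearing` flag for that band.
#'
#' @param pre_mm,post_mm length-3 positive dimensions (mm), e.g. length,
#'   width, height.
#' @return An object of class `dimension_change` with fields `pre_mm`,
#'   `post_mm`, `percent_change`, `consistent_with_clearing`.
#' @export
shrinkage_percent <- function(pre_mm, post_mm) {
  stopifnot(length(pre_mm) == 3, length(post_mm) == 3)
  if (any(pre_mm <= 0) || any(post_mm <= 0))
    stop("dimensions must be strictly positive")
  pc <- (pre_mm - post_mm) / pre_mm * 100
  stopifnot(all(is.finite(pc)))
  structure(list(pre_mm = as.numeric(pre_mm), post_mm = as.numeric(post_mm),
                 percent_change = pc,
                 consistent_with_clearing = all(pc >= 10 & pc <= 30)),
            class = "dimension_change")
}

#' @export
print.dimension_change <- function(x, ...) {
  cat(sprintf("<dimension_change> %s%% per axis%s\n",
              paste(format(round(x$percent_change, 2)), collapse = ", "),
              if (x$consistent_with_clearing)
                " (consistent with clearing shrinkage)" else ""))
  invisible(x)
}

#' Correct a measured volume for clearing shrinkage
#'
#' Divides the measured (post-clearing) volume by the product of the linear
#' factors `post/pre`, recovering pre-clearing scale; 20% shrinkage on every
#' axis corresponds to a volume factor `1 / 0.8^3`, i.e. roughly a twofold
#' reduction. Correction is deliberately not applied by default anywhere in
#' the package: cross-modality comparisons are made in post-clearing space
#' because relative lesion size is preserved by the (consistent) shrinkage.
#'
#' @param vol a [volume_result].
#' @param change a `dimension_change` from [shrinkage_percent()].
#' @return A [volume_result] with the correction recorded.
#' @export
correct_for_shrinkage <- function(vol, change) {
  stopifnot(inherits(vol, "volume_result"), inherits(change, "dimension_change"))
  f <- change$post_mm / change$pre_mm
  if (any(f <= 0)) stop("linear factors must be positive")
  if (any(f > 1)) stop("post-clearing dimensions exceed pre-clearing; not shrinkage")
  volume_result(vol$volume_mm3 / prod(f), vol$method, correction = f)
}
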