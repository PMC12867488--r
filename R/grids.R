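#' Volumetric image with physical voxel spacing
#'
#' The carrier of all volumetric imagery in the package: a 3D scalar array in
#' `(z, y, x)` axis order (z is the axial/acquisition direction) with a
#' physical spacing in micrometres per voxel along each axis. Light-sheet
#' acquisitions are strongly anisotropic -- in-plane pitch of a few
#' micrometres against 10- to 15-micrometre axial steps -- so the spacing is
#' mandatory and asserted positive.
#'
#' @param data 3D numeric array, axis order `(z, y, x)`.
#' @param spacing_um numeric length-3, micrometres per voxel along `(z, y, x)`;
#'   all strictly positive.
#' @param origin_label free-text orientation tag (e.g. `"dorsal"`,
#'   `"sagittal"`).
#' @param origin_um physical position (micrometres) of the centre of voxel
#'   `[1, 1, 1]` along `(z, y, x)`. Defaults to centring the grid on the
#'   physical origin.
#' @return An object of class `voxel_grid` with fields `data`, `spacing_um`,
#'   `origin_label`, `origin_um`.
#' @examples
#' vg <- voxel_grid(array(0, c(4, 5, 6)), spacing_um = c(10, 2, 2))
#' voxel_volume_um3(vg)  # 40 um^3 per voxel
#' @export
voxel_grid <- function(data, spacing_um, origin_label = "", origin_um = NULL) {
  data <- check_volume_array(data, "data")
  spacing_um <- check_spacing(spacing_um)
  if (is.null(origin_um)) origin_um <- -(dim(data) - 1) / 2 * spacing_um
  stopifnot(is.numeric(origin_um), length(origin_um) == 3)
  structure(
    list(data = data, spacing_um = spacing_um,
         origin_label = as.character(origin_label)[1], origin_um = origin_um),
    class = "voxel_grid")
}

#' Binary mask on a voxel grid
#'
#' A 3D binary array sharing the shape and spacing of the volume it was
#' derived from. Values are stored as logical; any numeric input is accepted
#' as long as it only contains 0 and 1 (or NA-free logical).
#'
#' @param data 3D logical or 0/1 numeric array in `(z, y, x)` order.
#' @inheritParams voxel_grid
#' @return An object of class `mask_grid`.
#' @export
mask_grid <- function(data, spacing_um, origin_label = "", origin_um = NULL) {
  data <- check_volume_array(data, "data", allow_logical = TRUE)
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1)))
      stop("mask values must be restricted to {0, 1}")
    data <- array(data != 0, dim = dim(data))
  }
  if (anyNA(data)) stop("mask must not contain NA")
  spacing_um <- check_spacing(spacing_um)
  if (is.null(origin_um)) origin_um <- -(dim(data) - 1) / 2 * spacing_um
  structure(
    list(data = data, spacing_um = spacing_um,
         origin_label = as.character(origin_label)[1], origin_um = origin_um),
    class = "mask_grid")
}

check_volume_array <- function(data, what, allow_logical = FALSE) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (!is.array(data) || length(dim(data)) != 3)
    stop(sprintf("%s must be a 3D array in (z, y, x) order", what))
  if (!is.numeric(data) && !(allow_logical && is.logical(data)))
    stop(sprintf("%s must be numeric", what))
  if (any(dim(data) < 1)) stop(sprintf("%s must have extent >= 1 on every axis", what))
  data
}

check_spacing <- function(spacing_um) {
  if (!is.numeric(spacing_um) || length(spacing_um) != 3)
    stop("spacing_um must be three numbers (z, y, x)")
  bad <- which(!is.finite(spacing_um) | spacing_um <= 0)
  if (length(bad)) {
    ax <- c("z", "y", "x")[bad[1]]
    stop(sprintf("spacing_um must be strictly positive; offending axis: %s", ax))
  }
  as.numeric(spacing_um)
}

#' Physical volume of one voxel
#'
#' @param x a `voxel_grid` or `mask_grid`.
#' @return Voxel volume in cubic micrometres (product of the three spacings).
#' @export
voxel_volume_um3 <- function(x) {
  stopifnot(inherits(x, c("voxel_grid", "mask_grid")))
  prod(x$spacing_um)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' @export
dim.mask_grid <- function(x) dim(x$data)

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, spacing (%s) um%s\n",
              paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing_um), collapse = ", "),
              if (nzchar(x$origin_label)) paste0(", orientation '", x$origin_label, "'") else ""))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.mask_grid <- function(x, ...) {
  cat(sprintf("<mask_grid> %s voxels, spacing (%s) um, %d foreground\n",
              paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing_um), collapse = ", "),
              sum(x$data)))
  invisible(x)
}

# Physical voxel-centre coordinates (um) along one axis (1 = z, 2 = y, 3 = x).
axis_coords_um <- function(grid, axis) {
  grid$origin_um[axis] + (seq_len(dim(grid$data)[axis]) - 1) * grid$spacing_um[axis]
}

# Logical array marking voxel centres inside an axis-aligned ellipsoid.
ellipsoid_mask <- function(dims, spacing_um, origin_um, center_um, semiaxes_um) {
  u <- lapply(1:3, function(a) {
    co <- origin_um[a] + (seq_len(dims[a]) - 1) * spacing_um[a]
    ((co - center_um[a]) / semiaxes_um[a])^2
  })
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  q <- rep(u[[1]], times = ny * nx) +
    rep(rep(u[[2]], each = nz), times = nx) +
    rep(u[[3]], each = nz * ny)
  array(q <= 1, dim = dims)
}
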