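#' Read a volumetric image from TIFF or NIfTI
#'
#' Reads a 3D volume as a [voxel_grid], attaching physical spacing. Supported
#' sources: a multi-page TIFF, a directory of single-plane TIFFs ordered along
#' z by file name, or a NIfTI-1 file (`.nii` / `.nii.gz`). Intensities are
#' never rescaled: integer TIFF samples are returned as the stored integers,
#' float samples and NIfTI data verbatim.
#'
#' TIFF carries no reliable z spacing, so `spacing_um` is mandatory for TIFF
#' input -- silence is an error, not a default, because an axial step of
#' 10-15 um silently replaced by the in-plane pitch corrupts every volume
#' downstream. NIfTI spacings are read from the header, interpreted as
#' millimetres per the NIfTI convention, and converted to micrometres. The
#' array is taken in `(z, y, x)` order as stored (TIFF pages are `(y, x)` and
#' stacked along z).
#'
#' @param path file or directory path.
#' @param spacing_um micrometres per voxel along `(z, y, x)`. Required for
#'   TIFF; for NIfTI it overrides the header when supplied.
#' @param origin_label optional orientation tag carried on the result.
#' @return A [voxel_grid].
#' @export
read_volume <- function(path, spacing_um = NULL, origin_label = "") {
  if (!file.exists(path)) stop(sprintf("no such file or directory: %s", path))
  if (is_nifti_path(path)) {
    img <- RNifti::readNifti(path)
    hdr_sp <- RNifti::pixdim(img) * 1000  # mm -> um
    if (is.null(spacing_um)) spacing_um <- hdr_sp
    arr <- array(as.numeric(img), dim = dim(img))
    if (length(dim(arr)) != 3) stop("NIfTI volume must be 3D")
    return(voxel_grid(arr, spacing_um, origin_label = origin_label))
  }
  if (is.null(spacing_um))
    stop("spacing_um must be supplied for TIFF input (TIFF carries no reliable z spacing)")
  planes <- read_tiff_planes(path)
  shp <- vapply(planes, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("inconsistent plane shapes across the z series")
  arr <- array(0, dim = c(length(planes), shp[1, 1], shp[2, 1]))
  for (i in seq_along(planes)) arr[i, , ] <- planes[[i]]
  voxel_grid(arr, spacing_um, origin_label = origin_label)
}

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

# List of (y, x) matrices, one per z plane, exact sample values. Integer
# samples are recovered unnormalised; float samples are taken as stored
# (detected by checking whether the as-is read is the normalised read times
# the integer full scale).
read_tiff_planes <- function(path) {
  files <- if (dir.exists(path)) {
    f <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE, ignore.case = TRUE))
    if (!length(f)) stop(sprintf("no TIFF planes found in directory: %s", path))
    f
  } else path
  planes <- list()
  for (f in files) {
    norm <- tiff::readTIFF(f, all = TRUE, info = TRUE)
    if (!is.list(norm)) norm <- list(norm)
    raw <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
    if (!is.list(raw)) raw <- list(raw)
    bits <- attr(norm[[1]], "bits.per.sample")
    if (is.null(bits)) bits <- 8L
    integer_samples <- isTRUE(all.equal(
      as.vector(raw[[1]]) * 1.0, as.vector(unclass_plane(norm[[1]])) * (2^bits - 1),
      tolerance = 1e-6))
    use <- if (integer_samples) raw else norm
    planes <- c(planes, lapply(use, function(m) {
      m <- unclass_plane(m)
      storage.mode(m) <- "numeric"
      m
    }))
  }
  lapply(planes, function(m) {
    if (length(dim(m)) == 3 && dim(m)[3] == 1) m <- m[, , 1]
    if (length(dim(m)) != 2) stop("TIFF planes must be single-channel 2D images")
    m
  })
}

unclass_plane <- function(p) {
  attributes(p) <- list(dim = dim(p))
  p
}

#' Write a volumetric image to TIFF or NIfTI
#'
#' TIFF output is a 16-bit multi-page file, one page per z plane, as is
#' conventional for microscopy: volumes whose values are already integers in
#' `[0, 65535]` are stored exactly (and roundtrip bit-exactly through
#' [read_volume()]); any other data are clamped at 0 and linearly scaled to
#' the full 16-bit range. For verbatim floating-point storage use NIfTI,
#' which writes the array exactly with spacing in the header (mm).
#'
#' @param grid a [voxel_grid].
#' @param path destination; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is_nifti_path(path)) {
    img <- RNifti::asNifti(grid$data)
    RNifti::pixdim(img) <- grid$spacing_um / 1000
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  a <- quantize_uint16(grid$data)
  planes <- lapply(seq_len(dim(a)[1]), function(i) a[i, , ] / 65535)
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  invisible(path)
}

# Map arbitrary data onto the uint16 range: integer data in range passes
# through unchanged, anything else is clamped at 0 and scaled to full range.
quantize_uint16 <- function(a) {
  if (all(a >= 0 & a <= 65535 & a == round(a))) return(a)
  hi <- max(a)
  if (hi <= 0) return(array(0, dim = dim(a)))
  round(pmax(a, 0) / hi * 65535)
}

#' Write a binary mask to TIFF or NIfTI
#'
#' Encodes the mask as 8-bit with foreground 255 for TIFF, or as 0/1 integers
#' for NIfTI.
#'
#' @param mask a [mask_grid].
#' @param path destination; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_grid"))
  if (is_nifti_path(path)) {
    img <- RNifti::asNifti(array(as.integer(mask$data), dim = dim(mask$data)))
    RNifti::pixdim(img) <- mask$spacing_um / 1000
    RNifti::writeNifti(img, path, datatype = "uint8")
    return(invisible(path))
  }
  planes <- lapply(seq_len(dim(mask$data)[1]), function(i) mask$data[i, , ] * 1.0)
  tiff::writeTIFF(planes, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#'
#' Any nonzero sample is foreground, so both the TIFF (255) and NIfTI (1)
#' encodings decode to the same mask.
#'
#' @inheritParams read_volume
#' @return A [mask_grid].
#' @export
read_mask <- function(path, spacing_um = NULL, origin_label = "") {
  vg <- read_volume(path, spacing_um = spacing_um, origin_label = origin_label)
  mask_grid(vg$data != 0, vg$spacing_um, origin_label = vg$origin_label,
            origin_um = vg$origin_um)
}

#' Ordered per-section infarct areas
#'
#' Input to slice-based volumetry: the per-section infarct areas in square
#' millimetres, in anatomical order, with the section thickness (or, for
#' subsampled series, the inter-section interval) in millimetres that
#' multiplies the summed area.
#'
#' @param areas_mm2 numeric vector of non-negative areas, ordered along the
#'   sectioning axis.
#' @param thickness_mm positive section thickness / interval in millimetres.
#' @return An object of class `slice_series`.
#' @export
slice_series <- function(areas_mm2, thickness_mm) {
  areas_mm2 <- as.numeric(areas_mm2)
  if (!length(areas_mm2)) stop("no sections")
  if (anyNA(areas_mm2)) stop("non-numeric or missing area value")
  if (any(areas_mm2 < 0)) stop("negative area")
  thickness_mm <- as.numeric(thickness_mm)[1]
  if (!is.finite(thickness_mm) || thickness_mm <= 0) stop("thickness must be > 0")
  structure(list(areas_mm2 = areas_mm2, thickness_mm = thickness_mm),
            class = "slice_series")
}

#' @export
print.slice_series <- function(x, ...) {
  cat(sprintf("<slice_series> %d sections, thickness %g mm, total area %g mm^2\n",
              length(x$areas_mm2), x$thickness_mm, sum(x$areas_mm2)))
  invisible(x)
}

#' Read a per-section infarct area table from CSV
#'
#' The CSV must carry columns `section_index` and `area_mm2`. The section
#' thickness is taken from a comment header line of the form
#' `# thickness_mm: 0.2`, or from the `thickness_mm` argument (the argument
#' wins when both are present). Rows are returned in `section_index` order;
#' missing indices are permitted and treated as listed.
#'
#' @param path CSV file path.
#' @param thickness_mm optional thickness in millimetres.
#' @return A [slice_series].
#' @export
read_slice_table <- function(path, thickness_mm = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (is.null(thickness_mm)) {
    head_lines <- grep("^#", readLines(path, n = 10), value = TRUE)
    m <- regmatches(head_lines, regexec("thickness_mm[:=]\\s*([0-9.eE+-]+)", head_lines))
    hit <- Filter(function(g) length(g) == 2, m)
    if (length(hit)) thickness_mm <- as.numeric(hit[[1]][2])
  }
  if (is.null(thickness_mm))
    stop("thickness_mm not found in header and not supplied")
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("section_index", "area_mm2")
  if (!all(need %in% names(tab)))
    stop("CSV must have columns section_index and area_mm2")
  if (!nrow(tab)) stop("no sections")
  idx <- suppressWarnings(as.numeric(tab$section_index))
  areas <- suppressWarnings(as.numeric(tab$area_mm2))
  if (anyNA(idx) || anyNA(areas)) stop("non-numeric cell in slice table")
  slice_series(areas[order(idx)], thickness_mm)
}

#' Write a slice table readable by [read_slice_table()]
#'
#' @param series a [slice_series].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_slice_table <- function(series, path) {
  stopifnot(inherits(series, "slice_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# thickness_mm: %.10g", series$thickness_mm), con)
  write.csv(data.frame(section_index = seq_along(series$areas_mm2),
                       area_mm2 = series$areas_mm2),
            con, row.names = FALSE)
  invisible(path)
}
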