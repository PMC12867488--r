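#' Time series of laser speckle frames
#'
#' Raw speckle frames as a `(t, y, x)` array of non-negative intensities,
#' with the camera pixel pitch and frame rate. A typical acquisition covers
#' ~10 x 10 mm at 1024 x 1024 pixels (9.77 um pitch) for 30 s at 10 Hz.
#'
#' @param frames 3D array `(t, y, x)` of non-negative intensities.
#' @param pixel_pitch_um physical pixel pitch (um), > 0.
#' @param frame_rate_hz frame rate (Hz), > 0.
#' @return An object of class `speckle_stack`.
#' @export
speckle_stack <- function(frames, pixel_pitch_um, frame_rate_hz = 10) {
  if (is.matrix(frames)) dim(frames) <- c(1L, dim(frames))
  stopifnot(is.array(frames), length(dim(frames)) == 3, dim(frames)[1] >= 1,
            all(frames >= 0), pixel_pitch_um > 0, frame_rate_hz > 0)
  structure(list(frames = frames, pixel_pitch_um = as.numeric(pixel_pitch_um),
                 frame_rate_hz = as.numeric(frame_rate_hz)),
            class = "speckle_stack")
}

#' @export
print.speckle_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<speckle_stack> %d frames of %d x %d px, pitch %g um, %g Hz\n",
              d[1], d[2], d[3], x$pixel_pitch_um, x$frame_rate_hz))
  invisible(x)
}

#' Read a speckle frame stack from a multi-page TIFF
#'
#' @param path multi-page TIFF, one page per frame.
#' @param pixel_pitch_um physical pixel pitch (um).
#' @param frame_rate_hz frame rate (Hz).
#' @return A [speckle_stack].
#' @export
read_speckle <- function(path, pixel_pitch_um, frame_rate_hz = 10) {
  planes <- read_tiff_planes(path)
  shp <- vapply(planes, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("inconsistent frame shapes")
  fr <- array(0, dim = c(length(planes), shp[1, 1], shp[2, 1]))
  for (i in seq_along(planes)) fr[i, , ] <- planes[[i]]
  speckle_stack(fr, pixel_pitch_um, frame_rate_hz)
}

#' Write a speckle stack as a multi-page TIFF
#'
#' Frames are stored as 16-bit pages (integer intensities in `[0, 65535]`
#' exactly, anything else scaled to full range). Speckle contrast is
#' invariant under a global intensity scale, so the rescaling is harmless
#' for downstream analysis.
#'
#' @param stack a [speckle_stack].
#' @param path destination TIFF path.
#' @return `path`, invisibly.
#' @export
write_speckle <- function(stack, path) {
  stopifnot(inherits(stack, "speckle_stack"))
  a <- quantize_uint16(stack$frames)
  planes <- lapply(seq_len(dim(a)[1]), function(i) a[i, , ] / 65535)
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  invisible(path)
}

# Windowed sums by integral image with symmetric (reflect) border padding.
# Returns list(sum, sumsq) of window totals for an odd window w.
window_sums <- function(m, w) {
  r <- (w - 1L) %/% 2L
  n1 <- nrow(m); n2 <- ncol(m)
  if (r > n1 || r > n2) stop("window larger than the frame allows")
  ri <- c(r:1, 1:n1, n1:(n1 - r + 1))
  ci <- c(r:1, 1:n2, n2:(n2 - r + 1))
  box <- function(p) {
    s <- rbind(0, apply(p, 2, cumsum))               # (n1+2r+1) x (n2+2r)
    s <- s[(w + 1):(n1 + 2 * r + 1), , drop = FALSE] -
      s[1:n1, , drop = FALSE]                        # n1 x (n2+2r)
    s <- cbind(0, t(apply(s, 1, cumsum)))            # n1 x (n2+2r+1)
    s[, (w + 1):(n2 + 2 * r + 1), drop = FALSE] - s[, 1:n2, drop = FALSE]
  }
  p <- m[ri, ci, drop = FALSE]
  list(sum = box(p), sumsq = box(p * p))
}

#' Speckle contrast map
#'
#' Speckle contrast `k = SD / mean` of the intensity. In the default spatial
#' mode, `k` is computed per frame over a sliding square window (sample SD,
#' `n - 1` denominator; symmetric reflection at the borders) and the
#' per-frame maps are averaged over the stack. In temporal mode `k` is the
#' per-pixel SD/mean over time. Windows (or pixels) with zero mean get
#' `k = 0`. Fully developed unaveraged speckle has `k = 1`; flow blurs the
#' pattern and lowers `k`, so hypoperfused tissue shows *elevated* contrast.
#'
#' @param stack a [speckle_stack].
#' @param window_px odd window side length (>= 3); ignored in temporal mode.
#' @param mode `"spatial"` (default) or `"temporal"`.
#' @return An object of class `contrast_map` with fields `k` (2D array),
#'   `window_px`, `pixel_pitch_um`, `mode`, `n_frames`.
#' @export
contrast_map <- function(stack, window_px = 7, mode = c("spatial", "temporal")) {
  stopifnot(inherits(stack, "speckle_stack"))
  mode <- match.arg(mode)
  d <- dim(stack$frames)
  if (d[1] < 1) stop("empty stack")
  if (mode == "spatial") {
    if (window_px %% 2 != 1 || window_px < 3)
      stop("window_px must be odd and >= 3")
    wn <- window_px^2
    acc <- matrix(0, d[2], d[3])
    for (t in seq_len(d[1])) {
      ws <- window_sums(stack$frames[t, , ], as.integer(window_px))
      mu <- ws$sum / wn
      v <- pmax(ws$sumsq - ws$sum^2 / wn, 0) / (wn - 1)
      k <- sqrt(v)
      k <- ifelse(mu > 0, k / mu, 0)
      acc <- acc + k
    }
    k <- acc / d[1]
  } else {
    if (d[1] < 2) stop("temporal contrast needs at least 2 frames")
    mu <- apply(stack$frames, c(2, 3), mean)
    s <- apply(stack$frames, c(2, 3), sd)
    k <- ifelse(mu > 0, s / mu, 0)
  }
  structure(list(k = k, window_px = as.integer(window_px),
                 pixel_pitch_um = stack$pixel_pitch_um, mode = mode,
                 n_frames = d[1]),
            class = "contrast_map")
}

#' @export
print.contrast_map <- function(x, ...) {
  cat(sprintf("<contrast_map> %d x %d px (%s, window %d, %d frames), mean k %.3f\n",
              nrow(x$k), ncol(x$k), x$mode, x$window_px, x$n_frames, mean(x$k)))
  invisible(x)
}

#' Relative contrast change between baseline and post-stroke maps
#'
#' Elementwise `(post - baseline) / baseline`. Stroke raises speckle
#' contrast, so hypoperfusion appears as positive change. Pixels where the
#' baseline is zero are set to 0 and counted in a warning.
#'
#' @param baseline,post [contrast_map]s of equal shape and window.
#' @return 2D numeric array of relative change.
#' @export
relative_change <- function(baseline, post) {
  stopifnot(inherits(baseline, "contrast_map"), inherits(post, "contrast_map"))
  if (!all(dim(baseline$k) == dim(post$k)))
    stop("contrast maps have mismatched shapes")
  if (baseline$window_px != post$window_px)
    stop("contrast maps have mismatched windows")
  zero <- baseline$k == 0
  if (any(zero))
    warning(sprintf("%d pixel(s) with zero baseline contrast set to 0", sum(zero)))
  out <- (post$k - baseline$k) / ifelse(zero, 1, baseline$k)
  out[zero] <- 0
  out
}

#' Hypoperfused area from a relative contrast change map
#'
#' Thresholds the relative contrast increase at `cutoff` and reports both the
#' total supra-cutoff area and the area of the largest 8-connected region
#' (the default reported value -- isolated noisy pixels should not count as
#' infarct footprint).
#'
#' @param change 2D relative change array from [relative_change()].
#' @param cutoff minimum relative contrast increase; > 0.
#' @param pixel_pitch_um pixel pitch (um).
#' @return list with `largest_region_mm2` (default reported value),
#'   `total_mm2` and `n_pixels`.
#' @export
hypoperfused_area <- function(change, cutoff = 0.3, pixel_pitch_um) {
  stopifnot(is.matrix(change), cutoff > 0, pixel_pitch_um > 0)
  sel <- change >= cutoff
  px_mm2 <- (pixel_pitch_um / 1000)^2
  if (!any(sel))
    return(list(largest_region_mm2 = 0, total_mm2 = 0, n_pixels = 0L))
  lab <- .cc_label3d(as.vector(sel), c(1L, nrow(sel), ncol(sel)), 26L)
  counts <- tabulate(lab)
  list(largest_region_mm2 = max(counts) * px_mm2,
       total_mm2 = sum(sel) * px_mm2,
       n_pixels = sum(sel))
}
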