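#' Simple linear regression for cross-modality agreement
#'
#' Ordinary least squares of `y` on `x` by the closed forms (means and
#' cross-products), with the coefficient of determination
#' `r^2 = 1 - SS_res / SS_tot` and a two-sided p-value for the slope from
#' `t = slope / SE(slope)` on `n - 2` degrees of freedom. This is the
#' statistic used to compare lesion volumes across imaging modalities and
#' orientations; the closed forms are implemented directly so worked
#' examples are bit-reproducible, with only the t CDF taken from [stats].
#'
#' @param x,y numeric vectors of equal length, `n >= 3`; `x` must vary.
#' @return An object of class `regression_result`: `slope`, `intercept`,
#'   `r2`, `p_value`, `n`, `se_slope`.
#' @examples
#' fit <- linreg(c(1, 2, 3), c(1, 2, 4))
#' fit$slope  # 1.5
#' fit$r2     # 27/28
#' @export
linreg <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 points")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop("x is constant; slope undefined")
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  ss_res <- sum(res^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  se <- sqrt(ss_res / (n - 2) / sxx)
  p <- if (se == 0) .Machine$double.xmin else {
    tval <- slope / se
    max(2 * pt(-abs(tval), df = n - 2), .Machine$double.xmin)
  }
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 p_value = p, n = n, se_slope = se),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> y = %.4g x + %.4g, r2 = %.4f, p = %.3g (n = %d)\n",
              x$slope, x$intercept, x$r2, x$p_value, x$n))
  invisible(x)
}

#' Percent difference relative to a reference
#'
#' `(a - b) / a * 100`: the percent by which `b` falls short of the
#' reference `a` (e.g. post- vs pre-clearing brain dimensions).
#'
#' @param a reference value, nonzero.
#' @param b comparison value.
#' @return Percent difference.
#' @export
percent_difference <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (any(a == 0)) stop("reference value must be nonzero")
  (a - b) / a * 100
}
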