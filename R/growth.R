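#' Maximal specific growth rate from an OD time series
#'
#' Slides a window of `window_points` consecutive time points along the
#' curve, fits `ln(OD)` against time (hours) within each window, and reports
#' the steepest slope as the maximal specific growth rate `mu_max` (per
#' hour). Because plate-reader noise is approximately additive in OD, its
#' variance after the log transform scales as `1/OD^2`; window fits are
#' therefore weighted by `OD^2` by default, which keeps low-OD early windows
#' from dominating the maximum through noise alone. Windows containing
#' non-positive (blanked) OD values are skipped.
#'
#' @param time_min Time points in minutes, strictly increasing.
#' @param od OD600 readings (same length, >= 5 points).
#' @param window_points Number of points per window (default 15; must be
#'   >= 3).
#' @param weighted Weight window fits by `OD^2` (default `TRUE`).
#' @param blank Background to subtract: a number (default 0), or `"first"`
#'   to use the first time point's OD.
#' @return Object of class `growth_rate`: list with `mu_max` (per hour),
#'   `window` (`c(t_start, t_end)` in minutes), `r_squared` of the winning
#'   fit, and `n_windows` evaluated.
#' @examples
#' t_min <- seq(0, 300, by = 10)
#' od <- 0.05 * exp(0.5 * t_min / 60)
#' max_growth_rate(t_min, od, window_points = 5)$mu_max  # 0.5
#' @export
max_growth_rate <- function(time_min, od, window_points = 15L,
                            weighted = TRUE, blank = 0) {
  if (length(time_min) != length(od)) stop("time and OD lengths differ")
  if (any(diff(time_min) <= 0)) stop("time points must be strictly increasing")
  if (window_points < 3L) stop("window_points must be >= 3")
  if (identical(blank, "first")) blank <- od[1L]
  od <- od - blank
  n <- length(od)
  w <- min(as.integer(window_points), n)
  if (n < 5L) stop("need at least 5 time points")
  th <- time_min / 60
  best <- list(mu = -Inf, window = c(NA_real_, NA_real_), r2 = NA_real_)
  n_win <- 0L
  for (i in seq_len(n - w + 1L)) {
    idx <- i:(i + w - 1L)
    if (any(od[idx] <= 0)) next
    x <- th[idx]; y <- log(od[idx])
    wt <- if (weighted) od[idx]^2 else rep(1, w)
    fit <- stats::lm.wfit(cbind(1, x), y, wt)
    n_win <- n_win + 1L
    mu <- unname(fit$coefficients[2L])
    if (mu > best$mu) {
      ybar <- sum(wt * y) / sum(wt)
      r2 <- 1 - sum(wt * fit$residuals^2) / sum(wt * (y - ybar)^2)
      if (!is.finite(r2)) r2 <- 1   # constant-y window
      best <- list(mu = mu, window = c(time_min[idx[1L]], time_min[idx[w]]),
                   r2 = max(0, min(1, r2)))
    }
  }
  if (n_win == 0L) stop("no window with all-positive OD values")
  structure(list(mu_max = max(best$mu, 0), window = best$window,
                 r_squared = best$r2, n_windows = n_win),
            class = "growth_rate")
}

#' @export
print.growth_rate <- function(x, ...) {
  cat(sprintf("mu_max = %.4g / h  (window %g-%g min, r^2 = %.3f)\n",
              x$mu_max, x$window[1L], x$window[2L], x$r_squared))
  invisible(x)
}

#' Growth rate relative to a reference
#'
#' Expresses a strain's maximal growth rate as a percentage of a reference
#' (e.g. the wild type, or the no-drug condition of the same strain).
#'
#' @param test,reference `growth_rate` objects from [max_growth_rate()]
#'   (or bare numbers).
#' @return Percent: `100 * mu_test / mu_reference`.
#' @export
relative_growth <- function(test, reference) {
  mu_t <- if (inherits(test, "growth_rate")) test$mu_max else test
  mu_r <- if (inherits(reference, "growth_rate")) reference$mu_max else reference
  if (mu_r <= 0) stop("reference growth rate must be > 0")
  100 * mu_t / mu_r
}
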