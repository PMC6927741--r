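#' Cross-correlogram of left/right ventral-root envelopes
#'
#' Pearson correlation of two mean-subtracted smoothed envelopes evaluated
#' over a grid of time lags; the zero-lag coefficient `r0` (the center of the
#' cross-correlogram) measures left/right coupling. Positive `r0` indicates
#' synchronous activity, negative `r0` out-of-phase (locomotor-like)
#' activity. Lag 0 is always the exact full-overlap Pearson coefficient; at
#' non-zero lags the coefficient is computed over the overlapping segment.
#' The default lag grid is 10 ms; set `lag_step_s = 1/rate` for
#' sample-resolution lags.
#'
#' @param env_left,env_right [envelope()]s (or single-channel recordings /
#'   numeric vectors already on an envelope scale) of equal length and rate.
#' @param max_lag_s correlogram half-width in seconds.
#' @param lag_step_s lag grid spacing (default 0.01 s).
#' @param rate_hz required only when bare numeric vectors are supplied.
#' @return an object of class `coupling_result`: `r0`, `correlogram`
#'   (`data.frame` of `lag_s, r`), and `label` from [classify_coupling()].
#' @export
cross_correlogram <- function(env_left, env_right, max_lag_s = 5,
                              lag_step_s = 0.01, rate_hz = NULL) {
  a <- as_signal(env_left, rate_hz = rate_hz)
  b <- as_signal(env_right, rate_hz = rate_hz)
  if (a$rate_hz != b$rate_hz) stop("channels must share one sampling rate")
  x <- a$samples; y <- b$samples
  if (length(x) != length(y)) stop("channels must have equal length")
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: a channel has zero variance")
  }
  step <- max(1L, round(lag_step_s * a$rate_hz))
  max_lag <- min(round(max_lag_s * a$rate_hz), n - 2L)
  lags <- unique(c(rev(seq(0L, max_lag, by = step)) * -1L,
                   seq(0L, max_lag, by = step)))
  r <- vapply(lags, function(k) {
    if (k >= 0) stats::cor(x[1:(n - k)], y[(1 + k):n])
    else stats::cor(x[(1 - k):n], y[1:(n + k)])
  }, numeric(1))
  r0 <- stats::cor(x, y)
  res <- structure(list(
    r0 = r0,
    correlogram = data.frame(lag_s = lags / a$rate_hz, r = r),
    max_lag_s = max_lag / a$rate_hz),
    class = "coupling_result")
  res$label <- classify_coupling(res)
  res
}

#' Classify left/right coupling from the zero-lag coefficient
#'
#' Applies the fixed rule: `r0 > 0.5` is synchronous, `r0 < -0.5` is a
#' locomotor-like (fictive locomotion) episode, anything else — including the
#' boundary values themselves — is unclassified.
#'
#' @param result a `coupling_result` from [cross_correlogram()], or a bare
#'   numeric zero-lag coefficient.
#' @return `"synchronous"`, `"locomotor-like"`, or `"unclassified"`.
#' @export
classify_coupling <- function(result) {
  r0 <- if (inherits(result, "coupling_result")) result$r0 else as.numeric(result)
  if (is.na(r0)) stop("r0 is undefined")
  if (r0 > 0.5) "synchronous"
  else if (r0 < -0.5) "locomotor-like"
  else "unclassified"
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling> r0 = %.4f -> %s (correlogram +/- %g s)\n",
              x$r0, x$label, x$max_lag_s))
  invisible(x)
}
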