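#' IPSP amplitude-vs-holding-potential series
#'
#' IPSP amplitudes evoked at a set of holding potentials in one motoneuron.
#' The reversal potential E_IPSP is the holding potential at which the
#' amplitude crosses zero; at least 22 points per cell is the conventional
#' sampling density, enforced as a warning (not an error) at fit time.
#'
#' @param holding_mv holding potentials in mV.
#' @param amp_mv IPSP amplitudes in mV (hyperpolarizing responses negative).
#' @param v_rest_mv resting membrane potential in mV, used for the driving
#'   force.
#' @param junction_offset_mv liquid-junction potential subtracted from the
#'   holding potentials before fitting (off-line correction).
#' @return an object of class `ipsp_series`.
#' @export
ipsp_series <- function(holding_mv, amp_mv, v_rest_mv = NA_real_,
                        junction_offset_mv = 0) {
  if (length(holding_mv) != length(amp_mv)) {
    stop("holding_mv and amp_mv must have equal length")
  }
  structure(list(points = data.frame(holding_mv = as.numeric(holding_mv),
                                     amp_mv = as.numeric(amp_mv)),
                 v_rest_mv = v_rest_mv,
                 junction_offset_mv = junction_offset_mv),
            class = "ipsp_series")
}

#' Estimate the IPSP reversal potential
#'
#' Ordinary least-squares line `amplitude = m*V + b` through the
#' (junction-corrected) holding potentials; E_IPSP is the intercept of the
#' regression line with the x-axis, `-b/m`, and the chloride driving force is
#' `E_IPSP - V_rest`. A flat line (slope below numerical tolerance) leaves
#' the x-intercept unidentifiable and is an error.
#'
#' @param series an [ipsp_series()] with at least 2 distinct holding
#'   potentials.
#' @param n_warn warn when fewer than this many points are supplied
#'   (default 22).
#' @return an object of class `eipsp_result`: `e_ipsp_mv`,
#'   `slope_mv_per_mv`, `intercept_mv`, `driving_force_mv`, `residual_sd_mv`,
#'   `n`.
#' @export
estimate_eipsp <- function(series, n_warn = 22L) {
  stopifnot(inherits(series, "ipsp_series"))
  v <- series$points$holding_mv - series$junction_offset_mv
  a <- series$points$amp_mv
  if (length(unique(v)) < 2L) {
    stop("need at least 2 distinct holding potentials")
  }
  if (length(v) < n_warn) {
    warning(sprintf("only %d points (fewer than the conventional %d)",
                    length(v), n_warn))
  }
  fit <- stats::lm(a ~ v)
  b <- unname(stats::coef(fit)[1])
  m <- unname(stats::coef(fit)[2])
  if (abs(m) < 1e-12 * max(1, abs(b))) {
    stop("unidentifiable intercept: regression slope is numerically zero")
  }
  e <- -b / m
  structure(list(
    e_ipsp_mv = e, slope_mv_per_mv = m, intercept_mv = b,
    driving_force_mv = e - series$v_rest_mv,
    residual_sd_mv = sqrt(mean(stats::residuals(fit)^2)),
    n = length(v)),
    class = "eipsp_result")
}

#' @export
print.eipsp_result <- function(x, ...) {
  cat(sprintf(
    "<E_IPSP> %.2f mV (slope %.3g, n = %d, residual sd %.3g mV); driving force %.2f mV\n",
    x$e_ipsp_mv, x$slope_mv_per_mv, x$n, x$residual_sd_mv,
    x$driving_force_mv))
  invisible(x)
}

#' Voltage-ramp trace
#'
#' Command/current pair from the slow-ramp protocol used to isolate the
#' persistent sodium current: the command rises linearly (the canonical
#' protocol is 12 mV/s from -70 to -10 mV over 5 s, slow enough to
#' inactivate the transient sodium current), and the recorded current is the
#' sum of a linear leak and voltage-gated components. Currents are in pA,
#' inward negative.
#'
#' @param v_cmd_mv command voltage samples (mV), non-decreasing.
#' @param i_pa recorded current samples (pA).
#' @param rate_hz sampling rate in Hz.
#' @param truth optional ground-truth annotation (used by the synthetic
#'   generator).
#' @return an object of class `ramp_trace`.
#' @export
ramp_trace <- function(v_cmd_mv, i_pa, rate_hz, truth = NULL) {
  if (length(v_cmd_mv) != length(i_pa)) {
    stop("v_cmd_mv and i_pa must have equal length")
  }
  if (any(diff(v_cmd_mv) < 0)) stop("command ramp must be non-decreasing")
  structure(list(v_cmd_mv = as.numeric(v_cmd_mv), i_pa = as.numeric(i_pa),
                 rate_hz = as.numeric(rate_hz), truth = truth),
            class = "ramp_trace")
}

#' Fit the linear leak current
#'
#' Least-squares line `I = g_leak * (V - e_leak)` over the subthreshold
#' portion of the ramp, where voltage-gated conductances are still closed.
#' The default window (-70, -60) mV sits well below persistent-sodium
#' activation, so contamination of the fit is negligible; it is fully
#' configurable.
#'
#' @param ramp a [ramp_trace()].
#' @param window_mv `c(lo, hi)` voltage window for the fit; needs at least
#'   10 samples.
#' @return `list(g_leak_ns, e_leak_mv)` (slope in nS for mV/pA data, reversal
#'   in mV).
#' @export
fit_leak <- function(ramp, window_mv = c(-70, -60)) {
  stopifnot(inherits(ramp, "ramp_trace"))
  sel <- ramp$v_cmd_mv >= window_mv[1] & ramp$v_cmd_mv <= window_mv[2]
  if (sum(sel) < 10L) stop("leak window contains fewer than 10 samples")
  fit <- stats::lm(ramp$i_pa[sel] ~ ramp$v_cmd_mv[sel])
  g <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  if (abs(g) < 1e-15) stop("leak conductance is numerically zero")
  list(g_leak_ns = g, e_leak_mv = -b / g)
}

#' Extract the persistent sodium current from a leak-subtracted ramp
#'
#' Subtracts the fitted linear leak from the ramp current,
#' `I* = I - g_leak*(V - e_leak)`, and measures the magnitude of I_NaP as
#' the peak of the leak-subtracted inward current during the ascending phase
#' of the voltage command (reported as a positive amplitude). The voltage
#' activation threshold is the membrane potential at which the slope of the
#' leak-subtracted current first becomes negative: slopes are estimated by
#' least squares over a sliding `slope_window_mv` voltage window (raw
#' differencing is noise-dominated), and the negative slope must persist for
#' at least `persist_mv` to count, preventing single-sample triggers. When no
#' supra-tolerance negative slope exists the threshold is flagged undefined
#' and the peak is still reported.
#'
#' @param ramp a [ramp_trace()].
#' @param leak leak parameters from [fit_leak()] (list with `g_leak_ns`,
#'   `e_leak_mv`).
#' @param slope_window_mv width of the sliding slope-estimation window (mV).
#' @param slope_tol slope must fall below `-slope_tol` (pA/mV); `NULL`
#'   (default) uses 3 standard errors of the sliding-window slope estimate
#'   derived from the leak-fit residuals, which degrades to 0 for noiseless
#'   traces.
#' @param persist_mv voltage span over which the negative slope must persist.
#' @param smooth_mv the peak is read from a running mean of the
#'   leak-subtracted current over this command-voltage span, so single-sample
#'   noise extremes do not masquerade as the peak; 0 disables smoothing.
#' @return an object of class `inap_result`: `peak_amp_pa`,
#'   `v_threshold_mv` (`NA` + `threshold_defined = FALSE` when undefined),
#'   `g_leak_ns`, `e_leak_mv`, `i_sub_pa` (the leak-subtracted trace).
#' @export
extract_inap <- function(ramp, leak = fit_leak(ramp), slope_window_mv = 2,
                         slope_tol = NULL, persist_mv = 1, smooth_mv = 0.5) {
  stopifnot(inherits(ramp, "ramp_trace"))
  v <- ramp$v_cmd_mv
  i_sub <- ramp$i_pa - leak$g_leak_ns * (v - leak$e_leak_mv)
  dv_per_sample <- mean(diff(v))
  i_for_peak <- i_sub
  if (smooth_mv > 0 && dv_per_sample > 0) {
    w <- round(smooth_mv / dv_per_sample)
    if (w >= 2L) {
      sm <- as.numeric(stats::filter(i_sub, rep(1 / w, w), sides = 2))
      i_for_peak <- sm[!is.na(sm)]
    }
  }
  peak <- abs(min(i_for_peak))
  # sliding least-squares slope over slope_window_mv, stepped every half window
  step_mv <- slope_window_mv / 4
  centers <- seq(min(v) + slope_window_mv / 2, max(v) - slope_window_mv / 2,
                 by = step_mv)
  slope_at <- function(c0) {
    sel <- v >= c0 - slope_window_mv / 2 & v <= c0 + slope_window_mv / 2
    if (sum(sel) < 3L) return(NA_real_)
    vv <- v[sel]
    unname(stats::cov(vv, i_sub[sel]) / stats::var(vv))
  }
  slopes <- vapply(centers, slope_at, numeric(1))
  if (is.null(slope_tol)) {
    # SE of the window slope under iid noise; noise SD estimated from the
    # residuals of a local linear detrend at the foot of the ramp, so a
    # systematic (signal) slope there does not inflate the tolerance
    sel0 <- v >= centers[1] - slope_window_mv / 2 &
      v <= centers[1] + slope_window_mv / 2
    foot <- v <= min(v) + 5
    noise_sd <- stats::sd(stats::residuals(stats::lm(i_sub[foot] ~ v[foot])))
    ssx <- sum((v[sel0] - mean(v[sel0]))^2)
    slope_tol <- if (ssx > 0) 3 * noise_sd / sqrt(ssx) else 0
  }
  run_len <- max(1L, round(persist_mv / step_mv))
  neg <- !is.na(slopes) & slopes < -slope_tol
  v_thr <- NA_real_
  if (any(neg)) {
    r <- rle(neg)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= run_len)
    if (length(ok)) v_thr <- centers[starts[ok[1]]]
  }
  structure(list(
    peak_amp_pa = peak,
    v_threshold_mv = v_thr,
    threshold_defined = !is.na(v_thr),
    g_leak_ns = leak$g_leak_ns, e_leak_mv = leak$e_leak_mv,
    slope_tol = slope_tol,
    i_sub_pa = i_sub),
    class = "inap_result")
}

#' @export
print.inap_result <- function(x, ...) {
  thr <- if (x$threshold_defined) sprintf("%.2f mV", x$v_threshold_mv) else "undefined"
  cat(sprintf(
    "<I_NaP> peak %.2f pA; activation threshold %s; leak g = %.3g nS, E = %.3g mV\n",
    x$peak_amp_pa, thr, x$g_leak_ns, x$e_leak_mv))
  invisible(x)
}
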