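#' Full-wave rectification
#'
#' Samplewise absolute value of one channel, the first stage of the
#' rectify-integrate-smooth chain applied to ventral-root and EMG signals.
#'
#' @param rec a [recording()].
#' @param channel channel label or index (`NULL` for a single-channel
#'   recording).
#' @return a single-channel [recording()] of `|x|`.
#' @export
rectify <- function(rec, channel = NULL) {
  idx <- channel_index(rec, channel)
  recording(abs(rec$samples[idx, ]), rec$rate_hz, rec$channel_ids[idx],
            t0_s = rec$t0_s, meta = rec$meta)
}

#' Rectified-integrated envelope
#'
#' Emulates the analog RC integrator of the acquisition chain: the channel is
#' full-wave rectified and passed through a causal first-order leaky
#' integrator with unity DC gain,
#' `y[n] = a*y[n-1] + (1-a)*|x[n]|`, `a = exp(-1/(rate*tau))`. A constant
#' input `c` settles to `c`; a unit step reaches `1 - exp(-1)` of its final
#' value one time constant after onset. The default `tau_s = 0.1` is the
#' 100 ms integration constant used for ventral-root activity. A trailing
#' rolling-mean smoother of width `tau_s` is available as a non-default
#' alternative.
#'
#' @param rec a [recording()].
#' @param channel channel label or index.
#' @param tau_s smoothing time constant in seconds; must resolve at least two
#'   sample intervals.
#' @param method `"leaky"` (default) or `"rolling"`.
#' @return an object of class `envelope`: non-negative samples at the source
#'   rate, with `tau_s` and `source_channel` recorded.
#' @export
envelope <- function(rec, channel = NULL, tau_s = 0.1,
                     method = c("leaky", "rolling")) {
  method <- match.arg(method)
  idx <- channel_index(rec, channel)
  if (tau_s <= 0) stop("tau_s must be > 0")
  if (tau_s < 2 / rec$rate_hz) {
    stop("tau_s shorter than 2 sample intervals cannot be resolved")
  }
  x <- abs(rec$samples[idx, ])
  if (method == "leaky") {
    a <- exp(-1 / (rec$rate_hz * tau_s))
    y <- as.numeric(stats::filter((1 - a) * x, a, method = "recursive"))
  } else {
    w <- max(2L, round(tau_s * rec$rate_hz))
    k <- rep(1 / w, w)
    y <- as.numeric(stats::filter(x, k, sides = 1))
    y[seq_len(w - 1L)] <- cumsum(x[seq_len(w - 1L)]) / seq_len(w - 1L)
  }
  structure(list(samples = y, rate_hz = rec$rate_hz, t0_s = rec$t0_s,
                 tau_s = tau_s, source_channel = rec$channel_ids[idx],
                 method = method),
            class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope> %d samples @ %g Hz, tau = %g s, source '%s'\n",
              length(x$samples), x$rate_hz, x$tau_s, x$source_channel))
  invisible(x)
}

# coerce recording / envelope / numeric to a common sampled-signal view
as_signal <- function(x, channel = NULL, rate_hz = NULL) {
  if (inherits(x, "envelope")) {
    list(samples = x$samples, rate_hz = x$rate_hz, t0_s = x$t0_s)
  } else if (inherits(x, "recording")) {
    list(samples = get_channel(x, channel), rate_hz = x$rate_hz, t0_s = x$t0_s)
  } else if (is.numeric(x)) {
    if (is.null(rate_hz)) stop("rate_hz required for a bare numeric signal")
    list(samples = as.numeric(x), rate_hz = rate_hz, t0_s = 0)
  } else {
    stop("expected a recording, envelope, or numeric vector")
  }
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`filtfilt`), giving
#' unit DC gain and no phase shift — the off-line digital filtering used for
#' the 8 Hz EMG envelope. Contrast with [envelope()], which is deliberately
#' causal.
#'
#' @param rec a [recording()].
#' @param channel channel label or index.
#' @param cutoff_hz -3 dB corner, `0 < cutoff_hz < rate/2`.
#' @param order filter order (of each pass).
#' @return a single-channel [recording()] of the filtered signal.
#' @export
lowpass <- function(rec, channel = NULL, cutoff_hz, order = 4L) {
  idx <- channel_index(rec, channel)
  if (cutoff_hz <= 0 || cutoff_hz >= rec$rate_hz / 2) {
    stop("cutoff_hz must lie strictly between 0 and the Nyquist frequency")
  }
  bf <- signal::butter(order, cutoff_hz / (rec$rate_hz / 2), type = "low")
  y <- signal::filtfilt(bf, rec$samples[idx, ])
  recording(as.numeric(y), rec$rate_hz, rec$channel_ids[idx],
            t0_s = rec$t0_s, meta = rec$meta)
}

#' Baseline statistics over a period of inactivity
#'
#' Mean and standard deviation of an envelope over a quiet window; detection
#' thresholds throughout the package are `mean + k*sd` of this baseline.
#' `window = "auto"` selects the 1 s sliding window with minimal RMS, a
#' batch-mode stand-in for a hand-picked inactivity period.
#'
#' @param env an `envelope` (or any object [as_signal()] accepts, with
#'   `rate_hz` supplied for bare vectors).
#' @param window `c(start_s, stop_s)` of at least `min_window_s`, or
#'   `"auto"`.
#' @param min_window_s minimum window length in seconds.
#' @param rate_hz sampling rate, only for bare numeric `env`.
#' @return an object of class `baseline_stats` with fields `mean`, `sd`,
#'   `window`.
#' @export
baseline_stats <- function(env, window = "auto", min_window_s = 1,
                           rate_hz = NULL) {
  sig <- as_signal(env, rate_hz = rate_hz)
  n <- length(sig$samples)
  dur <- n / sig$rate_hz
  if (identical(window, "auto")) {
    w <- round(min_window_s * sig$rate_hz)
    if (w > n) stop("recording shorter than the minimum baseline window")
    cs <- cumsum(c(0, sig$samples^2))
    ms <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
    i0 <- which.min(ms)
    window <- sig$t0_s + c(i0 - 1L, i0 - 1L + w) / sig$rate_hz
  } else {
    if (length(window) != 2L || window[1] >= window[2]) {
      stop("window must be c(start_s, stop_s) with start < stop, or \"auto\"")
    }
    if (window[1] < sig$t0_s - 1e-9 || window[2] > sig$t0_s + dur + 1e-9) {
      stop("baseline window outside recording bounds")
    }
    if (diff(window) < min_window_s - 1e-9) {
      stop(sprintf("baseline window must span at least %g s", min_window_s))
    }
  }
  i0 <- round((window[1] - sig$t0_s) * sig$rate_hz) + 1L
  i1 <- round((window[2] - sig$t0_s) * sig$rate_hz)
  seg <- sig$samples[i0:i1]
  structure(list(mean = mean(seg), sd = stats::sd(seg),
                 window = as.numeric(window)),
            class = "baseline_stats")
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("<baseline> mean %.4g, sd %.4g over [%g, %g) s\n",
              x$mean, x$sd, x$window[1], x$window[2]))
  invisible(x)
}
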