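#' Peak detection on a rectified sweep
#'
#' Voltage-peak detection on one stimulus-aligned sweep: an event is a local
#' maximum of the rectified trace exceeding `mean + k_sd * sd` of the
#' pre-stimulus baseline, with no second event accepted within `refractory_s`
#' of an accepted one, and the artifact window
#' `[stimulus, stimulus + blank_s)` excluded. Events before the stimulus are
#' detected too — they feed the spontaneous-activity correction.
#'
#' @param sweep single-channel [recording()] spanning pre- and post-stimulus
#'   time; it is rectified internally.
#' @param base optional [baseline_stats()]; when `NULL` the mean and SD of
#'   the rectified pre-stimulus segment are used.
#' @param k_sd threshold multiplier (default 3).
#' @param refractory_s dead time after each accepted event.
#' @param blank_s stimulus-artifact blanking in seconds.
#' @param stimulus_time_s stimulus onset (default 0; sweeps are aligned so
#'   the stimulus sits at time 0).
#' @return an [event_table()] of detected peaks (`value` = rectified
#'   amplitude).
#' @export
detect_events <- function(sweep, base = NULL, k_sd = 3, refractory_s = 0.003,
                          blank_s = 0.002, stimulus_time_s = 0) {
  x <- abs(get_channel(sweep))
  tt <- time_axis(sweep)
  if (is.null(base)) {
    pre <- x[tt < stimulus_time_s]
    if (length(pre) < 2L) {
      stop("no pre-stimulus segment to estimate the baseline from; supply `base`")
    }
    thr <- mean(pre) + k_sd * stats::sd(pre)
  } else {
    if (base$window[2] > stimulus_time_s + 1e-12) {
      stop("baseline window overlaps the post-stimulus period")
    }
    thr <- base$mean + k_sd * base$sd
  }
  n <- length(x)
  # strict rise on the left, non-strict fall on the right: plateaus yield one
  # candidate at their first sample
  cand <- which(x > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[x[cand] > x[cand - 1L] & x[cand] >= x[cand + 1L]]
  # exclude artifact window
  in_blank <- tt[cand] >= stimulus_time_s & tt[cand] < stimulus_time_s + blank_s
  cand <- cand[!in_blank]
  if (length(cand) == 0L) {
    return(event_table(channel_id = character(0)))
  }
  # enforce refractory period, earliest-first
  keep <- logical(length(cand))
  last_t <- -Inf
  ct <- tt[cand]
  for (i in seq_along(cand)) {
    if (ct[i] - last_t >= refractory_s) {
      keep[i] <- TRUE
      last_t <- ct[i]
    }
  }
  cand <- cand[keep]
  event_table(time_s = tt[cand], channel_id = sweep$channel_ids[1],
              label = "event", value = x[cand])
}

#' Build a peristimulus time histogram
#'
#' Accumulates detected events from consecutive sweeps into 20 ms bins over a
#' 15 s post-stimulus window (750 bins), with the matched-length pre-stimulus
#' window kept for the spontaneous-activity correction. Event latencies
#' relative to each sweep's stimulus are retained alongside the binned
#' counts so reflex windows that do not align with the bin grid can be
#' counted exactly.
#'
#' @param sweep_events list of [event_table()]s, one per sweep (from
#'   [detect_events()]).
#' @param stimuli list of [stimulus_event()]s (or numeric stimulus times),
#'   one per sweep.
#' @param bin_width_s bin width in seconds (default 0.020).
#' @param window_s post-stimulus window, half-open (default `c(0, 15)`).
#' @param pre_window_s length of the pre-stimulus window used for the
#'   correction; default matches the post-stimulus window length.
#' @return an object of class `psth`: `counts` (integer per bin), `breaks`,
#'   `n_sweeps`, `pre_counts` (total pre-stimulus events), `pre_window_s`,
#'   and `rel_times` (list of per-sweep latencies).
#' @export
build_psth <- function(sweep_events, stimuli, bin_width_s = 0.020,
                       window_s = c(0, 15), pre_window_s = diff(window_s)) {
  if (length(sweep_events) != length(stimuli)) {
    stop("one stimulus per sweep is required")
  }
  stim_t <- vapply(stimuli, function(s)
    if (inherits(s, "stimulus_event")) s$time_s else as.numeric(s), numeric(1))
  n_bins <- round(diff(window_s) / bin_width_s)
  breaks <- window_s[1] + bin_width_s * (0:n_bins)
  counts <- integer(n_bins)
  pre_counts <- 0L
  rel_times <- vector("list", length(sweep_events))
  for (i in seq_along(sweep_events)) {
    rel <- sweep_events[[i]]$time_s - stim_t[i]
    rel_times[[i]] <- rel
    post <- rel[rel >= window_s[1] & rel < window_s[2]]
    if (length(post)) {
      b <- pmin(n_bins, floor((post - window_s[1]) / bin_width_s) + 1L)
      tb <- tabulate(b, nbins = n_bins)
      counts <- counts + tb
    }
    pre_counts <- pre_counts + sum(rel >= -pre_window_s & rel < 0)
  }
  structure(list(counts = counts, breaks = breaks, bin_width_s = bin_width_s,
                 window_s = window_s, n_sweeps = length(sweep_events),
                 pre_counts = as.integer(pre_counts),
                 pre_window_s = pre_window_s, rel_times = rel_times),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf(
    "<psth> %d bins x %g s over [%g, %g) s, %d sweeps, %d events (%d pre-stimulus)\n",
    length(x$counts), x$bin_width_s, x$window_s[1], x$window_s[2], x$n_sweeps,
    sum(x$counts), x$pre_counts))
  invisible(x)
}

#' Quantify evoked reflex components
#'
#' Computes, from a [build_psth()] object, the monosynaptic amplitude and the
#' short-latency (SLR, 10-40 ms) and long-lasting (LLR, 0.5-15 s) reflex
#' event counts accumulated over sweeps. Raw counts are corrected for
#' spontaneous activity by subtracting the pre-stimulus event rate scaled to
#' each window's length and the number of sweeps, floored at zero:
#' `corrected = max(0, raw - pre_rate * window_len * n_sweeps)`. The
#' monosynaptic amplitude is the mean over sweeps of the peak rectified
#' amplitude inside `mono_window_s` (artifact already excluded by the
#' blanking in [detect_events()]; the window starts after it).
#'
#' @param psth a `psth`.
#' @param sweeps optional list of single-channel [recording()]s (the raw
#'   sweeps) for the monosynaptic amplitude; `NA` amplitude when omitted.
#' @param stimuli stimuli matching `sweeps` (stimulus events or times);
#'   default places every stimulus at 0.
#' @param mono_window_s monosynaptic search window, seconds post-stimulus.
#' @param slr_window_s,llr_window_s SLR and LLR count windows (half-open).
#' @return an object of class `reflex_summary` with raw and corrected SLR and
#'   LLR counts, `mono_amp`, the pre-stimulus rate, and `n_sweeps`.
#' @export
quantify_reflex <- function(psth, sweeps = NULL, stimuli = NULL,
                            mono_window_s = c(0.001, 0.010),
                            slr_window_s = c(0.010, 0.040),
                            llr_window_s = c(0.500, 15.000)) {
  stopifnot(inherits(psth, "psth"))
  rel <- unlist(psth$rel_times)
  count_in <- function(w) sum(rel >= w[1] & rel < w[2])
  raw_slr <- count_in(slr_window_s)
  raw_llr <- count_in(llr_window_s)
  corrected <- TRUE
  if (psth$pre_window_s > 0) {
    pre_rate <- psth$pre_counts / (psth$pre_window_s * psth$n_sweeps)
  } else {
    warning("no pre-stimulus data: spontaneous correction skipped")
    pre_rate <- 0
    corrected <- FALSE
  }
  corr <- function(raw, w) max(0, raw - pre_rate * diff(w) * psth$n_sweeps)
  mono_amp <- NA_real_
  if (!is.null(sweeps)) {
    if (is.null(stimuli)) stimuli <- rep(0, length(sweeps))
    stim_t <- vapply(stimuli, function(s)
      if (inherits(s, "stimulus_event")) s$time_s else as.numeric(s), numeric(1))
    peaks <- mapply(function(rec, st) {
      seg <- slice_window(rec, st + mono_window_s[1], st + mono_window_s[2])
      max(abs(get_channel(seg)))
    }, sweeps, stim_t)
    mono_amp <- mean(peaks)
  }
  structure(list(
    mono_amp = mono_amp,
    slr_count = corr(raw_slr, slr_window_s),
    llr_count = corr(raw_llr, llr_window_s),
    raw_slr = raw_slr, raw_llr = raw_llr,
    pre_rate_hz = pre_rate, corrected = corrected,
    n_sweeps = psth$n_sweeps,
    slr_window_s = slr_window_s, llr_window_s = llr_window_s),
    class = "reflex_summary")
}

#' @export
print.reflex_summary <- function(x, ...) {
  cat(sprintf(
    "<reflex> mono %.4g; SLR %.4g (raw %d); LLR %.4g (raw %d); pre-rate %.3g Hz; %d sweeps\n",
    x$mono_amp, x$slr_count, x$raw_slr, x$llr_count, x$raw_llr, x$pre_rate_hz,
    x$n_sweeps))
  invisible(x)
}

#' Stimulus threshold from an intensity series
#'
#' Lowest stimulus intensity whose reflex summary satisfies the detection
#' criterion: `"slr"` — corrected SLR count at least `min_count`; `"mono"` —
#' monosynaptic amplitude above `mono_criterion`.
#'
#' @param responses list of `list(intensity = , summary = reflex_summary)`
#'   with strictly increasing intensities.
#' @param criterion `"mono"` or `"slr"`.
#' @param mono_criterion amplitude a response must exceed under `"mono"`.
#' @param min_count minimal corrected SLR count under `"slr"`.
#' @return an object of class `threshold_result`: `threshold_intensity`
#'   (`NA` with `reached = FALSE` when no intensity responds) and
#'   `tested_intensities`.
#' @export
estimate_threshold <- function(responses, criterion = c("slr", "mono"),
                               mono_criterion = 0, min_count = 1) {
  criterion <- match.arg(criterion)
  intens <- vapply(responses, function(r) r$intensity, numeric(1))
  if (any(diff(intens) <= 0)) stop("intensities must be strictly increasing")
  hit <- vapply(responses, function(r) {
    s <- r$summary
    if (criterion == "mono") isTRUE(s$mono_amp > mono_criterion)
    else s$slr_count >= min_count
  }, logical(1))
  idx <- which(hit)[1]
  structure(list(
    threshold_intensity = if (is.na(idx)) NA_real_ else intens[idx],
    reached = !is.na(idx),
    tested_intensities = intens,
    criterion = criterion),
    class = "threshold_result")
}

#' Use-dependent decline of the long-lasting reflex
#'
#' The LLR declines when stimuli are delivered too close together; an
#' interpulse interval of several minutes is needed for full recovery.
#' Given LLR counts measured at different interpulse intervals, returns the
#' per-interval mean and its ratio to the mean at the longest interval, plus
#' a flag marking a monotone decline toward shorter intervals.
#'
#' @param series `data.frame` with columns `interval_s` and `llr_count` (or a
#'   list of `c(interval_s, llr_count)` pairs); at least 2 distinct
#'   intervals.
#' @return `data.frame` of class `use_dependence` with columns
#'   `interval_s, mean_llr, ratio`, sorted by interval, and attribute
#'   `declining`.
#' @export
assess_use_dependence <- function(series) {
  if (!is.data.frame(series)) {
    series <- do.call(rbind, lapply(series, function(p)
      data.frame(interval_s = p[[1]], llr_count = p[[2]])))
  }
  if (length(unique(series$interval_s)) < 2L) {
    stop("need LLR counts at two or more interpulse intervals")
  }
  agg <- stats::aggregate(llr_count ~ interval_s, series, mean)
  agg <- agg[order(agg$interval_s), , drop = FALSE]
  ref <- agg$llr_count[nrow(agg)]
  out <- data.frame(interval_s = agg$interval_s, mean_llr = agg$llr_count,
                    ratio = if (ref > 0) agg$llr_count / ref else NA_real_)
  rownames(out) <- NULL
  # declining = mean LLR is non-decreasing with interval and lower somewhere
  attr(out, "declining") <- all(diff(out$mean_llr) >= 0) &&
    any(out$mean_llr < ref)
  class(out) <- c("use_dependence", "data.frame")
  out
}
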