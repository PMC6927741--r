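#' Threshold-based burst detection
#'
#' Detects spontaneous ventral-root bursts on a rectified-integrated
#' [envelope()]. The threshold is `T = mean + k_sd * sd` of the supplied
#' baseline; a burst is a maximal epoch with envelope `>= T`, after merging
#' epochs separated by less than `merge_gap_s` (sub-smoothing-constant gaps
#' are treated as artifacts of the envelope) and discarding merged epochs
#' shorter than `min_dur_s`. Onset and end are the threshold crossings of the
#' envelope, not of the raw trace; peak time/amplitude are the envelope
#' maximum within the epoch. Detections are disjoint, time-ordered, and
#' invariant under joint positive scaling of signal and baseline.
#'
#' @param env an [envelope()].
#' @param base a [baseline_stats()] from the same channel.
#' @param k_sd threshold multiplier on the baseline SD (default 3, the
#'   mean-plus-three-SD rule shared with the EMG chain).
#' @param min_dur_s minimum burst duration in seconds.
#' @param merge_gap_s sub-threshold gaps shorter than this are bridged.
#' @return a `data.frame` of class `burst_table` with columns
#'   `onset_s, end_s, peak_time_s, peak_amp, channel_id`.
#' @export
detect_bursts <- function(env, base, k_sd = 3, min_dur_s = 0.05,
                          merge_gap_s = 0.2) {
  stopifnot(inherits(env, "envelope"), inherits(base, "baseline_stats"))
  if (base$sd == 0 && base$mean == 0) {
    stop("degenerate threshold: baseline mean and sd are both zero")
  }
  thr <- base$mean + k_sd * base$sd
  x <- env$samples
  rate <- env$rate_hz
  above <- x >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_i <- starts[r$values]
  off_i <- ends[r$values]
  empty <- structure(
    data.frame(onset_s = numeric(0), end_s = numeric(0),
               peak_time_s = numeric(0), peak_amp = numeric(0),
               channel_id = character(0), stringsAsFactors = FALSE),
    class = c("burst_table", "data.frame"))
  if (length(on_i) == 0L) return(empty)
  # merge epochs separated by < merge_gap_s
  if (length(on_i) > 1L) {
    gaps <- (on_i[-1L] - off_i[-length(off_i)] - 1L) / rate
    grp <- cumsum(c(1L, as.integer(gaps >= merge_gap_s)))
    on_i <- tapply(on_i, grp, min)
    off_i <- tapply(off_i, grp, max)
  }
  dur <- (off_i - on_i + 1L) / rate
  keep <- dur >= min_dur_s
  on_i <- on_i[keep]; off_i <- off_i[keep]
  if (length(on_i) == 0L) return(empty)
  peak_i <- mapply(function(i, j) i - 1L + which.max(x[i:j]), on_i, off_i)
  out <- data.frame(
    onset_s = env$t0_s + (on_i - 1L) / rate,
    end_s = env$t0_s + off_i / rate,           # half-open right edge
    peak_time_s = env$t0_s + peak_i / rate,
    peak_amp = x[peak_i],
    channel_id = env$source_channel,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("burst_table", "data.frame")
  out
}

#' Summarize detected bursts
#'
#' Frequency (events/min), amplitude and duration summaries of a burst table,
#' matching the per-preparation quantities reported for spontaneous
#' ventral-root activity. An empty table yields zero counts with `NA` means
#' and `empty = TRUE`.
#'
#' @param bursts a `burst_table` from [detect_bursts()].
#' @param duration_s recording span in seconds the bursts were detected over.
#' @return an object of class `burst_summary`.
#' @export
summarize_bursts <- function(bursts, duration_s) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  n <- nrow(bursts)
  durs <- bursts$end_s - bursts$onset_s
  structure(list(
    n_bursts = n,
    frequency_per_min = n / (duration_s / 60),
    mean_amp = if (n) mean(bursts$peak_amp) else NA_real_,
    sd_amp = if (n > 1L) stats::sd(bursts$peak_amp) else if (n) 0 else NA_real_,
    mean_duration_s = if (n) mean(durs) else NA_real_,
    sd_duration_s = if (n > 1L) stats::sd(durs) else if (n) 0 else NA_real_,
    duration_s = duration_s,
    empty = n == 0L),
    class = "burst_summary")
}

#' @export
print.burst_summary <- function(x, ...) {
  cat(sprintf(
    "<burst summary> n = %d (%.3g/min); amp %.4g +/- %.3g; duration %.3g +/- %.3g s\n",
    x$n_bursts, x$frequency_per_min, x$mean_amp, x$sd_amp,
    x$mean_duration_s, x$sd_duration_s))
  invisible(x)
}
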