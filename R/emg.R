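#' EMG response duration
#'
#' Duration of a motor response measured from the rectified, 8 Hz low-pass
#' filtered EMG envelope: the response lasts as long as the envelope exceeds
#' a threshold set to the mean plus `k_sd` times the standard deviation of
#' the envelope during a period of inactivity. By default the duration sums
#' all supra-threshold epochs between the first onset and the last offset
#' (long-lasting responses can be interrupted); `mode = "span"` returns the
#' first-onset-to-last-offset span instead.
#'
#' @param rec a [recording()] holding the EMG channel.
#' @param channel EMG channel label or index.
#' @param baseline_window `c(start_s, stop_s)` of pre-response inactivity, or
#'   `"auto"` for the minimal-RMS window.
#' @param k_sd threshold multiplier (default 3).
#' @param cutoff_hz envelope low-pass corner (default 8 Hz).
#' @param mode `"total"` (sum of supra-threshold time) or `"span"`.
#' @return an object of class `emg_result`: `duration_s`, `onset_s`,
#'   `offset_s`, `threshold_used`, `responded`.
#' @export
emg_response_duration <- function(rec, channel = NULL,
                                  baseline_window = "auto", k_sd = 3,
                                  cutoff_hz = 8, mode = c("total", "span")) {
  mode <- match.arg(mode)
  env_rec <- lowpass(rectify(rec, channel), cutoff_hz = cutoff_hz)
  env <- structure(list(samples = pmax(get_channel(env_rec), 0),
                        rate_hz = env_rec$rate_hz, t0_s = env_rec$t0_s,
                        tau_s = NA_real_,
                        source_channel = env_rec$channel_ids[1],
                        method = "lowpass"),
                   class = "envelope")
  base <- baseline_stats(env, window = baseline_window)
  thr <- base$mean + k_sd * base$sd
  above <- env$samples > thr
  # ignore the baseline window itself when locating the response
  tt <- env$t0_s + (seq_along(env$samples) - 1L) / env$rate_hz
  above[tt >= base$window[1] & tt < base$window[2]] <- FALSE
  if (!any(above)) {
    return(structure(list(duration_s = 0, onset_s = NA_real_,
                          offset_s = NA_real_, threshold_used = thr,
                          responded = FALSE, mode = mode),
                     class = "emg_result"))
  }
  i_on <- which(above)[1]
  i_off <- which(above)[length(which(above))]
  onset <- tt[i_on]
  offset <- tt[i_off] + 1 / env$rate_hz
  dur <- if (mode == "total") sum(above) / env$rate_hz else offset - onset
  structure(list(duration_s = dur, onset_s = onset, offset_s = offset,
                 threshold_used = thr, responded = TRUE, mode = mode),
            class = "emg_result")
}

#' @export
print.emg_result <- function(x, ...) {
  if (x$responded) {
    cat(sprintf("<EMG> response %.3f s (onset %.3f s, offset %.3f s; threshold %.4g)\n",
                x$duration_s, x$onset_s, x$offset_s, x$threshold_used))
  } else {
    cat("<EMG> no supra-threshold response\n")
  }
  invisible(x)
}

#' Mechanical stimulation threshold
#'
#' Minimal pressure (weight in grams) applied to the tail that evokes an EMG
#' response: the smallest tested pressure whose [emg_response_duration()]
#' result has positive duration.
#'
#' @param trials `data.frame` with columns `pressure_g` and `duration_s`
#'   (sorted by strictly increasing pressure), or a list of
#'   `list(pressure_g =, result = emg_result)`.
#' @return an object of class `threshold_result` with the threshold pressure,
#'   a `reached` flag, and the tested pressures.
#' @export
mechanical_threshold <- function(trials) {
  if (!is.data.frame(trials)) {
    trials <- data.frame(
      pressure_g = vapply(trials, function(t) t$pressure_g, numeric(1)),
      duration_s = vapply(trials, function(t) t$result$duration_s, numeric(1)))
  }
  if (any(diff(trials$pressure_g) <= 0)) {
    stop("trials must be sorted by strictly increasing pressure")
  }
  idx <- which(trials$duration_s > 0)[1]
  structure(list(
    threshold_intensity = if (is.na(idx)) NA_real_ else trials$pressure_g[idx],
    reached = !is.na(idx),
    tested_intensities = trials$pressure_g,
    criterion = "emg"),
    class = "threshold_result")
}

#' Count myoclonic twitches with the coincidence rule
#'
#' Scores twitch events over an observation window (the standard session is a
#' continuous 10 min recording). Simultaneous twitching of any hindlimb(s)
#' with the tail is scored as a single twitch: events across channels falling
#' within `coincidence_s` of each other are merged transitively into one
#' cluster, and each cluster counts once, at the time of its earliest event.
#'
#' @param events an [event_table()] with channel ids such as
#'   `"hindlimb-left"`, `"hindlimb-right"`, `"tail"`.
#' @param window `c(start_s, stop_s)` observation window (default 10 min).
#' @param coincidence_s events closer than this are "simultaneous".
#' @param bin_s optional bin width for a within-window time course of counts.
#' @return an object of class `twitch_count`: `n_twitches`, `window`,
#'   `times` (one representative time per merged twitch), and `bin_counts`
#'   when `bin_s` is given.
#' @export
count_twitches <- function(events, window = c(0, 600), coincidence_s = 0.1,
                           bin_s = NULL) {
  tt <- sort(events$time_s)
  if (length(tt) == 0L) {
    reps <- numeric(0)
  } else {
    grp <- cumsum(c(1L, as.integer(diff(tt) >= coincidence_s)))
    reps <- as.numeric(tapply(tt, grp, min))
  }
  reps <- reps[reps >= window[1] & reps < window[2]]
  bin_counts <- NULL
  if (!is.null(bin_s)) {
    breaks <- seq(window[1], window[2], by = bin_s)
    if (breaks[length(breaks)] < window[2]) breaks <- c(breaks, window[2])
    bin_counts <- data.frame(
      bin_start_s = breaks[-length(breaks)],
      count = as.integer(table(cut(reps, breaks, right = FALSE))))
  }
  structure(list(n_twitches = length(reps), window = window,
                 times = reps, bin_counts = bin_counts,
                 coincidence_s = coincidence_s),
            class = "twitch_count")
}

#' @export
print.twitch_count <- function(x, ...) {
  cat(sprintf("<twitches> %d over [%g, %g) s (coincidence window %g s)\n",
              x$n_twitches, x$window[1], x$window[2], x$coincidence_s))
  invisible(x)
}

#' Hourly twitch time course
#'
#' Descriptive per-hour summary (mean +/- SD, n) of twitch counts across
#' sessions, as used to track spasm frequency hour by hour after a
#' treatment.
#'
#' @param sessions `data.frame` with columns `t_hours` and `n_twitches` (one
#'   row per session), or a list of `list(t_hours =, count = twitch_count)`.
#' @return `data.frame` with columns `t_hours, mean, sd, n`, sorted by time.
#' @export
twitch_timecourse <- function(sessions) {
  if (!is.data.frame(sessions)) {
    sessions <- data.frame(
      t_hours = vapply(sessions, function(s) s$t_hours, numeric(1)),
      n_twitches = vapply(sessions, function(s) s$count$n_twitches, numeric(1)))
  }
  if (nrow(sessions) == 0L) stop("no sessions supplied")
  out <- do.call(rbind, lapply(split(sessions, sessions$t_hours), function(d) {
    data.frame(t_hours = d$t_hours[1], mean = mean(d$n_twitches),
               sd = if (nrow(d) > 1L) stats::sd(d$n_twitches) else 0,
               n = nrow(d))
  }))
  out <- out[order(out$t_hours), , drop = FALSE]
  rownames(out) <- NULL
  out
}
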