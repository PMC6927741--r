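# All generators draw from one explicit per-config seed and restore the
# caller's RNG state, so equal configs give bit-identical output and no
# global state leaks.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

# white or 1/f (pink) Gaussian noise with the requested SD
make_noise <- function(n, sd, kind = c("white", "pink")) {
  kind <- match.arg(kind)
  if (sd == 0) return(numeric(n))
  if (kind == "white") return(stats::rnorm(n, sd = sd))
  # spectrally shaped white noise: amplitude ~ 1/sqrt(f)
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                      # symmetric frequency index
  sp <- sp / sqrt(f)
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  x / stats::sd(x) * sd
}

#' Ventral-root simulation configuration
#'
#' Parameters of the spontaneous-activity generator: Poisson-timed bursts
#' riding on baseline noise. Bursts are modeled as multiplicative
#' noise-amplitude envelopes (a Hann window scaling the carrier noise up to
#' `amp` times its baseline SD), matching the look of rectified multiunit
#' activity — detection operates on envelopes, so carrier detail is
#' irrelevant.
#'
#' @param duration_s recording length in seconds.
#' @param rate_hz sampling rate (default 10 kHz, the ventral-root
#'   acquisition rate).
#' @param burst_rate_per_min Poisson rate of spontaneous bursts.
#' @param burst_amp_range `c(lo, hi)` burst amplitude in multiples of the
#'   baseline noise SD.
#' @param burst_dur_range_s `c(lo, hi)` burst duration in seconds.
#' @param baseline_sd baseline noise SD in signal units.
#' @param noise_kind `"white"` or `"pink"`.
#' @param seed integer RNG seed.
#' @return a validated config object.
#' @export
ventral_root_sim_config <- function(duration_s = 600, rate_hz = 10000,
                                    burst_rate_per_min = 2,
                                    burst_amp_range = c(8, 8),
                                    burst_dur_range_s = c(1, 2),
                                    baseline_sd = 1,
                                    noise_kind = c("white", "pink"),
                                    seed = 1L) {
  noise_kind <- match.arg(noise_kind)
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (burst_rate_per_min < 0) stop("burst_rate_per_min must be >= 0")
  stopifnot(burst_amp_range[1] <= burst_amp_range[2],
            burst_dur_range_s[1] <= burst_dur_range_s[2])
  structure(as.list(environment()), class = "ventral_root_sim_config")
}

#' Generate a synthetic spontaneous ventral-root recording
#'
#' Draws a Poisson number of bursts (`burst_rate_per_min x duration_min`),
#' places them uniformly with a 0.5 s separation guard (overlapping draws are
#' dropped and the annotation reflects what was actually placed), and
#' returns the recording together with a ground-truth [event_table()]:
#' one `"burst_onset"` row per burst (`value` = duration in seconds) and one
#' `"burst_peak"` row at the envelope-peak time (`value` = peak amplitude
#' multiplier).
#'
#' @param cfg a [ventral_root_sim_config()].
#' @return `list(recording, events, config)`.
#' @export
generate_ventral_root <- function(cfg) {
  stopifnot(inherits(cfg, "ventral_root_sim_config"))
  with_seed(cfg$seed, {
    n <- round(cfg$duration_s * cfg$rate_hz)
    noise <- make_noise(n, cfg$baseline_sd, cfg$noise_kind)
    n_bursts <- stats::rpois(1, cfg$burst_rate_per_min * cfg$duration_s / 60)
    onsets <- durs <- amps <- numeric(0)
    if (n_bursts > 0) {
      durs <- stats::runif(n_bursts, cfg$burst_dur_range_s[1],
                           cfg$burst_dur_range_s[2])
      lo <- 1
      hi <- pmax(lo, cfg$duration_s - durs - 1)
      onsets <- stats::runif(n_bursts, lo, hi)
      o <- order(onsets)
      onsets <- onsets[o]; durs <- durs[o]
      amps <- stats::runif(n_bursts, cfg$burst_amp_range[1],
                           cfg$burst_amp_range[2])
      keep <- logical(n_bursts)
      last_end <- -Inf
      for (i in seq_len(n_bursts)) {
        if (onsets[i] >= last_end + 0.5) {
          keep[i] <- TRUE
          last_end <- onsets[i] + durs[i]
        }
      }
      onsets <- onsets[keep]; durs <- durs[keep]; amps <- amps[keep]
    }
    mult <- rep(1, n)
    for (i in seq_along(onsets)) {
      i0 <- max(1L, round(onsets[i] * cfg$rate_hz) + 1L)
      i1 <- min(n, round((onsets[i] + durs[i]) * cfg$rate_hz))
      w <- i1 - i0 + 1L
      # fast attack, plateau, slower release: multiunit bursts switch on
      # abruptly and wane gradually
      ta <- min(round(0.05 * cfg$rate_hz), w %/% 4)
      tr <- min(round(0.25 * cfg$rate_hz), w %/% 4)
      shape <- rep(1, w)
      if (ta > 0) shape[1:ta] <- sin(pi * (1:ta) / (2 * ta))^2
      if (tr > 0) shape[(w - tr + 1L):w] <- cos(pi * (1:tr) / (2 * tr))^2
      mult[i0:i1] <- mult[i0:i1] + (amps[i] - 1) * shape
    }
    rec <- recording(noise * mult, cfg$rate_hz, "VR-L5",
                     meta = list(sim = "ventral_root", seed = cfg$seed))
    events <- event_table(
      time_s = c(onsets, onsets + durs / 2),
      channel_id = "VR-L5",
      label = rep(c("burst_onset", "burst_peak"), each = length(onsets)),
      value = c(durs, amps))
    list(recording = rec, events = events, config = cfg)
  })
}

#' Evoked-sweep simulation configuration
#'
#' Parameters of the dorsal-root-evoked sweep generator: each sweep spans
#' `[-pre_window_s, 15)` s around its stimulus and contains a 1 ms biphasic
#' artifact at time 0, a monosynaptic spike, a deterministic set of
#' short-latency (SLR) spikes in the 10-40 ms window, Poisson long-lasting
#' reflex (LLR) events over 0.5-15 s, and Poisson spontaneous events before
#' the stimulus. Spike and artifact amplitudes are in absolute signal units.
#' The default baseline is silent (`baseline_sd = 0`): the fixed mean+3SD
#' peak-detection rule presumes a baseline whose excursions rarely reach
#' threshold, a property full-bandwidth Gaussian noise does not have, so the
#' standard fixture models the evidence (discrete spikes) rather than the
#' carrier noise. Additive noise remains available for robustness checks.
#'
#' @param n_sweeps consecutive sweeps per preparation (default 5).
#' @param rate_hz sampling rate.
#' @param pre_window_s pre-stimulus span per sweep.
#' @param artifact_amp stimulus-artifact amplitude (signal units).
#' @param artifact_blank_s analysis blanking after the stimulus; the
#'   monosynaptic latency must exceed it.
#' @param mono_latency_s,mono_amp monosynaptic spike latency and amplitude.
#' @param slr_spikes list of `c(latency_s, amp)` with latencies in
#'   `[0.010, 0.040)`.
#' @param llr_rate_hz Poisson event rate over the 0.5-15 s window.
#' @param llr_amp LLR spike amplitude.
#' @param pre_rate_hz spontaneous event rate before the stimulus.
#' @param baseline_sd baseline noise SD.
#' @param seed integer RNG seed.
#' @return a validated config object.
#' @export
evoked_sim_config <- function(n_sweeps = 5L, rate_hz = 10000,
                              pre_window_s = 15, artifact_amp = 20,
                              artifact_blank_s = 0.002,
                              mono_latency_s = 0.003, mono_amp = 10,
                              slr_spikes = list(c(0.015, 8), c(0.025, 8),
                                                c(0.035, 8)),
                              llr_rate_hz = 0, llr_amp = 8,
                              pre_rate_hz = 0, baseline_sd = 0, seed = 1L) {
  if (mono_latency_s <= artifact_blank_s) {
    stop("monosynaptic spike would fall inside the artifact blanking window")
  }
  for (s in slr_spikes) {
    if (s[1] < 0.010 || s[1] >= 0.040) {
      stop("SLR spike latencies must lie in [0.010, 0.040) s")
    }
  }
  if (llr_rate_hz < 0 || pre_rate_hz < 0) stop("event rates must be >= 0")
  structure(as.list(environment()), class = "evoked_sim_config")
}

# add a half-sine spike of the given width, centered so its peak falls at
# latency t (s): ground-truth latencies are peak times, matching the peak
# detector's event semantics
add_spike <- function(x, rate_hz, t0_s, t, amp, width_s = 0.001) {
  w <- max(2L, round(width_s * rate_hz))
  i0 <- round((t - t0_s) * rate_hz) + 1L - w %/% 2L
  idx <- i0:(i0 + w - 1L)
  ok <- idx >= 1L & idx <= length(x)
  x[idx[ok]] <- x[idx[ok]] + amp * sin(pi * (seq_len(w)[ok] - 0.5) / w)
  x
}

#' Generate stimulus-locked evoked sweeps
#'
#' @param cfg an [evoked_sim_config()].
#' @return `list(sweeps, stimuli, truth, config)`: single-channel
#'   [recording()]s with `t0_s = -pre_window_s` (stimulus at 0), one
#'   [stimulus_event()] per sweep, and a ground-truth [event_table()] whose
#'   rows give each inserted spike's latency, window label
#'   (`mono`/`slr`/`llr`/`spont`) and sweep index (`value`).
#' @export
generate_evoked_sweeps <- function(cfg) {
  stopifnot(inherits(cfg, "evoked_sim_config"))
  with_seed(cfg$seed, {
    t0 <- -cfg$pre_window_s
    n <- round((cfg$pre_window_s + 15) * cfg$rate_hz)
    sweeps <- vector("list", cfg$n_sweeps)
    truth_t <- truth_lab <- truth_sweep <- list()
    for (k in seq_len(cfg$n_sweeps)) {
      x <- if (cfg$baseline_sd > 0) stats::rnorm(n, sd = cfg$baseline_sd)
           else numeric(n)
      # 1 ms biphasic artifact at t = 0
      a <- cfg$artifact_amp
      half <- max(1L, round(0.0005 * cfg$rate_hz))
      i0 <- round(-t0 * cfg$rate_hz) + 1L
      x[i0:(i0 + half - 1L)] <- x[i0:(i0 + half - 1L)] + a
      x[(i0 + half):(i0 + 2L * half - 1L)] <-
        x[(i0 + half):(i0 + 2L * half - 1L)] - a
      ev_t <- cfg$mono_latency_s
      ev_l <- "mono"
      for (s in cfg$slr_spikes) {
        ev_t <- c(ev_t, s[1]); ev_l <- c(ev_l, "slr")
      }
      slr_amp <- vapply(cfg$slr_spikes, `[`, numeric(1), 2)
      n_llr <- stats::rpois(1, cfg$llr_rate_hz * 14.5)
      if (n_llr > 0) {
        t_llr <- sort(stats::runif(n_llr, 0.5, 15))
        ev_t <- c(ev_t, t_llr); ev_l <- c(ev_l, rep("llr", n_llr))
      }
      n_pre <- stats::rpois(1, cfg$pre_rate_hz * cfg$pre_window_s)
      if (n_pre > 0) {
        t_pre <- sort(stats::runif(n_pre, t0, 0))
        ev_t <- c(ev_t, t_pre); ev_l <- c(ev_l, rep("spont", n_pre))
      }
      amp_of <- c(mono = cfg$mono_amp, llr = cfg$llr_amp,
                  spont = cfg$llr_amp)
      for (j in seq_along(ev_t)) {
        amp <- if (ev_l[j] == "slr") slr_amp[sum(ev_l[seq_len(j)] == "slr")]
               else amp_of[[ev_l[j]]]
        x <- add_spike(x, cfg$rate_hz, t0, ev_t[j], amp)
      }
      sweeps[[k]] <- recording(x, cfg$rate_hz, "VR-L5", t0_s = t0,
                               meta = list(sim = "evoked", sweep = k))
      truth_t[[k]] <- ev_t
      truth_lab[[k]] <- ev_l
      truth_sweep[[k]] <- rep(k, length(ev_t))
    }
    truth <- event_table(time_s = unlist(truth_t), channel_id = "VR-L5",
                         label = unlist(truth_lab),
                         value = unlist(truth_sweep))
    stimuli <- replicate(cfg$n_sweeps, stimulus_event(0, intensity = 1),
                         simplify = FALSE)
    list(sweeps = sweeps, stimuli = stimuli, truth = truth, config = cfg)
  })
}

#' Left/right coupling simulation configuration
#'
#' @param mode `"synchronous"` (identical burst phase), `"alternating"`
#'   (half-period phase shift, the fictive-locomotion pattern), or
#'   `"independent"` (two separate smoothed random processes).
#' @param cycle_period_s locomotor cycle period in seconds.
#' @param duty burst duty cycle in (0, 1); at the default 0.5 the envelope is
#'   a pure sinusoid, so noiseless synchronous/alternating pairs have exact
#'   zero-lag correlation +1/-1.
#' @param noise_sd additive white noise SD on each channel.
#' @param duration_s,rate_hz length and rate; the default 1 kHz reflects that
#'   these are envelope-scale signals.
#' @param seed integer RNG seed.
#' @return a validated config object.
#' @export
coupling_sim_config <- function(mode = c("synchronous", "alternating",
                                         "independent"),
                                cycle_period_s = 2, duty = 0.5,
                                noise_sd = 0, duration_s = 30,
                                rate_hz = 1000, seed = 1L) {
  mode <- match.arg(mode)
  if (cycle_period_s <= 0) stop("cycle_period_s must be > 0")
  if (duty <= 0 || duty >= 1) stop("duty must lie in (0, 1)")
  structure(as.list(environment()), class = "coupling_sim_config")
}

#' Generate a coupled left/right ventral-root pair
#'
#' @param cfg a [coupling_sim_config()].
#' @return a 2-channel [recording()] (`"VR-L5-left"`, `"VR-L5-right"`) of
#'   envelope-scale signals.
#' @export
generate_coupled_pair <- function(cfg) {
  stopifnot(inherits(cfg, "coupling_sim_config"))
  with_seed(cfg$seed, {
    n <- round(cfg$duration_s * cfg$rate_hz)
    tt <- (seq_len(n) - 1L) / cfg$rate_hz
    env_at <- function(phase_shift) {
      frac <- (tt / cfg$cycle_period_s + phase_shift) %% 1
      if (cfg$duty == 0.5) {
        (1 + sin(2 * pi * frac)) / 2
      } else {
        ifelse(frac < cfg$duty, sin(pi * frac / cfg$duty)^2, 0)
      }
    }
    if (cfg$mode == "independent") {
      smooth_noise <- function() {
        tau <- cfg$cycle_period_s / 8
        a <- exp(-1 / (cfg$rate_hz * tau))
        z <- as.numeric(stats::filter((1 - a) * stats::rnorm(n), a,
                                      method = "recursive"))
        (z - mean(z)) / stats::sd(z) * 0.3 + 0.5
      }
      left <- smooth_noise(); right <- smooth_noise()
    } else {
      left <- env_at(0)
      right <- if (cfg$mode == "synchronous") env_at(0) else env_at(0.5)
    }
    if (cfg$noise_sd > 0) {
      left <- left + stats::rnorm(n, sd = cfg$noise_sd)
      right <- right + stats::rnorm(n, sd = cfg$noise_sd)
    }
    recording(rbind(left, right), cfg$rate_hz,
              c("VR-L5-left", "VR-L5-right"),
              meta = list(sim = "coupling", mode = cfg$mode, seed = cfg$seed))
  })
}

#' IPSP-series simulation configuration
#'
#' @param true_eipsp_mv ground-truth reversal potential.
#' @param slope_mv_per_mv slope of the amplitude-voltage line (mV of IPSP per
#'   mV of holding potential); 0 produces an unidentifiable series.
#' @param v_rest_mv resting potential attached to the series.
#' @param holding_range_mv `c(lo, hi)` span of holding potentials; must
#'   bracket `true_eipsp_mv` so the x-intercept is interpolated, not
#'   extrapolated.
#' @param n_points number of (holding, amplitude) pairs (conventionally
#'   at least 22).
#' @param noise_sd_mv additive Gaussian noise on the amplitudes.
#' @param seed integer RNG seed.
#' @return a validated config object.
#' @export
ipsp_sim_config <- function(true_eipsp_mv = -58, slope_mv_per_mv = -0.5,
                            v_rest_mv = -65, holding_range_mv = c(-90, -40),
                            n_points = 22L, noise_sd_mv = 0.5, seed = 1L) {
  if (n_points < 2L) stop("n_points must be >= 2")
  if (true_eipsp_mv < holding_range_mv[1] ||
      true_eipsp_mv > holding_range_mv[2]) {
    stop("holding range must span true_eipsp_mv")
  }
  structure(as.list(environment()), class = "ipsp_sim_config")
}

#' Generate a synthetic IPSP amplitude-voltage series
#'
#' Amplitudes follow `slope * (V - true_eipsp) + noise` at evenly spaced
#' holding potentials.
#'
#' @param cfg an [ipsp_sim_config()].
#' @return an [ipsp_series()]; the generating config is attached as
#'   attribute `"config"`.
#' @export
generate_ipsp_series <- function(cfg) {
  stopifnot(inherits(cfg, "ipsp_sim_config"))
  with_seed(cfg$seed, {
    v <- seq(cfg$holding_range_mv[1], cfg$holding_range_mv[2],
             length.out = cfg$n_points)
    a <- cfg$slope_mv_per_mv * (v - cfg$true_eipsp_mv) +
      stats::rnorm(cfg$n_points, sd = cfg$noise_sd_mv)
    out <- ipsp_series(v, a, v_rest_mv = cfg$v_rest_mv)
    attr(out, "config") <- cfg
    out
  })
}

#' Ramp simulation configuration
#'
#' Synthetic stand-in for the persistent-sodium ramp protocol: a linear
#' voltage command (default 12 mV/s from -70 to -10 mV over 5 s) with current
#' `g_leak*(V - e_leak) + g_nap*m(V)*(V - e_na) + noise`, where
#' `m(V) = 1/(1 + exp(-(V - v_half)/k))` is the steady-state Boltzmann
#' activation. Conductances in nS, voltages in mV, currents in pA.
#'
#' @param v_start_mv,v_stop_mv ramp bounds.
#' @param ramp_rate_mv_per_s command slope.
#' @param rate_hz sampling rate.
#' @param g_leak_ns,e_leak_mv leak conductance and reversal.
#' @param g_nap_ns persistent-sodium maximal conductance.
#' @param v_half_mv,k_mv Boltzmann half-activation and slope factor
#'   (`k_mv > 0`).
#' @param e_na_mv sodium reversal potential.
#' @param noise_sd_pa additive current noise SD.
#' @param seed integer RNG seed.
#' @return a validated config object.
#' @export
ramp_sim_config <- function(v_start_mv = -70, v_stop_mv = -10,
                            ramp_rate_mv_per_s = 12, rate_hz = 10000,
                            g_leak_ns = 10, e_leak_mv = -70, g_nap_ns = 1,
                            v_half_mv = -45, k_mv = 5, e_na_mv = 60,
                            noise_sd_pa = 0, seed = 1L) {
  if (v_start_mv >= v_stop_mv) stop("v_start_mv must be below v_stop_mv")
  if (k_mv <= 0) stop("k_mv must be > 0")
  if (g_leak_ns < 0 || g_nap_ns < 0) stop("conductances must be >= 0")
  structure(as.list(environment()), class = "ramp_sim_config")
}

# analytic non-leak ramp current and its dense-grid ground truth
nap_current <- function(v, cfg) {
  m <- 1 / (1 + exp(-(v - cfg$v_half_mv) / cfg$k_mv))
  cfg$g_nap_ns * m * (v - cfg$e_na_mv)
}

ramp_ground_truth <- function(cfg, grid_mv = 0.01) {
  v <- seq(cfg$v_start_mv, cfg$v_stop_mv, by = grid_mv)
  f <- nap_current(v, cfg)
  peak <- abs(min(f))
  d <- diff(f) / grid_mv
  idx <- which(d < 0)[1]
  list(peak_pa = peak,
       v_threshold_mv = if (is.na(idx)) NA_real_ else v[idx])
}

#' Generate a synthetic voltage-ramp trace
#'
#' @param cfg a [ramp_sim_config()].
#' @return a [ramp_trace()] whose `truth` field holds the analytic
#'   leak-free peak amplitude and activation threshold evaluated on a
#'   0.01 mV grid.
#' @export
generate_ramp <- function(cfg) {
  stopifnot(inherits(cfg, "ramp_sim_config"))
  with_seed(cfg$seed, {
    dv <- cfg$ramp_rate_mv_per_s / cfg$rate_hz
    v <- seq(cfg$v_start_mv, cfg$v_stop_mv, by = dv)
    i <- cfg$g_leak_ns * (v - cfg$e_leak_mv) + nap_current(v, cfg) +
      stats::rnorm(length(v), sd = cfg$noise_sd_pa)
    ramp_trace(v, i, cfg$rate_hz, truth = c(ramp_ground_truth(cfg),
                                            list(config = cfg)))
  })
}

#' EMG / twitch simulation configuration
#'
#' @param duration_s observation length (default the standard 10 min
#'   session).
#' @param rate_hz EMG sampling rate (default 13.5 kHz, the in vivo
#'   acquisition rate).
#' @param baseline_sd EMG baseline noise SD.
#' @param bursts `data.frame` with columns `onset_s, duration_s, amp_mult`
#'   describing EMG response bursts (rectangular noise-amplitude
#'   modulation).
#' @param n_hindlimb,n_tail counts of isolated hindlimb / tail twitch
#'   events.
#' @param n_coincident number of hindlimb+tail pairs separated by
#'   `coincidence_offset_s` (each pair scores as a single twitch).
#' @param coincidence_offset_s within-pair separation.
#' @param seed integer RNG seed.
#' @return a validated config object.
#' @export
emg_sim_config <- function(duration_s = 600, rate_hz = 13500,
                           baseline_sd = 1,
                           bursts = data.frame(onset_s = numeric(0),
                                               duration_s = numeric(0),
                                               amp_mult = numeric(0)),
                           n_hindlimb = 0L, n_tail = 0L, n_coincident = 0L,
                           coincidence_offset_s = 0.05, seed = 1L) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (nrow(bursts) && any(bursts$onset_s + bursts$duration_s > duration_s)) {
    stop("a burst extends past the end of the recording")
  }
  n_slots <- length(seq(1, duration_s - 1, by = 2))
  if (n_hindlimb + n_tail + n_coincident > n_slots) {
    stop("too many twitch events for the recording length")
  }
  structure(as.list(environment()), class = "emg_sim_config")
}

#' Generate a synthetic EMG trace and twitch event train
#'
#' The EMG channel is baseline noise with rectangular amplitude modulation
#' during each configured burst. Twitch events are placed on a 2 s grid
#' (guaranteeing isolated events never fall within one coincidence window of
#' each other) across channels `"hindlimb-left"`, `"hindlimb-right"` and
#' `"tail"`; coincident pairs put a hindlimb and a tail event
#' `coincidence_offset_s` apart.
#'
#' @param cfg an [emg_sim_config()].
#' @return `list(recording, events, truth_n_twitches, config)`; the ground
#'   truth count scores each coincident pair once.
#' @export
generate_emg_and_twitches <- function(cfg) {
  stopifnot(inherits(cfg, "emg_sim_config"))
  with_seed(cfg$seed, {
    n <- round(cfg$duration_s * cfg$rate_hz)
    x <- stats::rnorm(n, sd = cfg$baseline_sd)
    if (nrow(cfg$bursts)) {
      for (i in seq_len(nrow(cfg$bursts))) {
        i0 <- round(cfg$bursts$onset_s[i] * cfg$rate_hz) + 1L
        i1 <- min(n, round((cfg$bursts$onset_s[i] +
                              cfg$bursts$duration_s[i]) * cfg$rate_hz))
        x[i0:i1] <- x[i0:i1] * cfg$bursts$amp_mult[i]
      }
    }
    rec <- recording(x, cfg$rate_hz, "EMG-triceps",
                     meta = list(sim = "emg", seed = cfg$seed))
    slots <- seq(1, cfg$duration_s - 1, by = 2)
    n_ev <- cfg$n_hindlimb + cfg$n_tail + cfg$n_coincident
    times <- ch <- lab <- val <- c()
    if (n_ev > 0) {
      picked <- sort(sample(slots, n_ev))
      picked <- picked + stats::runif(n_ev, 0, 0.5)
      kinds <- sample(rep(c("h", "t", "c"),
                          c(cfg$n_hindlimb, cfg$n_tail, cfg$n_coincident)))
      side <- c("hindlimb-left", "hindlimb-right")
      for (i in seq_len(n_ev)) {
        if (kinds[i] == "h") {
          times <- c(times, picked[i])
          ch <- c(ch, side[1 + i %% 2]); lab <- c(lab, "twitch")
          val <- c(val, 1)
        } else if (kinds[i] == "t") {
          times <- c(times, picked[i])
          ch <- c(ch, "tail"); lab <- c(lab, "twitch"); val <- c(val, 1)
        } else {
          times <- c(times, picked[i], picked[i] + cfg$coincidence_offset_s)
          ch <- c(ch, side[1 + i %% 2], "tail")
          lab <- c(lab, "twitch", "twitch"); val <- c(val, 2, 2)
        }
      }
    }
    events <- event_table(time_s = times, channel_id = ch, label = lab,
                          value = val)
    list(recording = rec, events = events,
         truth_n_twitches = n_ev, config = cfg)
  })
}

#' Write a simulation to disk
#'
#' Writes the pieces of a generator's output — recording(s), ground-truth
#' event table, and a YAML echo of the generating config — to a directory,
#' using the core I/O formats.
#'
#' @param sim output of one of the `generate_*()` functions.
#' @param dir output directory (created if needed).
#' @param format recording format, `"csv"` or `"container"`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, format = c("csv", "container")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "csv") "csv" else "rds"
  cfg <- NULL
  if (inherits(sim, "recording")) {
    write_recording(sim, file.path(dir, paste0("recording.", ext)), format)
    cfg <- sim$meta
  } else if (is.list(sim)) {
    cfg <- sim$config
    if (!is.null(sim$recording)) {
      write_recording(sim$recording,
                      file.path(dir, paste0("recording.", ext)), format)
    }
    if (!is.null(sim$sweeps)) {
      for (k in seq_along(sim$sweeps)) {
        write_recording(sim$sweeps[[k]],
                        file.path(dir, sprintf("sweep_%02d.%s", k, ext)),
                        format)
      }
    }
    truth <- if (!is.null(sim$events)) sim$events else sim$truth
    if (!is.null(truth)) write_events(truth, file.path(dir, "truth.csv"))
  }
  if (!is.null(cfg)) {
    plain <- lapply(unclass(cfg), function(v)
      if (is.data.frame(v)) as.list(v) else v)
    yaml::write_yaml(plain, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
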