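# shared fixtures, built in code at test time

# short spontaneous ventral-root fixture (full-length runs live in the
# acceptance suite)
vr_fixture <- function(seed, duration_s = 120) {
  generate_ventral_root(ventral_root_sim_config(duration_s = duration_s,
                                                seed = seed))
}

# deterministic evoked fixture: 3 SLR spikes x n sweeps, silent elsewhere
evoked_deterministic <- function(seed = 1, n_sweeps = 5L) {
  generate_evoked_sweeps(evoked_sim_config(n_sweeps = n_sweeps, seed = seed))
}

burst_onsets <- function(sim) {
  sim$events$time_s[sim$events$label == "burst_onset"]
}

reflex_from_sim <- function(sim, ...) {
  tabs <- lapply(sim$sweeps, detect_events)
  psth <- build_psth(tabs, sim$stimuli)
  quantify_reflex(psth, sweeps = sim$sweeps, ...)
}

true_leak <- function(cfg = ramp_sim_config()) {
  list(g_leak_ns = cfg$g_leak_ns, e_leak_mv = cfg$e_leak_mv)
}
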