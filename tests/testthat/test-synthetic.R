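test_that("generators are deterministic under a fixed seed", {
  cfg <- ventral_root_sim_config(duration_s = 10, seed = 5)
  expect_identical(generate_ventral_root(cfg), generate_ventral_root(cfg))
  rcfg <- ramp_sim_config(noise_sd_pa = 5, seed = 9)
  expect_identical(generate_ramp(rcfg), generate_ramp(rcfg))
  ccfg <- coupling_sim_config("independent", duration_s = 5, seed = 3)
  expect_identical(generate_coupled_pair(ccfg), generate_coupled_pair(ccfg))
  ecfg <- emg_sim_config(duration_s = 20, n_hindlimb = 2, seed = 4)
  expect_identical(generate_emg_and_twitches(ecfg),
                   generate_emg_and_twitches(ecfg))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(generate_ventral_root(
    ventral_root_sim_config(duration_s = 5, seed = 99)))
  expect_identical(rnorm(3), before)
})

test_that("zero burst rate yields an empty annotation and no detections", {
  sim <- generate_ventral_root(ventral_root_sim_config(
    duration_s = 30, burst_rate_per_min = 0, seed = 2))
  expect_equal(nrow(sim$events), 0L)
  env <- envelope(sim$recording)
  expect_equal(nrow(detect_bursts(env, baseline_stats(env, "auto"))), 0L)
})

test_that("annotated burst counts follow the Poisson rate", {
  counts <- vapply(1:50, function(s) {
    sim <- generate_ventral_root(ventral_root_sim_config(
      duration_s = 600, burst_rate_per_min = 2, seed = s))
    sum(sim$events$label == "burst_onset")
  }, numeric(1))
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20))
})

test_that("evoked ground truth matches its deterministic configuration", {
  sim <- evoked_deterministic(seed = 1)
  expect_equal(sum(sim$truth$label == "slr"), 15L)  # 3 spikes x 5 sweeps
  expect_equal(sum(sim$truth$label == "mono"), 5L)
  expect_equal(sum(sim$truth$label %in% c("llr", "spont")), 0L)
  expect_error(evoked_sim_config(mono_latency_s = 0.001),
               "artifact blanking")
  expect_error(evoked_sim_config(slr_spikes = list(c(0.05, 8))),
               "0.040")
})

test_that("annotated LLR counts follow the Poisson rate", {
  totals <- vapply(1:30, function(s) {
    sim <- generate_evoked_sweeps(evoked_sim_config(llr_rate_hz = 2, seed = s))
    sum(sim$truth$label == "llr")
  }, numeric(1))
  expect_lt(abs(mean(totals) - 145), 3 * sqrt(145))
})

test_that("noiseless IPSP series inverts exactly and flat series is flagged", {
  s <- generate_ipsp_series(ipsp_sim_config(true_eipsp_mv = -70,
                                            holding_range_mv = c(-90, -50),
                                            noise_sd_mv = 0, seed = 1))
  fit <- estimate_eipsp(s)
  expect_equal(fit$e_ipsp_mv, -70, tolerance = 1e-9)
  flat <- generate_ipsp_series(ipsp_sim_config(slope_mv_per_mv = 0,
                                               noise_sd_mv = 0, seed = 1))
  expect_error(estimate_eipsp(flat), "[Uu]nidentifiable")
})

test_that("ramp ground truth equals the dense-grid analytic minimum", {
  cfg <- ramp_sim_config(seed = 1)
  rmp <- generate_ramp(cfg)
  # independent brute-force oracle on a 0.01 mV grid
  v <- seq(-70, -10, by = 0.01)
  m <- 1 / (1 + exp(-(v - cfg$v_half_mv) / cfg$k_mv))
  f <- cfg$g_nap_ns * m * (v - cfg$e_na_mv)
  expect_equal(rmp$truth$peak_pa, abs(min(f)), tolerance = 1e-12)
  expect_equal(rmp$truth$v_threshold_mv, v[which(diff(f) < 0)[1]],
               tolerance = 1e-12)
  r0 <- generate_ramp(ramp_sim_config(g_nap_ns = 0, seed = 1))
  expect_equal(r0$truth$peak_pa, 0)
  expect_true(is.na(r0$truth$v_threshold_mv))
})

test_that("twitch generator encodes coincidences and EMG bursts as configured", {
  cfg <- emg_sim_config(duration_s = 40, n_hindlimb = 3, n_tail = 2,
                        n_coincident = 2, seed = 7)
  sim <- generate_emg_and_twitches(cfg)
  expect_equal(sim$truth_n_twitches, 7L)
  expect_equal(nrow(sim$events), 3 + 2 + 2 * 2)
  expect_true(all(sim$events$channel_id %in%
                    c("hindlimb-left", "hindlimb-right", "tail")))
  empty <- generate_emg_and_twitches(emg_sim_config(duration_s = 10, seed = 1))
  expect_equal(nrow(empty$events), 0L)
  expect_equal(empty$truth_n_twitches, 0L)
})

test_that("write_simulation emits recording, truth and config echo", {
  dir <- withr::local_tempdir()
  sim <- generate_ventral_root(ventral_root_sim_config(duration_s = 5,
                                                       seed = 3))
  write_simulation(sim, dir, format = "container")
  expect_true(file.exists(file.path(dir, "recording.rds")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  cfgy <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfgy$seed, 3)
  back <- read_recording(file.path(dir, "recording.rds"), "container")
  expect_identical(back$samples, sim$recording$samples)
})
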