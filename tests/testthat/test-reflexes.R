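test_that("silent sweeps yield no events", {
  rec <- recording(rep(0, 30000), 10000, "VR-L5", t0_s = -1.5)
  expect_equal(nrow(detect_events(rec)), 0L)
})

test_that("inserted spikes are found at their latencies, honoring refractory and blanking", {
  sim <- evoked_deterministic(seed = 2, n_sweeps = 1L)
  ev <- detect_events(sim$sweeps[[1]])
  truth <- sort(sim$truth$time_s)
  expect_equal(nrow(ev), length(truth))   # mono + 3 SLR, artifact blanked
  expect_lt(max(abs(ev$time_s - truth)), 1.5e-4)  # within one 10 kHz sample
  # two spikes 1 ms apart merge under the 3 ms refractory rule
  rate <- 10000
  x <- numeric(3 * rate)
  rec <- recording(x, rate, "VR-L5", t0_s = -1.5)
  x[round(1.52 * rate)] <- 10
  x[round(1.521 * rate)] <- 8
  rec$samples[1, ] <- x
  expect_equal(nrow(detect_events(rec)), 1L)
})

test_that("detect_events agrees with brute-force local-maxima enumeration", {
  set.seed(77)
  rate <- 1000
  x <- abs(rnorm(1000))
  x[c(300, 600, 900)] <- x[c(300, 600, 900)] + 8
  rec <- recording(x, rate, "VR-L5", t0_s = -0.5)
  got <- detect_events(rec, refractory_s = 0, blank_s = 0)
  pre <- x[1:(0.5 * rate)]
  thr <- mean(pre) + 3 * sd(pre)
  brute <- c()
  for (i in 2:(length(x) - 1)) {
    if (x[i] > thr && x[i] > x[i - 1] && x[i] >= x[i + 1]) brute <- c(brute, i)
  }
  expect_equal(round((got$time_s + 0.5) * rate) + 1L, brute)
})

test_that("PSTH binning, sweep-order invariance and coverage hold", {
  # one event at 15 ms in each of 5 sweeps -> first bin holds 5
  tabs <- replicate(5, event_table(0.015, "VR-L5", "event", 1),
                    simplify = FALSE)
  psth <- build_psth(tabs, as.list(rep(0, 5)))
  expect_equal(length(psth$counts), 750L)
  expect_equal(psth$counts[1], 5L)
  expect_equal(sum(psth$counts), 5L)
  empty <- build_psth(replicate(5, event_table(), simplify = FALSE),
                      as.list(rep(0, 5)))
  expect_true(all(empty$counts == 0L))
  # order invariance
  sim <- generate_evoked_sweeps(evoked_sim_config(llr_rate_hz = 1, seed = 6))
  tabs <- lapply(sim$sweeps, detect_events)
  p1 <- build_psth(tabs, sim$stimuli)
  p2 <- build_psth(rev(tabs), rev(sim$stimuli))
  expect_equal(p1$counts, p2$counts)
  expect_equal(sum(p1$counts), sum(lengths(p1$rel_times)) - p1$pre_counts)
})

test_that("reflex counts window exactly and the correction subtracts the pre-stimulus rate", {
  sim <- evoked_deterministic(seed = 1)
  rs <- reflex_from_sim(sim)
  expect_equal(rs$slr_count, 15)
  expect_equal(rs$llr_count, 0)
  expect_equal(rs$raw_slr, 15L)
  expect_equal(rs$mono_amp, 10, tolerance = 0.05)
  # matched pre/post rates cancel
  sim2 <- generate_evoked_sweeps(evoked_sim_config(llr_rate_hz = 2,
                                                   pre_rate_hz = 2, seed = 4))
  rs2 <- reflex_from_sim(sim2)
  expect_lte(rs2$llr_count, 3 * sqrt(rs2$raw_llr))
  expect_gte(rs2$llr_count, 0)
  expect_lte(rs2$llr_count, rs2$raw_llr)
})

test_that("correction floors at zero when expected spontaneous events exceed raw counts", {
  # 10 raw LLR events but a pre rate predicting ~14.5
  tabs <- list(event_table(c(seq(-14, -0.5, length.out = 29),
                             seq(1, 10, length.out = 10)),
                           "VR-L5", "event", 1))
  psth <- build_psth(tabs, list(0))
  rs <- quantify_reflex(psth)
  expect_equal(rs$raw_llr, 10L)
  expect_equal(rs$llr_count, 0)
})

test_that("stimulus threshold is the lowest responding intensity", {
  mk <- function(slr) structure(list(slr_count = slr, mono_amp = NA_real_),
                                class = "reflex_summary")
  resp <- list(list(intensity = 10, summary = mk(0)),
               list(intensity = 20, summary = mk(0)),
               list(intensity = 30, summary = mk(4)),
               list(intensity = 40, summary = mk(6)))
  thr <- estimate_threshold(resp, criterion = "slr")
  expect_equal(thr$threshold_intensity, 30)
  expect_true(thr$reached)
  silent <- estimate_threshold(resp[1:2], criterion = "slr")
  expect_false(silent$reached)
  expect_error(estimate_threshold(rev(resp)), "increasing")
})

test_that("threshold recovery matches a generator-defined response curve", {
  theta <- 25
  intensities <- c(10, 20, 30, 40)
  resp <- lapply(intensities, function(I) {
    cfg <- if (I >= theta) evoked_sim_config(seed = I)
           else evoked_sim_config(slr_spikes = list(), seed = I)
    list(intensity = I, summary = reflex_from_sim(generate_evoked_sweeps(cfg)))
  })
  thr <- estimate_threshold(resp, criterion = "slr")
  expect_equal(thr$threshold_intensity, min(intensities[intensities >= theta]))
})

test_that("use-dependence ratios normalize to the longest interval", {
  s <- data.frame(interval_s = c(60, 120, 240), llr_count = c(50, 50, 50))
  ud <- assess_use_dependence(s)
  expect_equal(ud$ratio, c(1, 1, 1))
  s2 <- data.frame(interval_s = c(60, 120, 240), llr_count = c(25, 40, 50))
  ud2 <- assess_use_dependence(s2)
  expect_equal(ud2$ratio[1], 0.5)
  expect_true(attr(ud2, "declining"))
  expect_error(assess_use_dependence(s2[1, ]), "two or more")
  # exponential recovery: mean LLR = L * (1 - exp(-t/tau_rec))
  tau_rec <- 120; L <- 100
  iv <- c(30, 60, 120, 240, 480)
  s3 <- data.frame(interval_s = iv, llr_count = L * (1 - exp(-iv / tau_rec)))
  ud3 <- assess_use_dependence(s3)
  analytic <- (1 - exp(-iv / tau_rec)) / (1 - exp(-480 / tau_rec))
  expect_equal(ud3$ratio, analytic, tolerance = 0.1)
})
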