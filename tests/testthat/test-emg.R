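test_that("baseline-only traces report no response", {
  sim <- generate_emg_and_twitches(emg_sim_config(duration_s = 20,
                                                  rate_hz = 2000, seed = 1))
  er <- emg_response_duration(sim$recording, baseline_window = c(0, 5))
  expect_false(er$responded)
  expect_equal(er$duration_s, 0)
})

test_that("a 3 s burst at 10x baseline is measured within the 8 Hz filter lag", {
  sim <- generate_emg_and_twitches(emg_sim_config(
    duration_s = 20, rate_hz = 2000,
    bursts = data.frame(onset_s = 8, duration_s = 3, amp_mult = 10),
    seed = 5))
  er <- emg_response_duration(sim$recording, baseline_window = c(0, 5))
  expect_true(er$responded)
  expect_equal(er$duration_s, 3, tolerance = 0.25 / 3)
  expect_equal(er$onset_s, 8, tolerance = 0.2)
  # doubling the amplitude moves the crossings by less than the rise lag
  sim2 <- generate_emg_and_twitches(emg_sim_config(
    duration_s = 20, rate_hz = 2000,
    bursts = data.frame(onset_s = 8, duration_s = 3, amp_mult = 20),
    seed = 5))
  er2 <- emg_response_duration(sim2$recording, baseline_window = c(0, 5))
  expect_lt(abs(er2$duration_s - er$duration_s), 0.15)
})

test_that("duration is monotone non-increasing in k_sd", {
  sim <- generate_emg_and_twitches(emg_sim_config(
    duration_s = 20, rate_hz = 2000,
    bursts = data.frame(onset_s = 8, duration_s = 3, amp_mult = 10),
    seed = 7))
  d <- vapply(c(3, 6, 12, 24), function(k)
    emg_response_duration(sim$recording, baseline_window = c(0, 5),
                          k_sd = k)$duration_s, numeric(1))
  expect_true(all(diff(d) <= 0))
})

test_that("mechanical threshold is the minimal responding pressure", {
  trials <- data.frame(pressure_g = c(6, 8, 10), duration_s = c(0, 1.2, 2.5))
  thr <- mechanical_threshold(trials)
  expect_equal(thr$threshold_intensity, 8)
  none <- mechanical_threshold(data.frame(pressure_g = c(6, 8),
                                          duration_s = c(0, 0)))
  expect_false(none$reached)
  expect_error(mechanical_threshold(data.frame(pressure_g = c(8, 6),
                                               duration_s = c(0, 0))),
               "increasing")
  # generator-style staircase with true threshold 7 g on a 1 g grid
  theta <- 7
  grid <- 1:12
  stair <- data.frame(pressure_g = grid,
                      duration_s = ifelse(grid >= theta, 1.5, 0))
  expect_equal(mechanical_threshold(stair)$threshold_intensity, 7)
})

test_that("coincident hindlimb and tail events score as a single twitch", {
  ev <- event_table(c(10.00, 10.05), c("hindlimb-left", "tail"), "twitch")
  expect_equal(count_twitches(ev, window = c(0, 600))$n_twitches, 1L)
  far <- event_table(c(10.0, 10.5), c("hindlimb-left", "tail"), "twitch")
  expect_equal(count_twitches(far, window = c(0, 600))$n_twitches, 2L)
  # transitive chains collapse to one
  chain <- event_table(c(10.00, 10.08, 10.16),
                       c("hindlimb-left", "tail", "hindlimb-right"), "twitch")
  expect_equal(count_twitches(chain, window = c(0, 600))$n_twitches, 1L)
  # invariant to event-list and channel order
  perm <- event_table(c(10.05, 10.00), c("tail", "hindlimb-left"), "twitch")
  expect_equal(count_twitches(perm, window = c(0, 600))$n_twitches, 1L)
})

test_that("generated isolated plus coincident events count by the merge rule", {
  sim <- generate_emg_and_twitches(emg_sim_config(
    duration_s = 600, rate_hz = 100, n_hindlimb = 20, n_tail = 10,
    n_coincident = 5, seed = 9))
  tc <- count_twitches(sim$events, window = c(0, 600))
  expect_equal(tc$n_twitches, sim$truth_n_twitches)
  expect_equal(tc$n_twitches, 35L)
})

test_that("twitch time courses aggregate hourly means and SDs", {
  sess <- data.frame(t_hours = c(1, 1, 2, 3), n_twitches = c(10, 20, 5, 0))
  tc <- twitch_timecourse(sess)
  expect_equal(tc$mean, c(15, 5, 0))
  expect_equal(tc$sd[1], sd(c(10, 20)))
  expect_equal(tc$sd[2], 0)
  expect_equal(tc$n, c(2, 1, 1))
  expect_error(twitch_timecourse(sess[0, ]), "no sessions")
  # Poisson sessions around a decaying hourly mean
  mus <- 30 * exp(-(0:5) / 3)
  set.seed(4)
  sess2 <- do.call(rbind, lapply(0:5, function(h)
    data.frame(t_hours = h, n_twitches = rpois(8, mus[h + 1]))))
  tc2 <- twitch_timecourse(sess2)
  expect_true(all(abs(tc2$mean - mus) < 3 * sqrt(mus / 8) + 1))
})
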