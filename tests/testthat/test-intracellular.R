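test_that("E_IPSP is the exact x-intercept for a noiseless line", {
  v <- seq(-90, -50, by = 2)
  s <- ipsp_series(v, -0.5 * (v + 70), v_rest_mv = -60)
  fit <- suppressWarnings(estimate_eipsp(s))
  expect_equal(fit$e_ipsp_mv, -70, tolerance = 1e-9)
  expect_equal(fit$driving_force_mv, -10, tolerance = 1e-9)
  expect_lt(fit$residual_sd_mv, 1e-9)
  # point order does not matter; affine V-shift moves E_IPSP identically
  sh <- ipsp_series(rev(v) + 5, -0.5 * (rev(v) + 70), v_rest_mv = -60)
  expect_equal(suppressWarnings(estimate_eipsp(sh))$e_ipsp_mv, -65,
               tolerance = 1e-9)
})

test_that("junction offset shifts the fitted reversal", {
  v <- seq(-90, -50, by = 2)
  s <- ipsp_series(v, -0.5 * (v + 70), v_rest_mv = -60,
                   junction_offset_mv = 10)
  expect_equal(suppressWarnings(estimate_eipsp(s))$e_ipsp_mv, -80,
               tolerance = 1e-9)
})

test_that("noisy series recover E_IPSP within the OLS sampling error", {
  # closed-form SE of the x-intercept via the delta method, per seed
  errs <- vapply(1:100, function(s) {
    ser <- generate_ipsp_series(ipsp_sim_config(true_eipsp_mv = -58,
                                                noise_sd_mv = 0.5, seed = s))
    estimate_eipsp(ser)$e_ipsp_mv - (-58)
  }, numeric(1))
  expect_lt(mean(abs(errs)), 1)
  v <- seq(-90, -40, length.out = 22)
  se_slope <- 0.5 / sqrt(sum((v - mean(v))^2))
  se_int <- sqrt((0.5^2 / 22) + (mean(v) + 58)^2 * se_slope^2) / 0.5
  expect_lt(abs(mean(errs)), 3 * se_int)   # unbiased within MC error
  expect_error(estimate_eipsp(ipsp_series(c(-60, -60), c(1, 2))), "distinct")
  expect_warning(estimate_eipsp(ipsp_series(seq(-80, -60, 5),
                                            seq(-80, -60, 5) * -0.5 - 35)),
                 "fewer")
})

test_that("pure leak traces are fitted exactly and noisy fits stay within OLS error", {
  rmp <- generate_ramp(ramp_sim_config(g_nap_ns = 0, seed = 1))
  lk <- fit_leak(rmp)
  expect_equal(lk$g_leak_ns, 10, tolerance = 1e-9)
  expect_equal(lk$e_leak_mv, -70, tolerance = 1e-6)
  devs <- vapply(1:5, function(s) {
    noisy <- generate_ramp(ramp_sim_config(g_nap_ns = 0, noise_sd_pa = 5,
                                           seed = s))
    sel <- noisy$v_cmd_mv >= -70 & noisy$v_cmd_mv <= -60
    se_g <- 5 / sqrt(sum((noisy$v_cmd_mv[sel] - mean(noisy$v_cmd_mv[sel]))^2))
    abs(fit_leak(noisy)$g_leak_ns - 10) / se_g
  }, numeric(1))
  expect_gte(sum(devs < 3), 4L)   # one 3-SE excursion tolerated
  expect_true(all(devs < 5))
  expect_error(fit_leak(rmp, window_mv = c(-70, -69.999)), "fewer than 10")
})

test_that("leak fit over the subthreshold window carries the analytic activation contamination", {
  cfg <- ramp_sim_config(seed = 1)
  rmp <- generate_ramp(cfg)
  lk <- fit_leak(rmp, window_mv = c(-70, -60))
  sel <- rmp$v_cmd_mv >= -70 & rmp$v_cmd_mv <= -60
  v <- rmp$v_cmd_mv[sel]
  f <- cfg$g_nap_ns * (1 / (1 + exp(-(v - cfg$v_half_mv) / cfg$k_mv))) *
    (v - cfg$e_na_mv)
  contamination <- cov(v, f) / var(v)   # analytic LS slope of the tail
  expect_equal(lk$g_leak_ns, cfg$g_leak_ns + contamination, tolerance = 1e-6)
})

test_that("leak-subtracted extraction matches the dense-grid analytic oracle", {
  cfg <- ramp_sim_config(seed = 1)
  rmp <- generate_ramp(cfg)
  res <- extract_inap(rmp, leak = true_leak(cfg))
  expect_equal(res$peak_amp_pa, rmp$truth$peak_pa, tolerance = 0.01)
  expect_lte(abs(res$v_threshold_mv - rmp$truth$v_threshold_mv), 2)
  # subtracting the generating leak from a leak-only trace leaves zero
  leak_only <- generate_ramp(ramp_sim_config(g_nap_ns = 0, seed = 3))
  r0 <- extract_inap(leak_only, leak = true_leak(cfg))
  expect_lt(r0$peak_amp_pa, 1e-9)
  expect_false(r0$threshold_defined)
  # linearity in g_nap
  r2 <- extract_inap(generate_ramp(ramp_sim_config(g_nap_ns = 2, seed = 1)),
                     leak = true_leak(cfg))
  expect_equal(r2$peak_amp_pa, 2 * res$peak_amp_pa, tolerance = 1e-6)
})

test_that("noisy ramps keep the median relative peak error under 5%", {
  cfg <- ramp_sim_config()
  errs <- vapply(1:50, function(s) {
    r <- generate_ramp(ramp_sim_config(noise_sd_pa = 5, seed = s))
    x <- extract_inap(r, leak = true_leak(cfg))
    abs(x$peak_amp_pa - r$truth$peak_pa) / r$truth$peak_pa
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})
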