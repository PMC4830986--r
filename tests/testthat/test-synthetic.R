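test_that("noiseless decay generation reproduces the model exactly", {
  sc <- decay_scenario(k_true = 5e-4, plateau_true = 0.2, noise_cv = 0,
                       seed = 1)
  s <- generate_decay_series(sc)
  mu <- 0.2 + 0.8 * exp(-5e-4 * s$data$time_s)
  expect_equal(s$data$py_fraction, mu)
  expect_true(7200 %in% s$data$time_s)   # 2 h benchmark always present
})

test_that("generators are pure functions of (scenario, seed)", {
  sc <- decay_scenario(noise_cv = 0.05, seed = 77, products = TRUE)
  expect_identical(generate_decay_series(sc), generate_decay_series(sc))
  s2 <- generate_decay_series(decay_scenario(noise_cv = 0.05, seed = 78,
                                             products = TRUE))
  expect_false(identical(generate_decay_series(sc)$data, s2$data))

  cv <- generate_rate_curve("LH", 1e-3, 2e-20, noise_cv = 0.1, seed = 5)
  expect_identical(cv, generate_rate_curve("LH", 1e-3, 2e-20,
                                           noise_cv = 0.1, seed = 5))

  fs <- field_scenario(seed = 9)
  expect_identical(generate_field_dataset(fs), generate_field_dataset(fs))
})

test_that("generated values respect physical bounds", {
  set.seed(3)
  for (i in 1:10) {
    s <- generate_decay_series(decay_scenario(noise_cv = 0.3,
                                              seed = 100 + i,
                                              products = TRUE))
    expect_true(all(s$data$py_fraction >= 0))
    expect_true(all(s$products$yield_fraction >= 0))
    cv <- generate_rate_curve("LH", 1e-3, 2e-20, noise_cv = 0.3,
                              seed = 100 + i)
    expect_true(all(cv$no2_number_density > 0))
    expect_true(all(cv$k_obs > 0))
    fd <- generate_field_dataset(field_scenario(seed = 100 + i))
    expect_true(all(fd$conc_1np >= 0))
    expect_true(all(fd$conc_bkf >= 0))
  }
})

test_that("simple-fit calibration: recovered k within 3 SE of truth", {
  hits <- vapply(1:100, function(i) {
    s <- generate_decay_series(decay_scenario(seed = 5000 + i))
    f <- fit_decay(s, model = "simple")
    abs(f$k_obs - 8.6e-4) <= 3 * f$k_obs_se
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("product tracks follow a consecutive-reaction shape", {
  sc <- decay_scenario(k_true = 8.6e-4, noise_cv = 0, products = TRUE,
                       times = c(0, 600, 1800, 3600, 7200, 14400, 43200))
  s <- generate_decay_series(sc)
  np <- s$products[s$products$species == "1-NP", ]
  # intermediate rises then falls; starts at zero
  expect_true(all(np$yield_fraction[np$time_s == 0] == 0))
  peak <- which.max(np$yield_fraction)
  expect_gt(peak, 1)
  expect_lt(peak, nrow(np))
  dnp <- s$products[s$products$species == "DNP", ]
  expect_true(all(diff(dnp$yield_fraction) >= -1e-12))  # terminal product
})

test_that("null field scenario leaves dust and non-dust ratios exchangeable", {
  fs <- field_scenario(dust_enhancement = 1, seed = 13)
  fd <- generate_field_dataset(fs)
  r <- ratio_1np_bkf(fd)
  heavy <- fd$dust_label == "heavy"
  expect_equal(median(r[heavy]), median(r[!heavy]), tolerance = 0.3)
})

test_that("enhanced field scenario is detectable by the rank test", {
  fs <- field_scenario(dust_enhancement = 5, lognormal_sigma = 0.2,
                       seed = 14)
  fd <- generate_field_dataset(fs)
  rep_ <- dust_effect_report(fd)
  expect_lt(rep_$test_coarse$p_value, 0.05)
})

test_that("scenario validation rejects inconsistent inputs", {
  expect_error(decay_scenario(plateau_true = 1.2))
  expect_error(decay_scenario(noise_cv = -0.1))
  expect_error(field_scenario(dust_enhancement = 0.5))
  expect_error(field_scenario(dust_periods = 99))
})
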