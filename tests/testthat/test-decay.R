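test_that("simple fit recovers the generating rate constant exactly", {
  f <- fit_decay(noiseless_decay(1e-3), model = "simple")
  expect_equal(f$k_obs, 1e-3, tolerance = 1e-6)
  expect_equal(f$plateau, 0)
  expect_identical(f$model, "simple")
})

test_that("all-constant data give k_obs = 0 with a warning", {
  d <- data.frame(time_s = c(0, 3600, 7200), py_fraction = c(1, 1, 1))
  expect_warning(f <- fit_decay(d, model = "simple"), "constant")
  expect_identical(f$k_obs, 0)
})

test_that("plateau fit recovers both generating parameters exactly", {
  f <- fit_decay(noiseless_decay(2.9e-4, 0.16,
                                 times = c(0, 1800, 3600, 7200, 14400)),
                 model = "plateau")
  expect_equal(f$k_obs, 2.9e-4, tolerance = 1e-6)
  expect_equal(f$plateau, 0.16, tolerance = 1e-6)
})

test_that("plateau model nests the simple model at p = 0", {
  d <- noiseless_decay(1e-3)
  fs <- fit_decay(d, model = "simple")
  fp <- suppressWarnings(fit_decay(d, model = "plateau"))
  expect_equal(fp$k_obs, fs$k_obs, tolerance = 1e-4)
  expect_true(fp$plateau_pinned)   # p estimate sits on the zero bound
  expect_lte(fp$rss, fs$rss + 1e-12)
})

test_that("noiseless fits recover truth to solver tolerance (property)", {
  set.seed(11)
  for (i in 1:10) {
    k <- 10^runif(1, -4.5, -2.5)
    p <- runif(1, 0.05, 0.5)
    tgrid <- sort(c(0, 7200, 10^runif(4, 2.5, 4.3)))
    fs <- fit_decay(noiseless_decay(k, 0, tgrid), model = "simple")
    expect_equal(fs$k_obs, k, tolerance = 1e-6)
    fp <- fit_decay(noiseless_decay(k, p, tgrid), model = "plateau")
    expect_equal(fp$k_obs, k, tolerance = 1e-6)
    expect_equal(fp$plateau, p, tolerance = 1e-6)
  }
})

test_that("auto selection: plateau data pick plateau, p = 0 data pick simple", {
  f0 <- suppressWarnings(
    fit_decay(generate_decay_series(decay_scenario(noise_cv = 0.05,
                                                   seed = 21))))
  expect_identical(f0$model, "simple")
  expect_identical(f0$selection$selected, "simple")

  fp <- fit_decay(generate_decay_series(
    decay_scenario(k_true = 2.9e-4, plateau_true = 0.3, noise_cv = 0.01,
                   times = c(0, 1800, 3600, 7200, 14400, 28800),
                   seed = 22)))
  expect_identical(fp$model, "plateau")
  expect_lt(fp$selection$p_value, 0.05)
})

test_that("3-point series forces the simple model with a warning", {
  d <- noiseless_decay(1e-3, times = c(0, 3600, 7200))
  expect_warning(f <- fit_decay(d), "forced|distinct")
  expect_identical(f$model, "simple")
  expect_identical(f$selection$rule, "forced_simple_insufficient_dof")
  expect_error(fit_decay(d, model = "plateau"), "4 distinct")
})

test_that("k_obs is invariant under common rescaling after normalisation", {
  sc <- decay_scenario(noise_cv = 0.05, seed = 31)
  s <- generate_decay_series(sc)
  f1 <- fit_decay(s, model = "simple")
  d2 <- s$data
  d2$py_fraction <- d2$py_fraction / d2$py_fraction[d2$time_s == 0][1]
  f2 <- suppressWarnings(fit_decay(d2, model = "simple"))
  # normalising to the first t=0 replicate is a common positive rescale
  expect_equal(f2$k_obs, f1$k_obs, tolerance = 0.05)
})

test_that("degradation percentage is mean-over-replicates arithmetic", {
  s <- decay_series(c(0, 3600, 7200), c(1, 0.2, 0.04))
  expect_equal(degradation_percent(s), 96)
  s2 <- decay_series(c(0, 3600, 7200), c(1, 0.5, 1.0))
  expect_equal(degradation_percent(s2), 0)
  s3 <- decay_series(c(0, 3600, 7200, 7200, 7200),
                     c(1, 0.5, 0.10, 0.12, 0.14))
  expect_equal(degradation_percent(s3), 88)
  expect_error(degradation_percent(s, t = 5000), "no observation")
})

test_that("product yields are read at the exact benchmark time", {
  pr <- data.frame(time_s = c(7200, 7200), species = c("1-NP", "DNP"),
                   yield_fraction = c(0.53, 0))
  s <- decay_series(c(0, 3600, 7200), c(1, 0.3, 0.04), products = pr)
  expect_equal(product_yield(s, "1-NP"), 53)
  expect_equal(product_yield(s, "DNP"), 0)
  expect_error(product_yield(s, "2-NP"), "available")
  expect_error(product_yield(decay_series(c(0, 1, 2), c(1, 1, 1)), "1-NP"),
               "no product")
})

test_that("DNP flag follows the 12 h detection-threshold rule", {
  pr <- data.frame(time_s = rep(43200, 2), species = c("DNP", "1-NP"),
                   yield_fraction = c(0.02, 0.5))
  s <- decay_series(c(0, 3600, 43200), c(1, 0.3, 0.01), products = pr)
  expect_identical(dnp_formed(s), "+")
  pr$yield_fraction[1] <- 0.001
  s2 <- decay_series(c(0, 3600, 43200), c(1, 0.3, 0.01), products = pr)
  expect_identical(dnp_formed(s2), "-")
})

test_that("decay_fit methods are coherent", {
  s <- generate_decay_series(decay_scenario(noise_cv = 0.03, seed = 41))
  f <- suppressWarnings(fit_decay(s))
  expect_named(coef(f), "k_obs")
  expect_equal(predict(f, 0), 1)
  expect_equal(sum(residuals(f)^2), f$rss, tolerance = 1e-10)
  expect_equal(unname(sqrt(diag(vcov(f)))[1]), f$k_obs_se)
  sm <- summary(f)
  expect_s3_class(sm, "summary.decay_fit")
  expect_equal(sm$halflife_s, log(2) / f$k_obs)
  sim <- simulate(f, nsim = 3, seed = 1)
  expect_identical(dim(sim), c(nrow(s$data), 4L))
  expect_true(all(sim[-1] >= 0))
})

test_that("series validation guards the contract", {
  expect_error(decay_series(c(0, 1), c(1, 0.5)), "3 distinct")
  expect_error(decay_series(c(0, -1, 2), c(1, 0.5, 0.2)), ">= 0")
  expect_warning(decay_series(c(0, 1, 2), c(1.1, 0.5, 0.2)), "noise")
})
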