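test_that("1-NP/BkF ratio contract: zero numerator ok, zero denominator NA", {
  expect_equal(ratio_1np_bkf(2, 4), 0.5)
  expect_equal(ratio_1np_bkf(0, 4), 0)
  expect_true(is.na(ratio_1np_bkf(2, 0)))
  expect_true(is.na(ratio_1np_bkf(2, NA)))
  expect_error(ratio_1np_bkf(-1, 2), ">= 0")
  df <- data.frame(conc_1np = c(1, 2), conc_bkf = c(2, 0))
  expect_equal(ratio_1np_bkf(df), c(0.5, NA))
})

test_that("period classification follows the two-threshold rule", {
  expect_identical(classify_periods(numeric(0)), character(0))
  expect_identical(classify_periods(c(10, 50, 99)), rep("none", 3))
  expect_identical(classify_periods(c(600, 150, 20)),
                   c("heavy", "low", "none"))
  expect_error(classify_periods(1, heavy_threshold = 10,
                                low_threshold = 20), "exceed")
})

test_that("exact Mann-Whitney matches the small-sample enumeration", {
  # a fully separated pair: 1 of the 6 rank assignments is as extreme
  r <- mann_whitney_u(c(1, 2), c(3, 4), "less")
  expect_identical(r$U, 0)
  expect_equal(r$p_value, 1 / 6)
  expect_identical(r$method, "exact")
  # identical multisets: degenerate contract
  expect_equal(mann_whitney_u(c(1, 1), c(1, 1))$p_value, 1)
  # minimal n: one observation per group
  r1 <- mann_whitney_u(1, 2)
  expect_gte(r1$p_value, 0.5)
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})

test_that("exact p equals the independent rank-permutation oracle", {
  # oracle: stats::wilcox.test exact p (independent implementation)
  set.seed(19)
  for (rep_ in 1:3) {
    for (n_a in 1:5) {
      for (n_b in n_a:(10 - n_a)) {
        x <- sample_no_ties(n_a + n_b)
        a <- x[seq_len(n_a)]
        b <- x[-seq_len(n_a)]
        for (alt in c("two.sided", "greater", "less")) {
          ours <- mann_whitney_u(a, b, alt)
          expect_identical(ours$method, "exact")
          ref <- wilcox.test(a, b, alternative = alt, exact = TRUE)
          expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
          expect_equal(ours$U, unname(ref$statistic))
        }
      }
    }
  }
})

test_that("normal approximation tracks the exact p at n_a = n_b = 8", {
  set.seed(23)
  x <- sample_no_ties(16)
  a <- x[1:8] + 0.2
  b <- x[9:16]
  exact <- mann_whitney_u(a, b, exact_limit = 16L)
  approx <- mann_whitney_u(a, b, exact_limit = 0L)
  expect_identical(exact$method, "exact")
  expect_identical(approx$method, "normal_approx")
  expect_equal(approx$p_value, exact$p_value, tolerance = 0.02)
})

test_that("tied data fall back to the tie-corrected approximation", {
  r <- mann_whitney_u(c(1, 2, 2, 3), c(2, 3, 3, 4))
  expect_identical(r$method, "normal_approx")
  expect_true(r$p_value > 0 && r$p_value <= 1)
  ref <- suppressWarnings(wilcox.test(c(1, 2, 2, 3), c(2, 3, 3, 4),
                                      exact = FALSE, correct = TRUE))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("U statistics are complementary and rank-transform invariant", {
  set.seed(29)
  for (i in 1:20) {
    n_a <- sample(2:6, 1); n_b <- sample(2:6, 1)
    x <- sample_no_ties(n_a + n_b)
    a <- x[seq_len(n_a)]; b <- x[-seq_len(n_a)]
    ra <- mann_whitney_u(a, b)
    rb <- mann_whitney_u(b, a)
    expect_equal(ra$U + rb$U, n_a * n_b)
    # strictly monotone transform leaves the exact p unchanged
    rt <- mann_whitney_u(exp(3 * a), exp(3 * b))
    expect_identical(rt$p_value, ra$p_value)
  }
})

test_that("dust report separates enhanced coarse fractions", {
  fd <- generate_field_dataset(field_scenario(seed = 2))
  rep_ <- dust_effect_report(fd)
  expect_s3_class(rep_, "dust_report")
  expect_lt(rep_$test_coarse$p_value, 0.05)
  expect_identical(rep_$n_excluded, 0L)
  expect_identical(nrow(rep_$by_fraction), 15L)  # 5 fractions x 3 labels
  js <- jsonlite::fromJSON(dust_report_json(rep_))
  expect_equal(js$test_coarse$p_value, rep_$test_coarse$p_value)
})

test_that("dust report excludes zero-BkF samples with a count", {
  fd <- generate_field_dataset(field_scenario(seed = 2))
  fd$conc_bkf[3] <- 0
  expect_message(rep_ <- dust_effect_report(fd), "excluded")
  expect_identical(rep_$n_excluded, 1L)
  fd$dust_label <- "heavy"
  expect_error(suppressMessages(dust_effect_report(fd)), "both")
})
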