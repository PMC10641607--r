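test_that("wilcoxon signed-rank handles degenerate and tiny exact cases", {
  res <- wilcoxon_signed_rank(c(2, 2, 2), c(2, 2, 2))
  expect_equal(res$p_value, 1)
  expect_equal(res$degenerate, "all_differences_zero")

  # differences (1, 2, 3), all positive: one-sided exact p = 1/8
  res <- wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1), alternative = "greater")
  expect_equal(res$p_value, 1 / 8)
  expect_equal(res$method, "exact_enumeration")
  expect_equal(res$statistic, 6)

  expect_error(wilcoxon_signed_rank(1:3, 1:4), "length")
  expect_error(wilcoxon_signed_rank(numeric(0), numeric(0)), "empty")
})

test_that("wilcoxon exact path agrees with the convolution oracle (n <= 8)", {
  set.seed(21)
  for (i in 1:150) {
    n <- sample(2:8, 1)
    x <- sample(0:4, n, replace = TRUE)
    y <- sample(0:4, n, replace = TRUE)
    for (alt in c("two.sided", "greater", "less")) {
      got <- wilcoxon_signed_rank(x, y, alternative = alt)$p_value
      expect_equal(got, oracle_signed_rank_p(x, y, alt), tolerance = 1e-12,
                   info = paste("n =", n, alt))
    }
  }
})

test_that("wilcoxon exact path agrees with wilcox.test on tie-free data", {
  set.seed(22)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    d <- sample(setdiff(-20:20, 0), n)  # distinct |d| not guaranteed; filter
    if (anyDuplicated(abs(d))) next
    x <- d; y <- rep(0, n)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(wilcoxon_signed_rank(x, y)$p_value, ref, tolerance = 1e-12)
  }
})

test_that("wilcoxon approximate path matches R's tie-corrected z test", {
  set.seed(23)
  for (i in 1:30) {
    n <- sample(30:120, 1)
    x <- sample(0:4, n, replace = TRUE)
    y <- sample(0:4, n, replace = TRUE)
    if (sum(x != y) <= 12) next  # would take the exact path
    got <- wilcoxon_signed_rank(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(got$method, "normal_tie_corrected")
  }
})

test_that("mann-whitney handles separation, symmetry and errors", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)  # complete separation, U for group_a
  expect_equal(res$p_value, 2 * (1 / choose(6, 3)))

  res <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 3 * 3 / 2)
  expect_equal(res$p_value, 1)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("mann-whitney exact path agrees with the bitmask oracle (n <= 8)", {
  set.seed(24)
  for (i in 1:120) {
    n_a <- sample(2:5, 1); n_b <- sample(2:4, 1)
    a <- sample(0:3, n_a, replace = TRUE)
    b <- sample(0:3, n_b, replace = TRUE)
    for (alt in c("two.sided", "greater", "less")) {
      got <- mann_whitney_u(a, b, alternative = alt)$p_value
      expect_equal(got, oracle_mw_p(a, b, alt), tolerance = 1e-12,
                   info = paste(n_a, n_b, alt))
    }
  }
})

test_that("mann-whitney approximate path matches R's tie-corrected z test", {
  set.seed(25)
  for (i in 1:30) {
    n_a <- sample(20:80, 1); n_b <- sample(20:80, 1)
    a <- sample(0:4, n_a, replace = TRUE)
    b <- sample(0:4, n_b, replace = TRUE)
    got <- mann_whitney_u(a, b)
    ref <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("paired exposure test matches the closed-form t oracle", {
  ads <- data.frame(ad_id = c("A", "B", "C", "D"),
                    emotional_variety = 2L, rational_variety = 0L,
                    wi_female = c(5, 3, 6, 4), wi_male = c(4, 4, 4, 4))
  res <- paired_exposure_test(ads, "female", "male", 2, "emotional")
  d <- c(1, -1, 2, 0)
  t_oracle <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$statistic, t_oracle)
  expect_equal(res$p_value, 2 * pt(-abs(t_oracle), df = 3))
  ref <- stats::t.test(ads$wi_female, ads$wi_male, paired = TRUE)
  expect_equal(res$p_value, ref$p.value)

  # identical strata: degenerate with p = 1
  res <- paired_exposure_test(ads, "female", "female", 2, "emotional")
  expect_equal(res$p_value, 1)
  expect_equal(res$degenerate, "identical")

  # constant nonzero difference: infinite separation
  ads$wi_male <- ads$wi_female - 2
  res <- paired_exposure_test(ads, "female", "male", 2, "emotional")
  expect_equal(res$degenerate, "infinite_separation")
  expect_equal(res$p_value, 0)

  # no ads at the level: explicit empty result, not an error
  res <- paired_exposure_test(ads, "female", "male", "4+", "emotional")
  expect_equal(res$degenerate, "empty_stratum")
  expect_true(is.na(res$p_value))

  expect_error(paired_exposure_test(ads, "female", "male", 7, "emotional"),
               "variety_level")
  expect_error(paired_exposure_test(ads, "female", "ses_low", 2, "emotional"),
               "wi_ses_low")
})
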