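test_that("config validation names the offending field", {
  expect_error(sim_config(gender_gap = -1), "gender_gap")
  expect_error(sim_config(frac_high_in = 1.5), "frac_high_in")
  expect_error(sim_config(ses_gradient = c(1, 2)), "ses_gradient")
  expect_error(sim_config(coder_error_rate = 2), "coder_error_rate")
  expect_error(sim_config(window = c(10, 9)), "window")
  ap <- default_appeal_prevalence()
  ap$p_high_in[1] <- 1.2
  expect_error(sim_config(appeal_prevalence = ap), "appeal_prevalence")
  bad_pops <- default_populations()
  bad_pops$population[2] <- bad_pops$population[2] + 1  # breaks female+male=overall
  expect_error(sim_config(populations = bad_pops), "female \\+ male")
})

test_that("fixed seed gives bit-identical outputs; degenerate counts work", {
  config <- small_config(seed = 99)
  d1 <- simulate_dataset(config)
  d2 <- simulate_dataset(config)
  expect_identical(d1$airings, d2$airings)
  expect_identical(d1$products, d2$products)
  expect_identical(d1$codings, d2$codings)

  # all instance counts forced to 1: exactly one row per ad
  config <- sim_config(seed = 3, n_unique_ads = 2, instances_mean = 1,
                       instances_dispersion = 0)
  air <- simulate_airings(config)
  expect_equal(nrow(air), 2L)
  expect_equal(sort(unique(air$ad_id)), c("AD00001", "AD00002"))
})

test_that("airing structure: window, year, versions, every ad present", {
  config <- small_config(seed = 12, n_unique_ads = 80)
  air <- simulate_airings(config)
  expect_setequal(unique(air$ad_id), sprintf("AD%05d", 1:80))
  hrs <- as.integer(substr(air$timestamp, 12, 13))
  expect_true(all(hrs >= 6 & hrs < 22))
  expect_true(all(substr(air$timestamp, 1, 4) == "2017"))
  expect_true(all(air$duration > 0))
  # multi-version ads: versions differ only in duration under one ad_id
  nv <- tapply(air$version_id, air$ad_id, function(v) length(unique(v)))
  expect_true(any(nv == 2))
  expect_true(all(nv <= 2))
})

test_that("gender gap and SES gradient shape the ratings as configured", {
  config <- sim_config(seed = 31, n_unique_ads = 500, instances_mean = 3,
                       instances_dispersion = 0.3, gender_gap = 1.5)
  air <- simulate_airings(config)
  ratio <- mean(air$rating_female) / mean(air$rating_male)
  expect_lt(abs(ratio / 1.5 - 1), 0.05)

  # monotone gradient: raising the low-SES multiplier raises low-SES exposure
  c_lo <- small_config(seed = 8, n_unique_ads = 300,
                       ses_gradient = c(low = 1.0, mid = 1.0, high = 0.6))
  c_hi <- small_config(seed = 8, n_unique_ads = 300,
                       ses_gradient = c(low = 2.0, mid = 1.0, high = 0.6))
  a_lo <- simulate_airings(c_lo)
  a_hi <- simulate_airings(c_hi)
  expect_gt(mean(a_hi$rating_ses_low), mean(a_lo$rating_ses_low))
  expect_equal(a_lo$rating_ses_mid, a_hi$rating_ses_mid)
})

test_that("product generator hits the high-in fraction and never bypasses the classifier", {
  config <- small_config(seed = 41)
  ids <- sprintf("PX%04d", 1:2000)
  p0 <- simulate_products(small_config(seed = 41, frac_high_in = 0),
                          product_ids = ids)
  expect_false(any(classify_products(p0)$high_in))
  p1 <- simulate_products(small_config(seed = 41, frac_high_in = 1),
                          product_ids = ids)
  expect_true(all(classify_products(p1)$high_in))
  pf <- simulate_products(small_config(seed = 41, frac_high_in = 0.776),
                          product_ids = ids)
  frac <- mean(classify_products(pf)$high_in)
  expect_lt(abs(frac - 0.776), 0.03)
  expect_true(all(pf$energy_kcal >= 0))
  expect_true(all(pf$free_sugars_g >= 0 & pf$sodium_mg >= 0))
})

test_that("standalone simulate_products recovers the airing product universe", {
  config <- small_config(seed = 55)
  ds <- simulate_dataset(config)
  standalone <- simulate_products(config)
  expect_identical(standalone, ds$products)
})

test_that("codings follow the prevalence pairs and the coder-noise model", {
  # error-free second coder: identical tables
  ds <- simulate_dataset(small_config(seed = 6, coder_error_rate = 0))
  c1 <- ds$codings[ds$codings$coder_id == "C1", -2]
  c2 <- ds$codings[ds$codings$coder_id == "C2", -2]
  rownames(c1) <- rownames(c2) <- NULL
  expect_identical(c1, c2)

  # prevalence pair (1, 1): flagged on every ad
  ap <- default_appeal_prevalence()
  ap[ap$appeal_type == "senses", c("p_high_in", "p_not_high_in")] <- 1
  ds <- simulate_dataset(small_config(seed = 6, appeal_prevalence = ap,
                                      coder_error_rate = 0))
  expect_true(all(ds$codings$senses == 1))

  # realized group prevalences near (0.458, 0.335) at n = 1000 ads
  config <- sim_config(seed = 77, n_unique_ads = 1000, instances_mean = 1,
                       instances_dispersion = 0, frac_high_in = 0.5)
  ds <- simulate_dataset(config)
  verd <- classify_products(ds$products)
  high_of <- setNames(verd$high_in, verd$product_id)
  ua <- group_unique(ds$airings)
  ad_high <- vapply(strsplit(ua$product_ids, ";"),
                    function(p) any(high_of[p]), logical(1))
  c1 <- ds$codings[ds$codings$coder_id == "C1", ]
  c1 <- c1[match(ua$ad_id, c1$ad_id), ]
  expect_lt(abs(mean(c1$senses[ad_high]) - 0.458), 0.04)
  expect_lt(abs(mean(c1$senses[!ad_high]) - 0.335), 0.04)

  # unknown appeal type in the prevalence map errors with the valid list
  ap <- rbind(default_appeal_prevalence(),
              data.frame(appeal_type = "sparkle", p_high_in = 0.5,
                         p_not_high_in = 0.5))
  cfg <- small_config(seed = 6)
  cfg$appeal_prevalence <- ap
  expect_error(simulate_codings(cfg, ua, ds$products), "sparkle.*senses")
})
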