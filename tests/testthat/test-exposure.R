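test_that("group_unique collapses instances and merges duration versions", {
  ins <- rbind(
    make_instances("A", rating_overall = c(0.5, 1.5, 1.0),
                   timestamp = paste0("2017-01-0", 1:3, " 10:00:00")),
    make_instances("B", rating_overall = c(2, 4),
                   timestamp = paste0("2017-02-0", 1:2, " 12:00:00")))
  ua <- group_unique(ins)
  expect_equal(nrow(ua), 2L)
  expect_equal(ua$n_instances, c(3L, 2L))
  expect_equal(ua$avg_rating_overall, c(1.0, 3.0))

  # two versions differing in duration merge; extended = longest
  ins <- rbind(
    make_instances("A", version_id = "A_v1", duration = 15,
                   rating_overall = c(1, 1)),
    make_instances("A", version_id = "A_v2", duration = 30,
                   rating_overall = c(2, 2)))
  ua <- group_unique(ins)
  expect_equal(nrow(ua), 1L)
  expect_equal(ua$n_instances, 4L)
  expect_equal(ua$extended_version_id, "A_v2")
  expect_equal(ua$extended_duration, 30)
  expect_equal(ua$avg_rating_overall, 1.5)
})

test_that("group_unique unions product ids and rejects bad input", {
  ins <- rbind(make_instances("A", product_ids = "P2;P1"),
               make_instances("A", product_ids = "P1;P3"))
  expect_equal(group_unique(ins)$product_ids, "P1;P2;P3")
  expect_error(group_unique(data.frame()), "empty")
  ins$rating_overall[2] <- NA
  expect_error(group_unique(ins), "A")
})

test_that("weekly_impressions matches the definition and the zero case", {
  expect_equal(weekly_impressions(1.0, 2470700, 52), 24707)
  expect_equal(weekly_impressions(0, 1235350, 17), 0)
  expect_error(weekly_impressions(-1, 100, 1), "avg_rating")
})

test_that("average-form weekly impressions equal the instance-sum oracle", {
  set.seed(42)
  for (i in 1:1000) {
    n_inst <- sample(1:300, 1)
    ratings <- runif(n_inst, 0, 5)
    pop <- sample(c(444726, 938866, 1235350, 2470700), 1)
    avg_form <- weekly_impressions(mean(ratings), pop, n_inst)
    oracle <- sum(ratings / 100 * pop) / 52
    expect_equal(avg_form, oracle, tolerance = 1e-9)
  }
})

test_that("select_top_fraction selects, breaks ties deterministically, is idempotent", {
  ua <- data.frame(ad_id = sprintf("AD%03d", 1:100), n_instances = 1L,
                   product_ids = "P1", avg_rating_overall = 1,
                   wi_overall = sample(1:100))
  sel <- select_top_fraction(ua, 0.2, "overall")
  expect_equal(sel$report$n_selected, 20L)
  expect_setequal(sel$selected$wi_overall, 81:100)
  expect_equal(sel$report$threshold_impressions, 81)

  all10 <- select_top_fraction(ua[1:10, ], 1.0, "overall")
  expect_equal(nrow(all10$selected), 10L)
  resel <- select_top_fraction(all10$selected, 1.0, "overall")
  expect_equal(resel$selected, all10$selected)

  # boundary ties break by ascending ad_id
  ua$wi_overall <- rep(1, 100)
  sel <- select_top_fraction(ua, 0.1, "overall")
  expect_equal(sel$selected$ad_id, sprintf("AD%03d", 1:10))

  expect_error(select_top_fraction(ua, 0), "fraction")
  expect_error(select_top_fraction(ua, 1.2), "fraction")
  expect_error(select_top_fraction(ua[, setdiff(names(ua), "wi_overall")], 0.2),
               "wi_overall")
})

test_that("apply_sample_filters removes by category, availability and nutrition", {
  ads <- data.frame(
    ad_id = c("A1", "A2", "A3", "A4", "A5"),
    product_ids = c("P1;P2", "P3", "P4", "P5;P6", "P7"),
    stringsAsFactors = FALSE)
  categories <- data.frame(
    product_id = sprintf("P%d", 1:7),
    category = c("food", "food", "alcoholic_beverage", "cooking_ingredient",
                 "food", "food", "food"),
    available = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  nutrition <- make_product(product_id = c("P1", "P2", "P5"))
  # A2 lacks nutrition for P3 but survives category? No: P3 is alcoholic ->
  # A2 dropped at category stage. A3 all cooking-ingredient -> dropped.
  # A5 unavailable -> dropped. A4 lacks nutrition for P5? P5 has a record,
  # P6 does not -> dropped at nutrition stage.
  res <- apply_sample_filters(ads, nutrition, categories)
  expect_equal(res$final_ads$ad_id, "A1")
  expect_equal(res$final_products,
               data.frame(ad_id = c("A1", "A1"), product_id = c("P1", "P2"),
                          stringsAsFactors = FALSE))
  expect_equal(res$report$n_selected, 5L)
  expect_equal(res$report$n_after_category_filter, 3L)
  expect_equal(res$report$n_available_for_purchase, 2L)
  expect_equal(res$report$n_excluded_no_nutrition, 1L)
  expect_equal(res$report$n_final_ads, 1L)
  expect_setequal(res$removals$reason[res$removals$ad_id == "A5"],
                  "not_available_for_purchase")

  # empty exclusion sets: identity
  categories$category <- "food"
  categories$available <- TRUE
  nutrition <- make_product(product_id = sprintf("P%d", 1:7))
  res <- apply_sample_filters(ads, nutrition, categories)
  expect_equal(res$final_ads, ads)
  expect_equal(res$report$n_final_ads, 5L)
  expect_equal(res$report$n_final_products, 7L)
  expect_equal(nrow(res$removals), 0L)
})

test_that("selection report arithmetic invariants hold on random fixtures", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    ua <- data.frame(ad_id = sprintf("AD%03d", 1:n),
                     product_ids = sprintf("P%03d", 1:n),
                     n_instances = 1L, wi_overall = runif(n))
    f <- runif(1, 0.05, 1)
    sel <- select_top_fraction(ua, f, "overall")
    expect_equal(sel$report$n_selected, floor(f * n))
    expect_equal(nrow(sel$selected), sel$report$n_selected)
    if (sel$report$n_selected > 0 && sel$report$n_selected < n) {
      unsel <- setdiff(ua$ad_id, sel$selected$ad_id)
      expect_true(min(sel$selected$wi_overall) >=
                    max(ua$wi_overall[ua$ad_id %in% unsel]))
    }
  }
})
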