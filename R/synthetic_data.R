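# Seeded synthetic-data generator.
#
# Emulates the three proprietary inputs of a televised food-marketing
# monitoring study -- instance-level airing logs with per-stratum audience
# rating points, label-derived product nutrition tables, and two-coder
# presence/absence appeal codings -- with the statistical structure the
# downstream analysis assumes: heavy-tailed airing counts (few ads air very
# often, so a "top 20%" is meaningful), a multiplicative female/male
# exposure gap, a socio-economic exposure gradient, a configurable fraction
# of "high-in" products, and appeal prevalences that differ between ads
# promoting high-in and not-high-in products.

#' Default appeal prevalence pairs
#'
#' Per appeal type, the probability that coder 1 flags the type on an ad
#' promoting at least one high-in product vs an ad promoting none. The
#' senses / cartoons / positive-emotions values reproduce published
#' monitoring prevalences for the most common emotional appeals; the
#' remaining pairs are calibrated analytically (under independence across
#' types) so that the any-emotional prevalence is 89.3% / 74.9% and the
#' any-rational prevalence 57.7% in the two groups, with rational pairs
#' equal across groups. Derivations in the methods vignette.
#'
#' @return data.frame: `appeal_type`, `p_high_in`, `p_not_high_in`.
#' @export
default_appeal_prevalence <- function() {
  data.frame(
    appeal_type = c("senses", "cartoons", "positive_emotions", "fun", "characters",
                    "health", "nutrition", "freshness", "ingredients", "quality"),
    p_high_in = c(0.458, 0.288, 0.318, 0.362, 0.362, rep(0.158, 5L)),
    p_not_high_in = c(0.335, 0.212, 0.215, 0.219, 0.219, rep(0.158, 5L)),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic-data generator. The
#' defaults state the emulated world: 500 unique ads, log-normal airing
#' counts (mean 204 instances per ad, matching roughly 600k instances per
#' 3000 unique ads in real year-long logs), mean rating 0.5 points, a
#' female/male exposure ratio of 1.2, a decreasing SES exposure gradient
#' (1.5 / 1.0 / 0.6), 77.6% of products high-in, and a 3% coder bit-flip
#' rate for the second coder.
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @param n_unique_ads number of unique ads.
#' @param instances_mean,instances_dispersion mean and log-scale dispersion
#'   of the per-ad airing-count distribution (`ceiling` of a log-normal;
#'   dispersion 0 forces every count to `ceiling(instances_mean)`).
#' @param rating_base mean rating points per instance (1 point = 1% of the
#'   stratum audience).
#' @param rating_ad_sdlog,rating_instance_sdlog,stratum_noise_sdlog
#'   log-normal spreads of between-ad, within-ad and per-stratum rating
#'   noise.
#' @param gender_gap multiplicative female/male exposure ratio (> 0).
#' @param ses_gradient positive multipliers `c(low, mid, high)`.
#' @param frac_high_in fraction of products classified high-in, in \[0, 1\].
#' @param appeal_prevalence data.frame `appeal_type`, `p_high_in`,
#'   `p_not_high_in` (see [default_appeal_prevalence()]).
#' @param products_per_ad probabilities for 1, 2 or 3 products per ad.
#' @param populations population table (female + male must equal overall).
#' @param coder_error_rate probability coder 2 flips any single flag.
#' @param year analysis year for timestamps.
#' @param window daily sampling window in hours, `c(start, end)`.
#' @param version_two_prob probability an ad has a short and an extended
#'   cut (15 s / 30 s) rather than a single version.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_unique_ads = 500L,
                       instances_mean = 204,
                       instances_dispersion = 1.0,
                       rating_base = 0.5,
                       rating_ad_sdlog = 0.6,
                       rating_instance_sdlog = 0.4,
                       stratum_noise_sdlog = 0.1,
                       gender_gap = 1.2,
                       ses_gradient = c(low = 1.5, mid = 1.0, high = 0.6),
                       frac_high_in = 0.776,
                       appeal_prevalence = default_appeal_prevalence(),
                       products_per_ad = c(`1` = 0.35, `2` = 0.40, `3` = 0.25),
                       populations = default_populations(),
                       coder_error_rate = 0.03,
                       year = 2017L,
                       window = c(6L, 22L),
                       version_two_prob = 0.25) {
  config <- list(
    seed = seed, n_unique_ads = n_unique_ads,
    instances_mean = instances_mean, instances_dispersion = instances_dispersion,
    rating_base = rating_base, rating_ad_sdlog = rating_ad_sdlog,
    rating_instance_sdlog = rating_instance_sdlog,
    stratum_noise_sdlog = stratum_noise_sdlog,
    gender_gap = gender_gap, ses_gradient = ses_gradient,
    frac_high_in = frac_high_in, appeal_prevalence = appeal_prevalence,
    products_per_ad = products_per_ad, populations = populations,
    coder_error_rate = coder_error_rate, year = year, window = window,
    version_two_prob = version_two_prob)
  class(config) <- "sim_config"
  validate_sim_config(config)
  config
}

#' Validate a simulation configuration
#'
#' @param config a `sim_config` list.
#' @return The config, invisibly; otherwise a validation error naming the
#'   offending field.
#' @export
validate_sim_config <- function(config) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) abort_validation("sim_config$", field, ": ", msg)
  }
  chk(is.numeric(config$seed) && length(config$seed) == 1L &&
        is.finite(config$seed) && config$seed == round(config$seed),
      "seed", "must be a single integer")
  chk(is.numeric(config$n_unique_ads) && config$n_unique_ads >= 1 &&
        config$n_unique_ads == round(config$n_unique_ads),
      "n_unique_ads", "must be a positive integer")
  chk(is.numeric(config$instances_mean) && config$instances_mean > 0,
      "instances_mean", "must be > 0")
  chk(is.numeric(config$instances_dispersion) && config$instances_dispersion >= 0,
      "instances_dispersion", "must be >= 0")
  chk(is.numeric(config$rating_base) && config$rating_base > 0,
      "rating_base", "must be > 0")
  for (f in c("rating_ad_sdlog", "rating_instance_sdlog", "stratum_noise_sdlog")) {
    chk(is.numeric(config[[f]]) && config[[f]] >= 0, f, "must be >= 0")
  }
  chk(is.numeric(config$gender_gap) && config$gender_gap > 0,
      "gender_gap", "must be > 0")
  chk(is.numeric(config$ses_gradient) && length(config$ses_gradient) == 3L &&
        all(config$ses_gradient > 0),
      "ses_gradient", "must be three positive multipliers (low, mid, high)")
  chk(is.numeric(config$frac_high_in) && config$frac_high_in >= 0 &&
        config$frac_high_in <= 1,
      "frac_high_in", "must be in [0, 1]")
  ap <- config$appeal_prevalence
  chk(is.data.frame(ap) &&
        all(c("appeal_type", "p_high_in", "p_not_high_in") %in% names(ap)),
      "appeal_prevalence", "needs columns appeal_type, p_high_in, p_not_high_in")
  chk(all(ap$p_high_in >= 0 & ap$p_high_in <= 1 &
            ap$p_not_high_in >= 0 & ap$p_not_high_in <= 1),
      "appeal_prevalence", "probabilities must be in [0, 1]")
  chk(is.numeric(config$products_per_ad) && length(config$products_per_ad) == 3L &&
        all(config$products_per_ad >= 0) && sum(config$products_per_ad) > 0,
      "products_per_ad", "must be three non-negative weights for 1/2/3 products")
  validate_populations(config$populations)
  chk(is.numeric(config$coder_error_rate) && config$coder_error_rate >= 0 &&
        config$coder_error_rate <= 1,
      "coder_error_rate", "must be in [0, 1]")
  chk(is.numeric(config$window) && length(config$window) == 2L &&
        config$window[1] < config$window[2] &&
        config$window[1] >= 0 && config$window[2] <= 24,
      "window", "must be c(start, end) hours with start < end within 0..24")
  chk(is.numeric(config$version_two_prob) && config$version_two_prob >= 0 &&
        config$version_two_prob <= 1,
      "version_two_prob", "must be in [0, 1]")
  invisible(config)
}

# per-ad product-id lists, deterministic given the RNG state
draw_products_per_ad <- function(config) {
  n <- config$n_unique_ads
  k <- sample(1:3, n, replace = TRUE,
              prob = config$products_per_ad / sum(config$products_per_ad))
  total <- sum(k)
  ids <- sprintf("PR%05d", seq_len(total))
  split(ids, rep(seq_len(n), k))
}

#' Simulate a year of airing instances
#'
#' One row per airing of one ad version: timestamps uniform over the year
#' inside the daily sampling window, per-ad airing counts from a ceiling'd
#' log-normal (heavy tail), and per-stratum rating points drawn around
#' `rating_base` scaled by `gender_gap` and `ses_gradient`. The overall
#' rating is the population-weighted combination of the female and male
#' ratings, so the gender split is internally consistent.
#'
#' @param config a [sim_config()].
#' @return data.frame of airing instances: `ad_id`, `version_id`,
#'   `timestamp`, `duration`, `channel`, `program`, `product_ids` and the
#'   six `rating_<stratum>` columns.
#' @export
simulate_airings <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_unique_ads)
  ad_id <- sprintf("AD%05d", seq_len(n))

  # product universe drawn first so simulate_products() can re-derive it
  # from the seed alone
  prods <- draw_products_per_ad(config)
  prod_str <- vapply(prods, paste, character(1), collapse = ";")

  mu <- log(config$instances_mean) - config$instances_dispersion^2 / 2
  n_inst <- as.integer(ceiling(rlnorm(n, mu, config$instances_dispersion)))
  n_inst <- pmax(n_inst, 1L)

  m_ad <- rlnorm(n, log(config$rating_base) - config$rating_ad_sdlog^2 / 2,
                 config$rating_ad_sdlog)
  two_ver <- runif(n) < config$version_two_prob
  base_dur <- sample(c(10, 15, 20, 30), n, replace = TRUE)

  idx <- rep(seq_len(n), n_inst)
  n_total <- length(idx)
  # version of each instance: extended (30 s) or short (15 s) cut for
  # two-version ads, the single cut otherwise
  ver_no <- ifelse(two_ver[idx], 1L + (runif(n_total) < 0.5), 1L)
  duration <- ifelse(two_ver[idx], c(15, 30)[ver_no], base_dur[idx])
  version_id <- paste0(ad_id[idx], "_v", ver_no)

  r <- m_ad[idx] * rlnorm(n_total, -config$rating_instance_sdlog^2 / 2,
                          config$rating_instance_sdlog)
  s <- config$stratum_noise_sdlog
  noise <- function() rlnorm(n_total, -s^2 / 2, s)
  gap <- config$gender_gap
  g_f <- 2 * gap / (1 + gap)
  g_m <- 2 / (1 + gap)
  rating_female <- r * g_f * noise()
  rating_male <- r * g_m * noise()
  pop <- setNames(config$populations$population, config$populations$stratum)
  rating_overall <- (rating_female * pop[["female"]] + rating_male * pop[["male"]]) /
    pop[["overall"]]
  ses <- config$ses_gradient
  rating_ses_low <- r * ses[[1]] * noise()
  rating_ses_mid <- r * ses[[2]] * noise()
  rating_ses_high <- r * ses[[3]] * noise()

  days_in_year <- as.integer(as.Date(paste0(config$year + 1L, "-01-01")) -
                               as.Date(paste0(config$year, "-01-01")))
  day <- sample.int(days_in_year, n_total, replace = TRUE) - 1L
  w <- config$window
  secs <- w[1] * 3600 + floor(runif(n_total) * (w[2] - w[1]) * 3600)
  stamp <- as.POSIXct(paste0(config$year, "-01-01"), tz = "UTC") +
    day * 86400 + secs
  timestamp <- format(stamp, "%Y-%m-%d %H:%M:%S")

  out <- data.frame(
    ad_id = ad_id[idx],
    version_id = version_id,
    timestamp = timestamp,
    duration = duration,
    channel = sample(sprintf("CH%02d", 1:15), n_total, replace = TRUE),
    program = sample(sprintf("PRG%03d", 1:80), n_total, replace = TRUE),
    product_ids = prod_str[idx],
    rating_overall = rating_overall,
    rating_female = rating_female,
    rating_male = rating_male,
    rating_ses_low = rating_ses_low,
    rating_ses_mid = rating_ses_mid,
    rating_ses_high = rating_ses_high,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$ad_id, out$timestamp, out$version_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a product nutrition table
#'
#' Each product is targeted high-in with probability `frac_high_in` and its
#' nutrient amounts are constructed to sit on the intended side of every
#' PAHO threshold; the realized labels are then verified by running
#' [classify_products()] (the generator never bypasses the classifier).
#' High-in products are processed/ultra-processed with at least one firing
#' criterion; not-high-in products are either outside the model's scope
#' (unprocessed / culinary) or applicable with every criterion below
#' threshold.
#'
#' When the product universe is derived from the config (the default), the
#' high-in target is drawn once per ad and shared by all its products:
#' products promoted together come from the same brand line and share
#' formulation, and this within-ad clustering is what makes the ad-level
#' coding prevalences visible in product-level contrasts. Explicitly
#' supplied `product_ids` carry no ad grouping, so targets are then drawn
#' independently per product.
#'
#' @param config a [sim_config()].
#' @param product_ids ids to generate; defaults to the product universe of
#'   [simulate_airings()] under the same config (re-derived
#'   deterministically, with its ad grouping).
#' @return data.frame in the nutrition-table schema accepted by
#'   [classify_products()].
#' @export
simulate_products <- function(config, product_ids = NULL) {
  validate_sim_config(config)
  if (is.null(product_ids)) {
    # the airing generator draws the product universe first, so replaying
    # that single draw under the same seed recovers the same ids
    set.seed(config$seed)
    groups <- draw_products_per_ad(config)
    product_ids <- unlist(groups, use.names = FALSE)
    gidx <- rep(seq_along(groups), lengths(groups))
  } else {
    gidx <- seq_along(product_ids)
  }
  set.seed(config$seed + 1L)
  n <- length(product_ids)
  target <- (runif(max(gidx)) < config$frac_high_in)[gidx]

  ru <- function(lo, hi) runif(n, lo, hi)
  rb <- function(p) runif(n) < p

  # processing category
  cat_hi <- ifelse(rb(0.8), "ultra_processed", "processed")
  u <- runif(n)
  cat_lo <- ifelse(u < 0.30, "unprocessed_minimally_processed",
                   ifelse(u < 0.35, "culinary_ingredient",
                          ifelse(u < 0.70, "processed", "ultra_processed")))
  category <- ifelse(target, cat_hi, cat_lo)
  applicable <- category %in% PAHO_APPLICABLE

  energy <- ifelse(target, ru(80, 500), ru(30, 400))

  # which criteria fire for high-in products (at least one forced)
  f_sugar <- rb(0.6); f_fat <- rb(0.4); f_sat <- rb(0.3)
  f_trans <- rb(0.1); f_sodium <- rb(0.35); f_sweet <- rb(0.25)
  none <- !(f_sugar | f_fat | f_sat | f_trans | f_sodium | f_sweet)
  f_sugar[none] <- TRUE
  fire <- function(f) target & f

  sugar_frac <- ifelse(fire(f_sugar), ru(0.10, 0.55), ru(0, 0.095))
  sat_frac <- ifelse(fire(f_sat), ru(0.10, 0.25), ru(0, 0.08))
  trans_frac <- ifelse(fire(f_trans), ru(0.01, 0.03), ru(0, 0.008))
  # total fat must cover saturated + trans without crossing 30% uninvited:
  # the non-firing draw floors at sat+trans (max 28% energy < 30%)
  fat_frac_raw <- ifelse(fire(f_fat), ru(0.30, 0.60), ru(0, 0.29))
  fat_frac <- pmax(fat_frac_raw, sat_frac + trans_frac)
  sodium_per_kcal <- ifelse(fire(f_sodium), ru(1, 3), ru(0, 0.9))
  sweet <- fire(f_sweet)

  # out-of-scope products keep modest, unconstrained-looking label values
  sugar_frac[!applicable] <- ru(0, 0.3)[!applicable]
  fat_frac[!applicable] <- ru(0, 0.4)[!applicable]
  sat_frac[!applicable] <- (fat_frac * ru(0, 0.5))[!applicable]
  trans_frac[!applicable] <- 0
  sodium_per_kcal[!applicable] <- ru(0, 1.5)[!applicable]
  sweet[!applicable] <- FALSE

  nutrition <- data.frame(
    product_id = product_ids,
    energy_kcal = energy,
    free_sugars_g = sugar_frac * energy / KCAL_PER_G_SUGAR,
    total_fat_g = fat_frac * energy / KCAL_PER_G_FAT,
    saturated_fat_g = sat_frac * energy / KCAL_PER_G_FAT,
    trans_fat_g = trans_frac * energy / KCAL_PER_G_FAT,
    sodium_mg = sodium_per_kcal * energy,
    has_noncaloric_sweetener = sweet,
    processing_category = category,
    stringsAsFactors = FALSE
  )
  verdict <- classify_products(nutrition)
  if (!all(verdict$high_in == target)) {
    stop("simulate_products: internal error - constructed nutrients disagree ",
         "with the classifier for ",
         sum(verdict$high_in != target), " products")
  }
  nutrition
}

#' Simulate two coders' appeal codings
#'
#' Coder 1's presence/absence flags are Bernoulli draws whose probability
#' per appeal type depends on whether the ad promotes at least one high-in
#' product (per [classify_products()] on the supplied nutrition table).
#' Coder 2 equals coder 1 with every flag independently flipped with
#' probability `coder_error_rate` -- the simplest disagreement model with a
#' tunable kappa.
#'
#' @param config a [sim_config()].
#' @param ads airing table or unique-ads table (needs `ad_id` and
#'   `product_ids`; airing tables are grouped with [group_unique()]).
#' @param products nutrition table for the ads' products.
#' @param codebook appeal-type codebook the prevalence map must live in.
#' @return data.frame: `ad_id`, `coder_id` ("C1"/"C2") and one 0/1 column
#'   per appeal type.
#' @export
simulate_codings <- function(config, ads, products, codebook = default_codebook()) {
  validate_sim_config(config)
  ap <- config$appeal_prevalence
  unknown <- setdiff(ap$appeal_type, codebook$appeal_type)
  if (length(unknown)) {
    abort_validation("appeal_prevalence: unknown appeal types: ",
                     paste(unknown, collapse = ", "),
                     " (valid: ", paste(codebook$appeal_type, collapse = ", "), ")")
  }
  if (anyDuplicated(ads$ad_id)) ads <- group_unique(ads)
  verdict <- classify_products(products)
  high_of <- setNames(verdict$high_in, verdict$product_id)
  ad_high <- vapply(split_product_ids(ads$product_ids),
                    function(p) any(high_of[p], na.rm = TRUE), logical(1))

  set.seed(config$seed + 2L)
  n <- nrow(ads)
  flags1 <- sapply(seq_len(nrow(ap)), function(j) {
    p <- ifelse(ad_high, ap$p_high_in[j], ap$p_not_high_in[j])
    as.integer(runif(n) < p)
  })
  flags1 <- matrix(flags1, nrow = n,
                   dimnames = list(NULL, ap$appeal_type))
  flips <- matrix(runif(n * nrow(ap)) < config$coder_error_rate, nrow = n)
  flags2 <- 1L * xor(flags1 == 1L, flips)

  mk <- function(coder, m) {
    cbind(data.frame(ad_id = ads$ad_id, coder_id = coder,
                     stringsAsFactors = FALSE),
          as.data.frame(m))
  }
  out <- rbind(mk("C1", flags1), mk("C2", flags2))
  out <- out[order(out$coder_id, out$ad_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate the full input bundle
#'
#' Convenience orchestration: airings, the matching nutrition table, and
#' both coders' codings under one config.
#'
#' @param config a [sim_config()].
#' @param codebook appeal-type codebook.
#' @return list: `airings`, `products`, `codings`, `populations`,
#'   `codebook`, `config`.
#' @export
simulate_dataset <- function(config, codebook = default_codebook()) {
  airings <- simulate_airings(config)
  products <- simulate_products(config)  # same universe, re-derived from seed
  airing_pids <- unique(unlist(split_product_ids(
    airings$product_ids[!duplicated(airings$ad_id)]), use.names = FALSE))
  stopifnot(setequal(products$product_id, airing_pids))
  codings <- simulate_codings(config, airings, products, codebook)
  list(airings = airings, products = products, codings = codings,
       populations = config$populations, codebook = codebook, config = config)
}

#' Null-world configuration for calibration studies
#'
#' A deliberately null stated world for checking the type-I error of every
#' test the pipeline runs: equal appeal prevalences across groups and
#' strategies (0.3 everywhere, five types per strategy), gender gap 1, flat
#' SES gradient, a gender-symmetric population table, balanced high-in
#' fraction (0.5), no coder noise, and small sizes so a thousand replicates
#' fit a desktop CPU budget.
#'
#' @param seed integer seed.
#' @param n_unique_ads ads per replicate (default 120).
#' @return A `sim_config`.
#' @export
null_sim_config <- function(seed = 1L, n_unique_ads = 120L) {
  ap <- default_appeal_prevalence()
  ap$p_high_in <- 0.3
  ap$p_not_high_in <- 0.3
  pops <- data.frame(
    stratum = ADMARK_STRATA,
    population = c(2000000, 1000000, 1000000, 800000, 700000, 500000),
    stringsAsFactors = FALSE
  )
  sim_config(
    seed = seed, n_unique_ads = n_unique_ads,
    instances_mean = 8, instances_dispersion = 0.5,
    rating_base = 0.5, rating_ad_sdlog = 0.4, rating_instance_sdlog = 0.3,
    stratum_noise_sdlog = 0.1,
    gender_gap = 1, ses_gradient = c(low = 1, mid = 1, high = 1),
    frac_high_in = 0.5, appeal_prevalence = ap,
    coder_error_rate = 0, populations = pops
  )
}
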