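# Independent oracles for the statistical machinery. These deliberately use
# different algorithms than the package (distribution convolution and
# bitmask subset enumeration vs the package's sign-matrix / combn paths).

# exact null distribution of the signed-rank statistic by convolution over
# doubled ranks (doubling makes mid-ranks integral); returns p-value
oracle_signed_rank_p <- function(x, y, alternative = "two.sided") {
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) return(1)
  r <- rank(abs(d))
  v2 <- round(2 * sum(r[d > 0]))
  r2 <- round(2 * r)
  dist <- c(1)  # dist[k+1] = P(2*T == k), support starts at 0
  for (w in r2) {
    grown <- c(dist, rep(0, w))
    shifted <- c(rep(0, w), dist)
    dist <- (grown + shifted) / 2
  }
  support <- seq_along(dist) - 1L
  p_ge <- sum(dist[support >= v2])
  p_le <- sum(dist[support <= v2])
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

popcount <- function(x) {
  n <- integer(length(x))
  while (any(x > 0)) {
    n <- n + (x %% 2L)
    x <- x %/% 2L
  }
  n
}

# exact permutation p-value for the Mann-Whitney U statistic by bitmask
# enumeration of group-label assignments
oracle_mw_p <- function(a, b, alternative = "two.sided") {
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  masks <- 0:(2^n - 1L)
  masks <- masks[popcount(masks) == n_a]
  u_all <- vapply(masks, function(m) {
    sel <- which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) > 0L)
    sum(r[sel]) - n_a * (n_a + 1) / 2
  }, numeric(1))
  eps <- 1e-9
  p_ge <- mean(u_all >= u_obs - eps)
  p_le <- mean(u_all <= u_obs + eps)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

# minimal airing-table builder for exposure tests
make_instances <- function(ad_id, version_id = paste0(ad_id, "_v1"),
                           duration = 20, rating_overall = 1,
                           product_ids = "P1", timestamp = "2017-06-01 10:00:00",
                           ...) {
  data.frame(ad_id = ad_id, version_id = version_id, timestamp = timestamp,
             duration = duration, channel = "CH01", program = "PRG001",
             product_ids = product_ids, rating_overall = rating_overall,
             ..., stringsAsFactors = FALSE)
}

# one fully-specified nutrition row; override what the case needs
make_product <- function(product_id = "P1", energy_kcal = 400,
                         free_sugars_g = 0, total_fat_g = 0,
                         saturated_fat_g = 0, trans_fat_g = 0, sodium_mg = 0,
                         has_noncaloric_sweetener = FALSE,
                         processing_category = "ultra_processed") {
  data.frame(product_id = product_id, energy_kcal = energy_kcal,
             free_sugars_g = free_sugars_g, total_fat_g = total_fat_g,
             saturated_fat_g = saturated_fat_g, trans_fat_g = trans_fat_g,
             sodium_mg = sodium_mg,
             has_noncaloric_sweetener = has_noncaloric_sweetener,
             processing_category = processing_category,
             stringsAsFactors = FALSE)
}

# small, fast generator config for unit tests
small_config <- function(seed = 1L, n_unique_ads = 50L, ...) {
  sim_config(seed = seed, n_unique_ads = n_unique_ads, instances_mean = 5,
             instances_dispersion = 0.5, ...)
}
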