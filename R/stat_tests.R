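# Nonparametric and paired tests used by the analysis stage.
#
# Conventions (documented, since source reports are silent on them):
#  * Wilcoxon signed-rank: zero differences discarded (classical), absolute
#    differences mid-ranked on ties; statistic V = sum of positive-difference
#    ranks. Exact sign-flip enumeration when the number of nonzero pairs is
#    <= 12, otherwise normal approximation with tie correction, no
#    continuity correction.
#  * Mann-Whitney: mid-ranks; statistic U for the first group. Exact label
#    permutation when n_a + n_b <= 14, otherwise tie-corrected normal
#    approximation.
#  * Two-sided p-values are 2 * min(lower tail, upper tail), capped at 1
#    (both null distributions here are symmetric, so this matches the
#    symmetric-tail convention).
#  * Paired t: classical mean(d) / (sd(d)/sqrt(n)) with n - 1 df.

new_test_result <- function(test, statistic, z = NA_real_, p_value,
                            estimates = list(), n = integer(),
                            method = NA_character_, degenerate = NA_character_) {
  structure(
    list(test = test, statistic = statistic, z = z, p_value = p_value,
         estimates = estimates, n = n, method = method, degenerate = degenerate),
    class = "admark_test")
}

#' @export
print.admark_test <- function(x, ...) {
  cat(x$test, "\n")
  cat("  statistic =", format(x$statistic), " z =", format(x$z),
      " p =", format.pval(x$p_value), "\n")
  if (length(x$estimates)) {
    cat("  ", paste(names(x$estimates), "=",
                    vapply(x$estimates, function(e) format(e, digits = 6), ""),
                    collapse = ", "), "\n")
  }
  cat("  n =", paste(x$n, collapse = "/"), " method =", x$method,
      if (!is.na(x$degenerate)) paste0(" [", x$degenerate, "]") else "", "\n")
  invisible(x)
}

two_sided_p <- function(p_le, p_ge) min(1, 2 * min(p_le, p_ge))

# exact distribution of the signed-rank statistic by full enumeration of the
# 2^n sign assignments over the (possibly tied, mid-ranked) ranks
signed_rank_exact_p <- function(ranks, v_obs, alternative) {
  n <- length(ranks)
  m <- 2L^n
  signs <- matrix(0L, nrow = m, ncol = n)
  for (j in seq_len(n)) {
    signs[, j] <- bitwAnd(seq_len(m) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }
  t_all <- as.numeric(signs %*% ranks)
  eps <- 1e-9
  p_ge <- mean(t_all >= v_obs - eps)
  p_le <- mean(t_all <= v_obs + eps)
  switch(alternative,
         two.sided = two_sided_p(p_le, p_ge),
         greater = p_ge,
         less = p_le)
}

#' Wilcoxon signed-rank test for paired ordinal scores
#'
#' Compares paired scores (e.g. a product's emotional vs rational appeal
#' variety). Zero differences are discarded; absolute differences are
#' mid-ranked on ties. With at most `exact_max_n` nonzero pairs the p-value
#' comes from full enumeration of sign assignments; beyond that from the
#' tie-corrected normal approximation. An input with no nonzero differences
#' returns a degenerate result with p = 1.
#'
#' @param x,y equal-length numeric vectors of paired scores.
#' @param alternative "two.sided" (default), "greater" (x tends above y) or
#'   "less".
#' @param exact_max_n largest number of nonzero pairs for the exact path
#'   (default 12).
#' @return An `admark_test` result: statistic V (sum of positive ranks), z
#'   (approximate path only), p-value, medians of `x` and `y`, pair counts.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1), alternative = "greater")
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("two.sided", "greater", "less"),
                                 exact_max_n = 12L) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) {
    abort_validation("wilcoxon_signed_rank: x and y differ in length")
  }
  if (!length(x)) abort_validation("wilcoxon_signed_rank: empty input")
  d <- x - y
  nz <- d != 0
  n_zero <- sum(!nz)
  d <- d[nz]
  n <- length(d)
  est <- list(median_x = median(x), median_y = median(y))
  if (n == 0L) {
    return(new_test_result("wilcoxon_signed_rank", statistic = 0, p_value = 1,
                           estimates = est, n = c(pairs = length(x), used = 0L),
                           method = "degenerate",
                           degenerate = "all_differences_zero"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max_n) {
    p <- signed_rank_exact_p(r, v, alternative)
    return(new_test_result("wilcoxon_signed_rank", statistic = v, p_value = p,
                           estimates = est, n = c(pairs = length(x), used = n),
                           method = "exact_enumeration"))
  }
  e_v <- n * (n + 1) / 4
  ties <- table(r)
  var_v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (v - e_v) / sqrt(var_v)
  p <- switch(alternative,
              two.sided = 2 * pnorm(-abs(z)),
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z))
  new_test_result("wilcoxon_signed_rank", statistic = v, z = z, p_value = p,
                  estimates = est, n = c(pairs = length(x), used = n),
                  method = "normal_tie_corrected")
}

mann_whitney_exact_p <- function(ranks, n_a, u_obs, alternative) {
  n <- length(ranks)
  offset <- n_a * (n_a + 1) / 2
  sel <- utils::combn(n, n_a)
  u_all <- colSums(matrix(ranks[sel], nrow = n_a)) - offset
  eps <- 1e-9
  p_ge <- mean(u_all >= u_obs - eps)
  p_le <- mean(u_all <= u_obs + eps)
  switch(alternative,
         two.sided = two_sided_p(p_le, p_ge),
         greater = p_ge,
         less = p_le)
}

#' Mann-Whitney U test for two independent groups of ordinal scores
#'
#' Compares score distributions between two groups (e.g. appeal variety for
#' high-in vs not-high-in products) using mid-ranks. With
#' `n_a + n_b <= exact_max_n` the p-value comes from full enumeration of
#' group-label assignments; otherwise from the tie-corrected normal
#' approximation.
#'
#' @param group_a,group_b numeric score vectors (both non-empty).
#' @param alternative "two.sided" (default), "greater" (`group_a` tends
#'   above `group_b`) or "less".
#' @param exact_max_n largest combined size for the exact path (default 14).
#' @return An `admark_test` result: statistic U (for `group_a`), z
#'   (approximate path only), p-value, group medians and sizes.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
mann_whitney_u <- function(group_a, group_b,
                           alternative = c("two.sided", "greater", "less"),
                           exact_max_n = 14L) {
  alternative <- match.arg(alternative)
  n_a <- length(group_a); n_b <- length(group_b)
  if (!n_a || !n_b) abort_validation("mann_whitney_u: both groups must be non-empty")
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  est <- list(median_a = median(group_a), median_b = median(group_b))
  n_tot <- n_a + n_b
  if (n_tot <= exact_max_n) {
    p <- mann_whitney_exact_p(r, n_a, u, alternative)
    return(new_test_result("mann_whitney_u", statistic = u, p_value = p,
                           estimates = est, n = c(a = n_a, b = n_b),
                           method = "exact_enumeration"))
  }
  e_u <- n_a * n_b / 2
  ties <- table(r)
  var_u <- n_a * n_b / 12 * (n_tot + 1 - sum(ties^3 - ties) / (n_tot * (n_tot - 1)))
  if (var_u <= 0) {
    return(new_test_result("mann_whitney_u", statistic = u, p_value = 1,
                           estimates = est, n = c(a = n_a, b = n_b),
                           method = "degenerate", degenerate = "all_values_tied"))
  }
  z <- (u - e_u) / sqrt(var_u)
  p <- switch(alternative,
              two.sided = 2 * pnorm(-abs(z)),
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z))
  new_test_result("mann_whitney_u", statistic = u, z = z, p_value = p,
                  estimates = est, n = c(a = n_a, b = n_b),
                  method = "normal_tie_corrected")
}

# classical paired t on two matched vectors; handles the two zero-variance
# degeneracies explicitly
paired_t <- function(a, b) {
  if (length(a) != length(b)) abort_validation("paired_t: unequal lengths")
  n <- length(a)
  if (!n) abort_validation("paired_t: empty input")
  d <- a - b
  est <- list(mean_a = mean(a), mean_b = mean(b), mean_diff = mean(d))
  if (n == 1L || sd(d) == 0) {
    if (all(d == 0)) {
      return(new_test_result("paired_t", statistic = 0, p_value = 1,
                             estimates = est, n = c(pairs = n),
                             method = "degenerate", degenerate = "identical"))
    }
    return(new_test_result("paired_t", statistic = sign(mean(d)) * Inf, p_value = 0,
                           estimates = est, n = c(pairs = n),
                           method = "degenerate", degenerate = "infinite_separation"))
  }
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  new_test_result("paired_t", statistic = t_stat, p_value = p,
                  estimates = est, n = c(pairs = n), method = "t")
}

#' Paired comparison of weekly impressions between two strata
#'
#' Restricts the unique-ads table to ads whose appeal variety for the given
#' strategy equals `variety_level`, then runs a paired t-test of per-ad
#' weekly impressions between the two audience strata. An empty stratum
#' (no ads at the requested level) yields an explicit empty result, not an
#' error.
#'
#' @param ads unique-ads table carrying `wi_<stratum>` columns (see
#'   [add_weekly_impressions()]) merged with variety scores
#'   (`emotional_variety`, `rational_variety`).
#' @param stratum_a,stratum_b stratum identifiers (see [admark_strata()]).
#' @param variety_level one of 0, 1, 2, 3, 4 or "4+" (4 and "4+" are the
#'   same capped level).
#' @param strategy "emotional" or "rational".
#' @return An `admark_test` result (degenerate marker "empty_stratum" with
#'   `p = NA` when no ads sit at the level).
#' @export
paired_exposure_test <- function(ads, stratum_a, stratum_b, variety_level,
                                 strategy = c("emotional", "rational")) {
  strategy <- match.arg(strategy)
  lvl <- if (identical(variety_level, "4+")) 4L else as.integer(variety_level)
  if (is.na(lvl) || lvl < 0L || lvl > 4L) {
    abort_validation("paired_exposure_test: variety_level must be 0..4 or '4+'")
  }
  vcol <- paste0(strategy, "_variety")
  ca <- paste0("wi_", stratum_a); cb <- paste0("wi_", stratum_b)
  for (cl in c(vcol, ca, cb)) {
    if (!cl %in% names(ads)) {
      abort_validation("paired_exposure_test: ads table lacks column '", cl, "'")
    }
  }
  sel <- ads[[vcol]] == lvl
  if (!any(sel)) {
    return(new_test_result("paired_t", statistic = NA_real_, p_value = NA_real_,
                           estimates = list(), n = c(pairs = 0L),
                           method = "degenerate", degenerate = "empty_stratum"))
  }
  res <- paired_t(ads[[ca]][sel], ads[[cb]][sel])
  res$test <- paste0("paired_exposure_", strategy, "_level", lvl, "_",
                     stratum_a, "_vs_", stratum_b)
  res
}
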