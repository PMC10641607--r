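# Intercoder reliability for presence/absence appeal coding:
# percent agreement and Cohen's kappa per appeal code.

#' Percent agreement between two coders
#'
#' @param flags1,flags2 equal-length binary (or categorical) vectors.
#' @return Percentage of positions where the coders agree, in \[0, 100\].
#' @export
#' @examples
#' percent_agreement(c(1, 1, 0, 0), c(1, 0, 0, 0))  # 75
percent_agreement <- function(flags1, flags2) {
  if (length(flags1) != length(flags2)) {
    abort_validation("percent_agreement: vectors differ in length (",
                     length(flags1), " vs ", length(flags2), ")")
  }
  if (!length(flags1)) abort_validation("percent_agreement: empty input")
  100 * mean(flags1 == flags2)
}

#' Cohen's kappa for two coders
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), where p_o is
#' the observed agreement proportion and p_e the expected agreement under
#' independent coding with each coder's marginal category frequencies.
#' When p_e = 1 (both coders used a single, identical category throughout)
#' kappa is undefined and `NA_real_` is returned: agreement on an
#' all-but-absent code carries no information, and collapsing the
#' degenerate case to 0 or 1 would misstate reliability for rare codes.
#'
#' @param flags1,flags2 equal-length binary (or categorical) vectors.
#' @return kappa in \[-1, 1\], or `NA_real_` when undefined.
#' @export
#' @examples
#' cohens_kappa(c(1, 1, 0, 0), c(1, 1, 0, 0))  # 1
cohens_kappa <- function(flags1, flags2) {
  if (length(flags1) != length(flags2)) {
    abort_validation("cohens_kappa: vectors differ in length (",
                     length(flags1), " vs ", length(flags2), ")")
  }
  n <- length(flags1)
  if (!n) abort_validation("cohens_kappa: empty input")
  p_o <- mean(flags1 == flags2)
  cats <- union(unique(flags1), unique(flags2))
  p_e <- sum(vapply(cats, function(cc) mean(flags1 == cc) * mean(flags2 == cc),
                    numeric(1)))
  if (p_e >= 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Intercoder reliability report across appeal codes
#'
#' Computes, per appeal code, the number of double-coded ads, percent
#' agreement, and Cohen's kappa, on a seeded random subsample of ads
#' (reliability assessments in content analysis are typically run on a
#' 10\%+ subsample rather than the full sample; the default floor of 59 ads
#' matches standard practice for this design).
#'
#' @param coder1,coder2 wide coding tables (`ad_id` + 0/1 appeal columns)
#'   covering the same ads.
#' @param codebook appeal-type codebook.
#' @param subsample fraction of ads to double-code (default 0.1); 1 uses
#'   every shared ad.
#' @param min_n lower bound on the subsample size (default 59).
#' @param seed integer seed for the subsample draw.
#' @return list with `per_code` (data.frame: `appeal_type`, `n_ads`,
#'   `percent_agreement`, `kappa`) and `summary` (min/max agreement and
#'   kappa across codes, NA-removed).
#' @export
reliability_report <- function(coder1, coder2, codebook = default_codebook(),
                               subsample = 0.1, min_n = 59L, seed = 1L) {
  flag_cols <- validate_codings(coder1, codebook)
  flag_cols2 <- validate_codings(coder2, codebook)
  if (!setequal(flag_cols, flag_cols2)) {
    abort_validation("reliability_report: coders carry different appeal columns")
  }
  if (!(subsample > 0 && subsample <= 1)) {
    abort_validation("reliability_report: subsample must be in (0, 1]")
  }
  shared <- intersect(coder1$ad_id, coder2$ad_id)
  if (!length(shared)) abort_validation("reliability_report: no shared ads")
  n_take <- min(length(shared), max(ceiling(subsample * length(shared)), min_n))
  set.seed(seed)
  take <- sort(sample(sort(shared), n_take))
  a <- coder1[match(take, coder1$ad_id), , drop = FALSE]
  b <- coder2[match(take, coder2$ad_id), , drop = FALSE]

  per_code <- data.frame(
    appeal_type = flag_cols,
    n_ads = n_take,
    percent_agreement = vapply(flag_cols, function(cl)
      percent_agreement(a[[cl]], b[[cl]]), numeric(1)),
    kappa = vapply(flag_cols, function(cl)
      cohens_kappa(a[[cl]], b[[cl]]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  kk <- per_code$kappa[!is.na(per_code$kappa)]
  list(
    per_code = per_code,
    summary = list(
      n_ads = n_take,
      agreement_min = min(per_code$percent_agreement),
      agreement_max = max(per_code$percent_agreement),
      kappa_min = if (length(kk)) min(kk) else NA_real_,
      kappa_max = if (length(kk)) max(kk) else NA_real_,
      n_kappa_undefined = sum(is.na(per_code$kappa))
    )
  )
}
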