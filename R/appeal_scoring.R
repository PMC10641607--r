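# Persuasive-appeal codebook and appeal-variety scoring.
#
# Appeal types partition into two persuasive strategies: emotional (the ad
# associates the product with senses, emotions, fun or characters) and
# rational (the ad states product attributes: health, nutrition, freshness,
# ingredients, quality). Coding is presence/absence per type per ad; the
# variety score per strategy is the number of distinct flagged types, capped
# at 4 (ordinal 0-4).

#' Default appeal-type codebook
#'
#' Ships the appeal-type names used by the default synthetic generator and
#' reporting: five emotional types (senses, cartoons, positive_emotions,
#' fun, characters) and five rational types (health, nutrition, freshness,
#' ingredients, quality). The definition texts are placeholders: the full
#' per-type definitions live in study codebooks and should be replaced by
#' the user for real coding work; definitions are payload, not logic.
#'
#' @return data.frame with columns `appeal_type`, `strategy`
#'   ("emotional"/"rational") and `definition`.
#' @export
default_codebook <- function() {
  data.frame(
    appeal_type = c("senses", "cartoons", "positive_emotions", "fun", "characters",
                    "health", "nutrition", "freshness", "ingredients", "quality"),
    strategy = rep(c("emotional", "rational"), each = 5L),
    definition = c(
      "References or depictions of taste, smell, texture or other senses (placeholder)",
      "Cartoon or animated characters, licensed or brand mascots (placeholder)",
      "Associations with happiness, excitement or other positive emotions (placeholder)",
      "Depictions of fun, play or adventure around consumption (placeholder)",
      "Child actors, celebrities or other appealing characters (placeholder)",
      "Claims about health advantages of consuming the product (placeholder)",
      "Claims about nutrient content or nutritional advantages (placeholder)",
      "Claims that the product or its ingredients are fresh (placeholder)",
      "Statements about the ingredients the product contains (placeholder)",
      "Claims about the quality of the product (placeholder)"
    ),
    stringsAsFactors = FALSE
  )
}

#' Validate a codebook
#'
#' @param codebook data.frame with columns `appeal_type`, `strategy`.
#' @return The codebook, invisibly.
#' @export
validate_codebook <- function(codebook) {
  if (!is.data.frame(codebook) ||
      !all(c("appeal_type", "strategy") %in% names(codebook))) {
    abort_validation("codebook: need columns 'appeal_type' and 'strategy'")
  }
  if (anyDuplicated(codebook$appeal_type)) {
    abort_validation("codebook: appeal_type ids must be unique")
  }
  bad <- setdiff(unique(codebook$strategy), c("emotional", "rational"))
  if (length(bad)) {
    abort_validation("codebook: strategy must be 'emotional' or 'rational', got: ",
                     paste(bad, collapse = ", "))
  }
  invisible(codebook)
}

codebook_types <- function(codebook, strategy) {
  codebook$appeal_type[codebook$strategy == strategy]
}

# check a wide codings table (ad_id, coder_id, one 0/1 column per appeal type)
# against the codebook; returns the appeal-type columns present
validate_codings <- function(codings, codebook) {
  validate_codebook(codebook)
  if (!is.data.frame(codings) || !"ad_id" %in% names(codings)) {
    abort_validation("codings: need an 'ad_id' column")
  }
  flag_cols <- setdiff(names(codings), c("ad_id", "coder_id"))
  unknown <- setdiff(flag_cols, codebook$appeal_type)
  if (length(unknown)) {
    abort_validation("codings: unknown appeal types: ",
                     paste(unknown, collapse = ", "),
                     " (valid: ", paste(codebook$appeal_type, collapse = ", "), ")")
  }
  for (cl in flag_cols) {
    v <- codings[[cl]]
    if (!all(v %in% c(0, 1))) {
      abort_validation("codings: column '", cl, "' must be binary 0/1")
    }
  }
  flag_cols
}

#' Emotional and rational appeal-variety scores per ad
#'
#' Counts the distinct flagged appeal types of each strategy per ad, capped
#' at 4, yielding the two ordinal variety scores (0-4).
#'
#' @param codings wide coding table: `ad_id`, optional `coder_id`, and one
#'   0/1 column per appeal type. One row per ad (pass a single coder's
#'   table).
#' @param codebook appeal-type codebook (default [default_codebook()]).
#' @return data.frame: `ad_id`, `emotional_variety`, `rational_variety`
#'   (ordinal 0-4), `any_emotional`, `any_rational`, `both_strategies`,
#'   `no_coded_appeal`.
#' @export
#' @examples
#' cb <- default_codebook()
#' x <- data.frame(ad_id = "A1", senses = 1, cartoons = 1, health = 0)
#' variety_scores(x, cb)
variety_scores <- function(codings, codebook = default_codebook()) {
  flag_cols <- validate_codings(codings, codebook)
  if (anyDuplicated(codings$ad_id)) {
    abort_validation("variety_scores: one row per ad expected; duplicated ad_id ",
                     "(did you pass both coders' tables?)")
  }
  count_strategy <- function(strategy) {
    cols <- intersect(flag_cols, codebook_types(codebook, strategy))
    if (!length(cols)) return(rep(0L, nrow(codings)))
    as.integer(rowSums(codings[, cols, drop = FALSE]))
  }
  n_emo <- count_strategy("emotional")
  n_rat <- count_strategy("rational")
  out <- data.frame(
    ad_id = codings$ad_id,
    emotional_variety = pmin(n_emo, 4L),
    rational_variety = pmin(n_rat, 4L),
    stringsAsFactors = FALSE
  )
  out$any_emotional <- out$emotional_variety >= 1L
  out$any_rational <- out$rational_variety >= 1L
  out$both_strategies <- out$any_emotional & out$any_rational
  out$no_coded_appeal <- !out$any_emotional & !out$any_rational
  out
}

#' Product-level analysis table
#'
#' Joins the final (ad, product) pairs with their ad's appeal-variety scores
#' (ads are coded once, on the extended version; scores broadcast to every
#' product the ad promotes), the product's high-in verdict, and the ad's
#' per-stratum weekly impressions when available.
#'
#' @param final_products data.frame of `ad_id`, `product_id` pairs (the
#'   post-filter sample).
#' @param codings reconciled (single-coder) wide coding table.
#' @param verdicts output of [classify_products()].
#' @param unique_ads optional unique-ads table carrying `wi_<stratum>`
#'   columns (see [add_weekly_impressions()]); joined when supplied.
#' @param codebook appeal-type codebook.
#' @return data.frame, one row per (ad, product): variety scores and
#'   strategy booleans, `high_in`, and any `wi_*` columns.
#' @export
product_level_table <- function(final_products, codings, verdicts,
                                unique_ads = NULL, codebook = default_codebook()) {
  if (!all(c("ad_id", "product_id") %in% names(final_products))) {
    abort_validation("final_products: need columns 'ad_id' and 'product_id'")
  }
  scores <- variety_scores(codings, codebook)
  missing_ads <- setdiff(final_products$ad_id, scores$ad_id)
  if (length(missing_ads)) {
    abort_validation("product_level_table: ads without codings: ",
                     paste(head(missing_ads, 10L), collapse = ", "))
  }
  missing_products <- setdiff(final_products$product_id, verdicts$product_id)
  if (length(missing_products)) {
    abort_validation("product_level_table: products without verdicts: ",
                     paste(head(missing_products, 10L), collapse = ", "))
  }
  dt <- data.table::as.data.table(final_products[, c("ad_id", "product_id")])
  dt <- merge(dt, data.table::as.data.table(scores), by = "ad_id", sort = FALSE)
  dt <- merge(dt,
              data.table::as.data.table(verdicts)[, c("product_id", "high_in"), with = FALSE],
              by = "product_id", sort = FALSE)
  if (!is.null(unique_ads)) {
    keep <- intersect(c("ad_id", wi_cols()), names(unique_ads))
    dt <- merge(dt, data.table::as.data.table(unique_ads)[, keep, with = FALSE],
                by = "ad_id", sort = FALSE)
  }
  data.table::setorder(dt, ad_id, product_id)
  data.table::setDF(dt)
  dt
}

#' Percentage of products at each appeal-variety level
#'
#' Reproduces the variety-distribution layout of the descriptive reporting:
#' for each strategy and each group (all products, high-in, not high-in),
#' the percentage of products promoted with 0, 1, 2, 3 or 4+ distinct
#' appeal types of that strategy. Percentages within a group sum to 100.
#'
#' @param product_table output of [product_level_table()].
#' @return data.frame: `strategy`, `group`, `variety_level` ("0".."3","4+"),
#'   `n`, `percent`.
#' @export
variety_percentage_table <- function(product_table) {
  groups <- list(all = rep(TRUE, nrow(product_table)),
                 high_in = product_table$high_in,
                 not_high_in = !product_table$high_in)
  levels_lab <- c("0", "1", "2", "3", "4+")
  rows <- list()
  for (strategy in c("emotional", "rational")) {
    v <- product_table[[paste0(strategy, "_variety")]]
    for (g in names(groups)) {
      vv <- v[groups[[g]]]
      n <- vapply(0:4, function(k) sum(vv == k), integer(1))
      pct <- if (length(vv)) 100 * n / length(vv) else rep(NA_real_, 5L)
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = strategy, group = g, variety_level = levels_lab,
        n = n, percent = pct, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Prevalence of each appeal type by high-in group
#'
#' Per appeal type, the percentage of products promoted in ads flagged with
#' that type, for all products and by high-in status (the supplementary
#' prevalence-table layout).
#'
#' @param final_products (ad, product) pairs.
#' @param codings reconciled wide coding table.
#' @param verdicts output of [classify_products()].
#' @param codebook appeal-type codebook.
#' @return data.frame: `appeal_type`, `strategy`, `pct_all`, `pct_high_in`,
#'   `pct_not_high_in`.
#' @export
appeal_prevalence_table <- function(final_products, codings, verdicts,
                                    codebook = default_codebook()) {
  flag_cols <- validate_codings(codings, codebook)
  dt <- merge(data.table::as.data.table(final_products[, c("ad_id", "product_id")]),
              data.table::as.data.table(codings), by = "ad_id", sort = FALSE)
  dt <- merge(dt,
              data.table::as.data.table(verdicts)[, c("product_id", "high_in"), with = FALSE],
              by = "product_id", sort = FALSE)
  pct <- function(mask) {
    if (!sum(mask)) return(rep(NA_real_, length(flag_cols)))
    vapply(flag_cols, function(cl) 100 * mean(dt[[cl]][mask]), numeric(1))
  }
  data.frame(
    appeal_type = flag_cols,
    strategy = codebook$strategy[match(flag_cols, codebook$appeal_type)],
    pct_all = pct(rep(TRUE, nrow(dt))),
    pct_high_in = pct(dt$high_in),
    pct_not_high_in = pct(!dt$high_in),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
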