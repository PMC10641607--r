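# Audience-exposure metrics: deduplicate airing instances into unique ads,
# convert average rating points into average weekly impressions per stratum,
# select the top exposure quantile, and apply the sample-filtering
# bookkeeping.
#
# Rating-point convention: 1 rating point = 1% of the stratum's audience, so
# ratings are divided by 100 before multiplying by the population. The weeks
# divisor is fixed at 52 exactly.

split_product_ids <- function(s) {
  if (is.list(s)) return(lapply(s, as.character))
  strsplit(as.character(s), ";", fixed = TRUE)
}

join_product_ids <- function(lst) {
  vapply(lst, function(p) paste(sort(unique(p)), collapse = ";"), character(1))
}

#' Group airing instances into unique ads
#'
#' All instances sharing an `ad_id` are collapsed into one unique ad,
#' including versions that differ only in duration; the instance count sums
#' over all versions and per-stratum average ratings are arithmetic means
#' over all instances. The longest version is marked as the extended
#' version (downstream content coding uses only extended cuts); duration
#' ties break by ascending `version_id`.
#'
#' @param instances airing table: `ad_id`, `version_id`, `duration`,
#'   `product_ids` (";"-separated string or list column) and one
#'   `rating_<stratum>` column per stratum present.
#' @return data.frame, one row per `ad_id`: `n_instances`,
#'   `extended_version_id`, `extended_duration`, `product_ids` (sorted
#'   ";"-joined union over instances) and `avg_rating_<stratum>` columns.
#' @export
group_unique <- function(instances) {
  if (!is.data.frame(instances) || !nrow(instances)) {
    abort_validation("group_unique: empty instance table")
  }
  rcols <- intersect(rating_cols(), names(instances))
  if (!length(rcols)) {
    abort_validation("group_unique: no rating_<stratum> columns present")
  }
  for (cl in rcols) {
    bad <- !is.finite(instances[[cl]])
    if (any(bad)) {
      abort_validation("group_unique: missing/non-finite ratings for ad_id ",
                       paste(unique(instances$ad_id[bad]), collapse = ", "))
    }
  }
  dt <- data.table::as.data.table(instances)
  dt$prod_list <- split_product_ids(dt$product_ids)
  agg <- dt[, c(list(n_instances = .N),
                setNames(lapply(.SD, mean), paste0("avg_", rcols)),
                list(product_ids = join_product_ids(list(unlist(prod_list))))),
            by = "ad_id", .SDcols = rcols]
  # extended version: longest duration, ties broken by ascending version_id
  ver <- dt[, list(duration = duration[1L]), by = c("ad_id", "version_id")]
  data.table::setorder(ver, ad_id, -duration, version_id)
  ext <- ver[, list(extended_version_id = version_id[1L],
                    extended_duration = duration[1L]), by = "ad_id"]
  out <- merge(agg, ext, by = "ad_id", sort = TRUE)
  data.table::setcolorder(out, c("ad_id", "n_instances", "extended_version_id",
                                 "extended_duration", "product_ids"))
  data.table::setDF(out)
  out
}

#' Average weekly impressions for one unique ad and stratum
#'
#' impressions/week = (avg_rating / 100) x stratum population x n_instances
#' / 52. Identical to summing per-instance impressions over the year and
#' dividing by 52, since avg_rating x n_instances equals the instance sum.
#'
#' @param avg_rating average rating points (1 point = 1% of the stratum).
#' @param population child-population count for the stratum.
#' @param n_instances number of airings of the unique ad over the year.
#' @return Average weekly impressions (person-views per week).
#' @export
#' @examples
#' weekly_impressions(1.0, 2470700, 52)  # 24707
weekly_impressions <- function(avg_rating, population, n_instances) {
  if (any(avg_rating < 0) || any(population <= 0) || any(n_instances < 1)) {
    abort_validation("weekly_impressions: avg_rating >= 0, population > 0, ",
                     "n_instances >= 1 required")
  }
  (avg_rating / 100) * population * n_instances / 52
}

#' Attach per-stratum weekly-impression columns to a unique-ads table
#'
#' @param unique_ads output of [group_unique()].
#' @param populations population table (default [default_populations()]).
#' @return `unique_ads` with one `wi_<stratum>` column per stratum that has
#'   both an `avg_rating_<stratum>` column and a population row.
#' @export
add_weekly_impressions <- function(unique_ads, populations = default_populations()) {
  validate_populations(populations)
  out <- unique_ads
  for (s in ADMARK_STRATA) {
    acol <- paste0("avg_rating_", s)
    if (!acol %in% names(unique_ads) || !s %in% populations$stratum) next
    out[[paste0("wi_", s)]] <- weekly_impressions(
      unique_ads[[acol]], population_of(populations, s), unique_ads$n_instances)
  }
  out
}

#' Select the top fraction of unique ads by weekly impressions
#'
#' Returns the `floor(fraction * N)` ads with the highest weekly impressions
#' in the given stratum. Ties at the selection boundary break by ascending
#' `ad_id`, making the selection deterministic.
#'
#' @param unique_ads table carrying a `wi_<stratum>` column (see
#'   [add_weekly_impressions()]).
#' @param fraction proportion in (0, 1] (default 0.20).
#' @param stratum stratum whose impressions rank the ads (default
#'   "overall").
#' @return list with `selected` (the chosen rows, highest impressions
#'   first) and `report` (a selection-report list: `n_unique_in`,
#'   `fraction`, `n_selected`, `threshold_impressions`).
#' @export
select_top_fraction <- function(unique_ads, fraction = 0.20, stratum = "overall") {
  if (!(is.numeric(fraction) && length(fraction) == 1L &&
        fraction > 0 && fraction <= 1)) {
    abort_validation("select_top_fraction: fraction must be in (0, 1]")
  }
  wcol <- paste0("wi_", stratum)
  if (!wcol %in% names(unique_ads)) {
    abort_validation("select_top_fraction: missing column '", wcol,
                     "' (run add_weekly_impressions first)")
  }
  n_in <- nrow(unique_ads)
  n_sel <- as.integer(floor(fraction * n_in))
  ord <- order(-unique_ads[[wcol]], unique_ads$ad_id)
  selected <- unique_ads[ord[seq_len(n_sel)], , drop = FALSE]
  rownames(selected) <- NULL
  report <- list(
    n_unique_in = n_in,
    fraction = fraction,
    n_selected = n_sel,
    threshold_impressions = if (n_sel) selected[[wcol]][n_sel] else NA_real_
  )
  list(selected = selected, report = report)
}

#' Apply the content-analysis sample filters
#'
#' Post-selection bookkeeping, in order: (1) drop ads all of whose products
#' are alcoholic beverages or cooking ingredients; (2) drop ads none of
#' whose products are available for purchase; (3) drop ads with at least
#' one promoted product lacking a nutrition record (their remaining
#' products leave the sample with them). Survivors expand to one row per
#' (ad, product) pair, covering listed and additional on-screen products
#' alike (both arrive via `product_ids`).
#'
#' @param selected_ads unique-ads table (with `product_ids`).
#' @param nutrition nutrition table (`product_id` + nutrient columns);
#'   membership defines "has a nutrition record".
#' @param categories data.frame `product_id`, `category` (values
#'   "alcoholic_beverage" and "cooking_ingredient" trigger the category
#'   filter; anything else passes) and optional logical `available`
#'   (default TRUE).
#' @return list: `final_ads` (surviving rows of `selected_ads`),
#'   `final_products` (data.frame `ad_id`, `product_id`), `report` (counts:
#'   `n_selected`, `n_after_category_filter`, `n_available_for_purchase`,
#'   `n_excluded_no_nutrition`, `n_final_ads`, `n_products_listed`,
#'   `n_products_excluded`, `n_final_products`) and `removals` (data.frame
#'   `ad_id`, `reason` for every dropped ad).
#' @export
apply_sample_filters <- function(selected_ads, nutrition, categories) {
  if (!"product_ids" %in% names(selected_ads)) {
    abort_validation("apply_sample_filters: selected_ads lacks 'product_ids'")
  }
  if (!all(c("product_id", "category") %in% names(categories))) {
    abort_validation("apply_sample_filters: categories needs 'product_id' and 'category'")
  }
  if (!"available" %in% names(categories)) categories$available <- TRUE
  prods <- split_product_ids(selected_ads$product_ids)
  cat_of <- setNames(as.character(categories$category), categories$product_id)
  avail_of <- setNames(as.logical(categories$available), categories$product_id)
  excluded_cats <- c("alcoholic_beverage", "cooking_ingredient")

  removals <- list()
  drop_with_reason <- function(keep, mask_drop, reason, ids) {
    dropped <- ids[keep & mask_drop]
    if (length(dropped)) {
      removals[[length(removals) + 1L]] <<- data.frame(
        ad_id = dropped, reason = reason, stringsAsFactors = FALSE)
    }
    keep & !mask_drop
  }

  ids <- selected_ads$ad_id
  keep <- rep(TRUE, nrow(selected_ads))
  all_excluded_cat <- vapply(prods, function(p) {
    cc <- cat_of[p]
    length(p) > 0 && all(!is.na(cc) & cc %in% excluded_cats)
  }, logical(1))
  keep <- drop_with_reason(keep, all_excluded_cat,
                           "alcohol_or_cooking_ingredient", ids)
  n_after_category <- sum(keep)

  none_available <- vapply(prods, function(p) {
    av <- avail_of[p]
    all(is.na(av) | !av)
  }, logical(1))
  keep <- drop_with_reason(keep, none_available, "not_available_for_purchase", ids)
  n_available <- sum(keep)
  listed_products <- sum(lengths(prods[keep]))

  lacks_nutrition <- vapply(prods, function(p) {
    !all(p %in% nutrition$product_id)
  }, logical(1))
  before <- keep
  keep <- drop_with_reason(keep, lacks_nutrition, "no_nutrition_record", ids)
  n_excluded_nutrition <- sum(before) - sum(keep)
  n_products_excluded <- sum(lengths(prods[before & !keep]))

  final_ads <- selected_ads[keep, , drop = FALSE]
  rownames(final_ads) <- NULL
  fp <- prods[keep]
  final_products <- data.frame(
    ad_id = rep(ids[keep], lengths(fp)),
    product_id = unlist(fp, use.names = FALSE) %||% character(0),
    stringsAsFactors = FALSE
  )
  report <- list(
    n_selected = nrow(selected_ads),
    n_after_category_filter = n_after_category,
    n_available_for_purchase = n_available,
    n_excluded_no_nutrition = n_excluded_nutrition,
    n_final_ads = nrow(final_ads),
    n_products_listed = listed_products,
    n_products_excluded = n_products_excluded,
    n_final_products = nrow(final_products)
  )
  stopifnot(report$n_final_ads ==
              report$n_available_for_purchase - report$n_excluded_no_nutrition)
  list(final_ads = final_ads, final_products = final_products,
       report = report,
       removals = if (length(removals)) do.call(rbind, removals) else
         data.frame(ad_id = character(0), reason = character(0)))
}
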