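# PAHO nutrient profile model: "high-in" classification of advertised products.
#
# Thresholds are applied only to processed / ultra-processed products.
# A product is high-in if it meets ANY of:
#   free sugars  >= 10% of total energy        (4 kcal/g)
#   total fat    >= 30% of total energy        (9 kcal/g)
#   saturated fat>= 10% of total energy        (9 kcal/g)
#   trans fat    >=  1% of total energy        (9 kcal/g)
#   sodium       >=  1 mg per kcal
#   any non-caloric sweetener among ingredients
# All thresholds inclusive (>=). Energy conversion uses standard Atwater
# factors; inputs are per reference amount with energy in kcal.

PROCESSING_CATEGORIES <- c("unprocessed_minimally_processed", "culinary_ingredient",
                           "processed", "ultra_processed")
PAHO_APPLICABLE <- c("processed", "ultra_processed")

KCAL_PER_G_SUGAR <- 4
KCAL_PER_G_FAT <- 9

#' Fraction of total energy contributed by a nutrient
#'
#' For zero-energy products the fraction is taken as `+Inf` when the nutrient
#' amount is positive (the criterion fires) and `0` when it is zero; the
#' ratio is otherwise undefined and the model's intent is flagging.
#'
#' @param nutrient_grams nutrient amount in grams (non-negative, vectorised).
#' @param kcal_per_gram energy conversion factor (4 for sugars, 9 for fats).
#' @param energy total energy in kcal (non-negative, vectorised).
#' @return Numeric vector of energy fractions (proportions, may be `Inf`).
#' @export
#' @examples
#' energy_fraction(10, 4, 400)  # 0.10
energy_fraction <- function(nutrient_grams, kcal_per_gram, energy) {
  if (any(nutrient_grams < 0, na.rm = TRUE) || any(kcal_per_gram < 0) ||
      any(energy < 0, na.rm = TRUE)) {
    abort_validation("energy_fraction: inputs must be non-negative")
  }
  out <- nutrient_grams * kcal_per_gram / energy
  zero_e <- energy == 0
  out[zero_e & nutrient_grams > 0] <- Inf
  out[zero_e & nutrient_grams == 0] <- 0
  out
}

#' Classify products as "high-in" under the PAHO nutrient profile model
#'
#' Applies the six PAHO criteria to every row of a nutrition table. Products
#' whose `processing_category` is unprocessed/minimally processed or a
#' culinary ingredient are out of the model's scope: they get
#' `applicable = FALSE`, all criterion flags `FALSE` and `high_in = FALSE`.
#'
#' @param nutrition data.frame with columns `product_id`, `energy_kcal`,
#'   `free_sugars_g`, `total_fat_g`, `saturated_fat_g`, `trans_fat_g`,
#'   `sodium_mg`, `has_noncaloric_sweetener` (logical or 0/1) and
#'   `processing_category` (one of unprocessed_minimally_processed,
#'   culinary_ingredient, processed, ultra_processed).
#' @return data.frame, one row per product: `product_id`, `applicable`, the
#'   six criterion flags (`high_free_sugars`, `high_total_fat`,
#'   `high_saturated_fat`, `high_trans_fat`, `high_sodium`, `high_sweetener`)
#'   and the overall `high_in` verdict (the OR of the six when applicable).
#' @export
#' @examples
#' classify_products(data.frame(
#'   product_id = "P1", energy_kcal = 400, free_sugars_g = 15,
#'   total_fat_g = 0, saturated_fat_g = 0, trans_fat_g = 0, sodium_mg = 0,
#'   has_noncaloric_sweetener = FALSE, processing_category = "ultra_processed"))
classify_products <- function(nutrition) {
  req <- c("product_id", "energy_kcal", "free_sugars_g", "total_fat_g",
           "saturated_fat_g", "trans_fat_g", "sodium_mg",
           "has_noncaloric_sweetener", "processing_category")
  missing_cols <- setdiff(req, names(nutrition))
  if (length(missing_cols)) {
    abort_validation("nutrition table: missing columns: ",
                     paste(missing_cols, collapse = ", "))
  }
  bad_cat <- setdiff(unique(nutrition$processing_category), PROCESSING_CATEGORIES)
  if (length(bad_cat)) {
    abort_validation("unknown processing_category: ",
                     paste(bad_cat, collapse = ", "),
                     " (valid: ", paste(PROCESSING_CATEGORIES, collapse = ", "), ")")
  }
  num_cols <- c("energy_kcal", "free_sugars_g", "total_fat_g", "saturated_fat_g",
                "trans_fat_g", "sodium_mg")
  for (cl in num_cols) {
    v <- nutrition[[cl]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      abort_validation("nutrition table: column '", cl,
                       "' must be finite and non-negative")
    }
  }

  e <- nutrition$energy_kcal
  applicable <- nutrition$processing_category %in% PAHO_APPLICABLE
  sweet <- as.logical(nutrition$has_noncaloric_sweetener)

  crit <- data.frame(
    high_free_sugars = energy_fraction(nutrition$free_sugars_g, KCAL_PER_G_SUGAR, e) >= 0.10,
    high_total_fat = energy_fraction(nutrition$total_fat_g, KCAL_PER_G_FAT, e) >= 0.30,
    high_saturated_fat = energy_fraction(nutrition$saturated_fat_g, KCAL_PER_G_FAT, e) >= 0.10,
    high_trans_fat = energy_fraction(nutrition$trans_fat_g, KCAL_PER_G_FAT, e) >= 0.01,
    # sodium density criterion: >= 1 mg Na per kcal; zero-energy convention as above
    high_sodium = ifelse(e == 0, nutrition$sodium_mg > 0, nutrition$sodium_mg / pmax(e, .Machine$double.xmin) >= 1),
    high_sweetener = sweet
  )
  crit[!applicable, ] <- FALSE
  out <- cbind(
    data.frame(product_id = nutrition$product_id, applicable = applicable,
               stringsAsFactors = FALSE),
    crit
  )
  out$high_in <- applicable & Reduce(`|`, crit)
  out
}
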