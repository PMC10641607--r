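#' Child population counts per audience stratum
#'
#' The shipped table carries the DANE-projected counts of Colombian children
#' aged 4-11 in 2017 used to convert rating points (1 point = 1% of a
#' stratum's audience) into impressions: 2 470 700 overall, split into
#' 1 260 057 female + 1 210 643 male, and 1 235 350 / 938 866 / 444 726 for
#' low / middle / high socio-economic strata (SES). The SES counts sum to
#' more than the overall figure; that inconsistency is present in the source
#' projections and is deliberately left untouched (only female + male =
#' overall is enforced).
#'
#' @return A data.frame with columns `stratum` and `population`.
#' @export
#' @examples
#' default_populations()
default_populations <- function() {
  data.frame(
    stratum = ADMARK_STRATA,
    population = c(2470700, 1260057, 1210643, 1235350, 938866, 444726),
    stringsAsFactors = FALSE
  )
}

#' Validate a population table
#'
#' Checks the stratum set, positive integer counts, and (for tables carrying
#' the gender split) that female + male equals overall.
#'
#' @param populations data.frame with columns `stratum`, `population`.
#' @param enforce_gender_sum require female + male == overall (default TRUE
#'   when all three strata are present).
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_populations <- function(populations, enforce_gender_sum = TRUE) {
  if (!is.data.frame(populations) ||
      !all(c("stratum", "population") %in% names(populations))) {
    abort_validation("populations: need columns 'stratum' and 'population'")
  }
  unknown <- setdiff(populations$stratum, ADMARK_STRATA)
  if (length(unknown)) {
    abort_validation("populations: unknown strata: ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(populations$stratum)) {
    abort_validation("populations: duplicate stratum rows")
  }
  p <- populations$population
  if (any(!is.finite(p)) || any(p <= 0) || any(p != round(p))) {
    abort_validation("populations: counts must be positive integers")
  }
  have <- function(s) s %in% populations$stratum
  if (enforce_gender_sum && have("overall") && have("female") && have("male")) {
    pop <- setNames(populations$population, populations$stratum)
    if (pop[["female"]] + pop[["male"]] != pop[["overall"]]) {
      abort_validation("populations: female + male must equal overall")
    }
  }
  invisible(populations)
}

population_of <- function(populations, stratum) {
  i <- match(stratum, populations$stratum)
  if (is.na(i)) abort_validation("stratum '", stratum, "' missing from population table")
  populations$population[i]
}
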