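# End-to-end analysis orchestration: exposure metrics -> sample filters ->
# PAHO verdicts -> appeal scores -> descriptive tables -> inferential stage.

default_run_config <- function(config = list()) {
  modifyList(list(
    fraction = 0.20,
    stratum = "overall",
    coder = "C1",
    codebook = default_codebook(),
    categories = NULL,
    holm_adjust = FALSE,
    reliability_subsample = 0.1,
    reliability_min_n = 59L,
    seed = 1L
  ), config)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

test_to_list <- function(res) {
  sanitize <- function(v) {
    if (is.numeric(v) && length(v) && any(!is.finite(v) & !is.na(v))) {
      return(as.character(v))
    }
    v
  }
  list(test = res$test,
       statistic = sanitize(res$statistic),
       z = res$z,
       p_value = res$p_value,
       estimates = lapply(res$estimates, sanitize),
       n = as.list(res$n),
       method = res$method,
       degenerate = res$degenerate)
}

mw_or_empty <- function(a, b, label) {
  if (!length(a) || !length(b)) {
    return(new_test_result("mann_whitney_u", statistic = NA_real_,
                           p_value = NA_real_,
                           estimates = list(),
                           n = c(a = length(a), b = length(b)),
                           method = "degenerate", degenerate = "empty_group"))
  }
  res <- mann_whitney_u(a, b)
  res$test <- label
  res
}

paired_grid <- function(ads_scored, comparisons, holm_adjust = FALSE) {
  rows <- list()
  for (strategy in c("emotional", "rational")) {
    for (lvl in 0:4) {
      for (cmp in comparisons) {
        res <- paired_exposure_test(ads_scored, cmp[1], cmp[2],
                                    if (lvl == 4L) "4+" else lvl, strategy)
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = strategy,
          variety_level = if (lvl == 4L) "4+" else as.character(lvl),
          stratum_a = cmp[1], stratum_b = cmp[2],
          n = unname(res$n[["pairs"]]),
          mean_a = res$estimates$mean_a %||% NA_real_,
          mean_b = res$estimates$mean_b %||% NA_real_,
          mean_diff = res$estimates$mean_diff %||% NA_real_,
          t = unname(res$statistic),
          p_value = res$p_value,
          degenerate = res$degenerate,
          stringsAsFactors = FALSE)
      }
    }
  }
  grid <- do.call(rbind, rows)
  if (holm_adjust) {
    grid$p_holm <- NA_real_
    ok <- !is.na(grid$p_value)
    grid$p_holm[ok] <- stats::p.adjust(grid$p_value[ok], method = "holm")
  }
  grid
}

#' Run the full monitoring analysis end to end
#'
#' Orchestrates every stage on validated input tables: unique-ad grouping,
#' weekly impressions, top-fraction selection, sample filters, PAHO
#' verdicts, appeal-variety scoring, the descriptive variety/prevalence
#' tables, the Wilcoxon signed-rank comparison of emotional vs rational
#' variety (product level), Mann-Whitney comparisons of variety by high-in
#' status (empty groups reported, not raised), intercoder reliability, and
#' the paired-t exposure grids (female vs male; all SES pairs) across
#' variety levels. Any stage failure is re-raised with the stage name.
#'
#' @param airings airing-instance table.
#' @param nutrition nutrition table.
#' @param codings two-coder codings table (`coder_id` column); the coder
#'   named by `config$coder` (default "C1") is the reconciled analysis
#'   coding.
#' @param populations population table.
#' @param config list overriding: `fraction` (0.20), `stratum`
#'   ("overall"), `coder`, `codebook`, `categories` (product category
#'   table; defaults to all-"food", all-available), `holm_adjust` (FALSE),
#'   `reliability_subsample` (0.1), `reliability_min_n` (59), `seed`.
#' @return list report bundle: `unique_ads`, `selection_report`,
#'   `filter_report`, `removals`, `product_table`, `ads_scored`,
#'   `variety_table`, `prevalence_table`, `tests` (admark_test objects),
#'   `paired_grid`, `reliability`, `run_log`.
#' @export
run_full_analysis <- function(airings, nutrition, codings,
                              populations = default_populations(),
                              config = list()) {
  cfg <- default_run_config(config)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, paste0(...))

  unique_ads <- run_stage("group_unique", group_unique(airings))
  say("group_unique: ", nrow(unique_ads), " unique ads from ",
      nrow(airings), " instances")
  unique_ads <- run_stage("weekly_impressions",
                          add_weekly_impressions(unique_ads, populations))
  sel <- run_stage("select_top_fraction",
                   select_top_fraction(unique_ads, cfg$fraction, cfg$stratum))
  say("select_top_fraction: ", sel$report$n_selected, " of ",
      sel$report$n_unique_in, " ads (fraction ", cfg$fraction,
      ", stratum ", cfg$stratum, ")")

  categories <- cfg$categories %||% data.frame(
    product_id = nutrition$product_id, category = "food", available = TRUE,
    stringsAsFactors = FALSE)
  filt <- run_stage("apply_sample_filters",
                    apply_sample_filters(sel$selected, nutrition, categories))
  say("apply_sample_filters: ", filt$report$n_final_ads, " final ads, ",
      filt$report$n_final_products, " final products")

  verdicts <- run_stage("classify_products", classify_products(nutrition))
  say("classify_products: ", sum(verdicts$high_in), " of ", nrow(verdicts),
      " products high-in")

  coding1 <- codings[codings$coder_id == cfg$coder, , drop = FALSE]
  coding1 <- coding1[coding1$ad_id %in% filt$final_ads$ad_id, , drop = FALSE]
  coding1$coder_id <- NULL
  ptab <- run_stage("product_level_table",
                    product_level_table(filt$final_products, coding1, verdicts,
                                        filt$final_ads, cfg$codebook))

  variety_table <- run_stage("variety_percentage_table",
                             variety_percentage_table(ptab))
  prevalence_table <- run_stage(
    "appeal_prevalence_table",
    appeal_prevalence_table(filt$final_products, coding1, verdicts, cfg$codebook))

  tests <- list()
  tests$wilcoxon_emotional_vs_rational <- run_stage(
    "wilcoxon_signed_rank",
    wilcoxon_signed_rank(ptab$emotional_variety, ptab$rational_variety))
  tests$mw_emotional_by_high_in <- run_stage(
    "mann_whitney_u",
    mw_or_empty(ptab$emotional_variety[ptab$high_in],
                ptab$emotional_variety[!ptab$high_in],
                "mw_emotional_by_high_in"))
  tests$mw_rational_by_high_in <- run_stage(
    "mann_whitney_u",
    mw_or_empty(ptab$rational_variety[ptab$high_in],
                ptab$rational_variety[!ptab$high_in],
                "mw_rational_by_high_in"))
  say("wilcoxon emotional vs rational: p = ",
      format.pval(tests$wilcoxon_emotional_vs_rational$p_value))
  say("mann-whitney emotional by high-in: p = ",
      format.pval(tests$mw_emotional_by_high_in$p_value))
  say("mann-whitney rational by high-in: p = ",
      format.pval(tests$mw_rational_by_high_in$p_value))

  # ad-level exposure comparisons (ads are the unit of analysis here)
  scores <- variety_scores(coding1, cfg$codebook)
  ads_scored <- merge(filt$final_ads, scores, by = "ad_id", sort = TRUE)
  comparisons <- list(c("female", "male"), c("ses_low", "ses_mid"),
                      c("ses_low", "ses_high"), c("ses_mid", "ses_high"))
  comparisons <- Filter(function(cmp) {
    all(paste0("wi_", cmp) %in% names(ads_scored))
  }, comparisons)
  grid <- run_stage("paired_exposure_test",
                    paired_grid(ads_scored, comparisons, cfg$holm_adjust))
  say("paired exposure grid: ", nrow(grid), " cells")

  reliability <- NULL
  if ("coder_id" %in% names(codings) &&
      length(unique(codings$coder_id)) >= 2L) {
    coders <- sort(unique(codings$coder_id))[1:2]
    c1 <- codings[codings$coder_id == coders[1], , drop = FALSE]
    c2 <- codings[codings$coder_id == coders[2], , drop = FALSE]
    c1$coder_id <- NULL; c2$coder_id <- NULL
    reliability <- run_stage(
      "reliability_report",
      reliability_report(c1, c2, cfg$codebook,
                         subsample = cfg$reliability_subsample,
                         min_n = cfg$reliability_min_n, seed = cfg$seed))
    say("reliability: agreement ",
        round(reliability$summary$agreement_min, 2), "-",
        round(reliability$summary$agreement_max, 2), "%, kappa ",
        round(reliability$summary$kappa_min, 3), "-",
        round(reliability$summary$kappa_max, 3))
  }

  list(unique_ads = unique_ads,
       selection_report = sel$report,
       filter_report = filt$report,
       removals = filt$removals,
       product_table = ptab,
       ads_scored = ads_scored,
       variety_table = variety_table,
       prevalence_table = prevalence_table,
       tests = tests,
       paired_grid = grid,
       reliability = reliability,
       run_log = log_lines)
}

#' Write a report bundle to disk
#'
#' Emits `tables/*.csv` (variety, prevalence, paired grid, product table,
#' unique ads, removals), `results.json` (reports, test results,
#' reliability) and `run.log`. Output is byte-identical across runs for the
#' same inputs: no wall-clock information is written.
#'
#' @param bundle output of [run_full_analysis()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  tdir <- file.path(dir, "tables")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(bundle$variety_table, file.path(tdir, "variety_percentages.csv"))
  write_table_csv(bundle$prevalence_table, file.path(tdir, "appeal_prevalence.csv"))
  write_table_csv(bundle$paired_grid, file.path(tdir, "paired_exposure_grid.csv"))
  write_table_csv(bundle$product_table, file.path(tdir, "product_table.csv"))
  write_table_csv(bundle$unique_ads, file.path(tdir, "unique_ads.csv"))
  write_table_csv(bundle$removals, file.path(tdir, "removals.csv"))
  results <- list(
    selection_report = bundle$selection_report,
    filter_report = bundle$filter_report,
    tests = lapply(bundle$tests, test_to_list),
    reliability = if (!is.null(bundle$reliability)) list(
      per_code = bundle$reliability$per_code,
      summary = bundle$reliability$summary) else NULL
  )
  jsonlite::write_json(results, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  writeLines(bundle$run_log, file.path(dir, "run.log"))
  invisible(dir)
}
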