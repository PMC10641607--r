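# Readers/writers with schema validation.
#
# CSV dialect is fixed for determinism: UTF-8, comma-separated, header row
# mandatory, "." decimal separator. Timestamps are ISO-8601 local time
# ("YYYY-MM-DD HH:MM:SS"); no timezone arithmetic is performed.

read_csv_checked <- function(path, required, what, colClasses = NULL) {
  if (!file.exists(path)) abort_validation(what, ": file not found: ", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE,
                          encoding = "UTF-8", colClasses = colClasses)
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    abort_validation(what, ": missing columns: ",
                     paste(missing_cols, collapse = ", "))
  }
  dt
}

timestamp_hour <- function(ts) {
  as.integer(substr(ts, 12, 13)) + as.integer(substr(ts, 15, 16)) / 60 +
    as.integer(substr(ts, 18, 19)) / 3600
}

#' Read and validate an airing-instance table
#'
#' Enforces the airing schema, collects row-level violations with row
#' numbers, and drops instances whose timestamps fall outside the daily
#' sampling window (the count of dropped rows is attached as attribute
#' `n_rejected_window`).
#'
#' @param path CSV file.
#' @param window daily window in hours, default `c(6, 22)`: airings
#'   starting at or after the end hour are rejected.
#' @param year optional analysis year; timestamps in other years are
#'   validation errors.
#' @return Validated airing data.frame (attribute `n_rejected_window`
#'   carries the window-rejection count).
#' @export
read_airings <- function(path, window = c(6, 22), year = NULL) {
  req <- c("ad_id", "version_id", "timestamp", "duration", "product_ids")
  air <- read_csv_checked(path, req, "airings",
                          colClasses = c(timestamp = "character"))
  rcols <- intersect(rating_cols(), names(air))
  if (!length(rcols)) {
    abort_validation("airings: no rating_<stratum> columns found (expected ",
                     "some of: ", paste(rating_cols(), collapse = ", "), ")")
  }
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows)) {
      problems <<- c(problems, paste0(msg, " (rows ",
                                      paste(head(rows, 10L), collapse = ", "),
                                      if (length(rows) > 10L) ", ..." else "", ")"))
    }
  }
  note(which(!is.finite(air$duration) | air$duration <= 0),
       "duration must be > 0")
  for (cl in rcols) {
    note(which(!is.finite(air[[cl]]) | air[[cl]] < 0),
         paste0(cl, " must be >= 0"))
  }
  ok_ts <- grepl("^\\d{4}-\\d{2}-\\d{2}[ T]\\d{2}:\\d{2}:\\d{2}$", air$timestamp)
  note(which(!ok_ts), "timestamp must be ISO-8601 'YYYY-MM-DD HH:MM:SS'")
  if (!is.null(year) && any(ok_ts)) {
    yr <- substr(air$timestamp, 1, 4)
    note(which(ok_ts & yr != as.character(year)),
         paste0("timestamp outside analysis year ", year))
  }
  if (length(problems)) {
    abort_validation("airings: ", paste(problems, collapse = "; "))
  }
  hours <- timestamp_hour(air$timestamp)
  in_window <- hours >= window[1] & hours < window[2]
  out <- air[in_window, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected_window") <- sum(!in_window)
  out
}

#' Read and validate a product nutrition table
#'
#' If an `energy_unit` column is present ("kcal" or "kJ"), kJ energies are
#' converted to kcal (4.184 kJ/kcal) and the column dropped.
#'
#' @param path CSV file.
#' @return Validated nutrition data.frame.
#' @export
read_nutrition <- function(path) {
  req <- c("product_id", "energy_kcal", "free_sugars_g", "total_fat_g",
           "saturated_fat_g", "trans_fat_g", "sodium_mg",
           "has_noncaloric_sweetener", "processing_category")
  nut <- read_csv_checked(path, setdiff(req, "energy_kcal"), "nutrition")
  if (!"energy_kcal" %in% names(nut)) {
    abort_validation("nutrition: missing columns: energy_kcal")
  }
  if ("energy_unit" %in% names(nut)) {
    unit <- tolower(nut$energy_unit)
    bad <- !unit %in% c("kcal", "kj")
    if (any(bad)) {
      abort_validation("nutrition: unknown energy_unit values: ",
                       paste(unique(nut$energy_unit[bad]), collapse = ", "))
    }
    nut$energy_kcal[unit == "kj"] <- nut$energy_kcal[unit == "kj"] / 4.184
    nut$energy_unit <- NULL
  }
  dup <- unique(nut$product_id[duplicated(nut$product_id)])
  if (length(dup)) {
    abort_validation("nutrition: duplicate product_id: ",
                     paste(head(dup, 10L), collapse = ", "))
  }
  nut$has_noncaloric_sweetener <- as.logical(nut$has_noncaloric_sweetener)
  classify_products(nut)  # full schema/range validation
  nut
}

#' Read and validate a codings table
#'
#' @param path CSV file (`ad_id`, optional `coder_id`, 0/1 appeal columns).
#' @param codebook codebook the appeal columns must belong to.
#' @return Validated codings data.frame.
#' @export
read_codings <- function(path, codebook = default_codebook()) {
  codings <- read_csv_checked(path, "ad_id", "codings")
  validate_codings(codings, codebook)
  key <- if ("coder_id" %in% names(codings)) {
    paste(codings$ad_id, codings$coder_id)
  } else codings$ad_id
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    abort_validation("codings: duplicate (ad_id, coder_id): ",
                     paste(head(dup, 10L), collapse = "; "))
  }
  codings
}

#' Read a population table (JSON map or CSV)
#'
#' @param path `.json` file mapping stratum to count, or a CSV with
#'   `stratum`, `population` columns.
#' @return Validated population data.frame.
#' @export
read_populations <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- jsonlite::fromJSON(path)
    pops <- data.frame(stratum = names(m),
                       population = as.numeric(unlist(m)),
                       stringsAsFactors = FALSE)
  } else {
    pops <- read_csv_checked(path, c("stratum", "population"), "populations")
  }
  validate_populations(pops)
  pops
}

#' Write a table as CSV in the package's fixed dialect
#'
#' @param x data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  data.table::fwrite(x, path, sep = ",", quote = "auto", eol = "\n",
                     logical01 = FALSE)
  invisible(path)
}

#' Write a population table as a JSON map
#'
#' @param populations population data.frame.
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
write_populations <- function(populations, path) {
  validate_populations(populations)
  m <- as.list(setNames(populations$population, populations$stratum))
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
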