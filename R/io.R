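cohort_columns <- function() {
  c("patient_id", "center_id", "center_oncology", "age", "ca125",
    "prop_solid", "max_diameter", "shadows", "ascites", "gt10_locules",
    "papillations", "outcome")
}

#' Write a cohort as delimited text
#'
#' Comma-separated, header row, "NA" for missing CA125, fixed column order.
#'
#' @param cohort An `ova_cohort`.
#' @param path Output file path.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)[, cohort_columns()]
  out$papillations <- as.character(out$papillations)
  out$outcome <- as.character(out$outcome)
  utils::write.csv(out, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read and validate a cohort file
#'
#' Reads the delimited dialect written by [write_cohort()] and applies the
#' full schema validation of [validate_cohort()].
#'
#' @param path Path to a cohort CSV.
#' @return A validated `ova_cohort` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  validate_cohort(raw, context = path)
}

#' Validate a patient-level cohort table
#'
#' Enforces the cohort schema: required columns, unique patient ids,
#' predictor ranges (age > 0, CA125 > 0 where present, solid proportion in
#' \[0,1\], diameter > 0, binaries in \{0,1\}), valid papillation and
#' outcome levels, and missingness confined to CA125. Violations raise
#' errors naming the offending column and row; absent outcome classes
#' produce a warning (the multiclass discrimination metrics need all five).
#'
#' @param x A data frame in the cohort dialect.
#' @param context Label used in error messages (e.g. the file path).
#' @return The validated table with class `ova_cohort` and a
#'   `ca125_missing` flag column.
#' @export
validate_cohort <- function(x, context = "cohort") {
  missing_cols <- setdiff(cohort_columns(), names(x))
  if (length(missing_cols)) {
    stop(context, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x)
  fail <- function(col, rows, why) {
    stop(context, ": column '", col, "' ", why, " (row ",
         paste(utils::head(rows, 3), collapse = ", "),
         if (length(rows) > 3) ", ..." else "", ")")
  }
  for (col in setdiff(cohort_columns(), "ca125")) {
    if (anyNA(x[[col]])) fail(col, which(is.na(x[[col]])), "has missing values; only ca125 may be missing")
  }
  if (anyDuplicated(x$patient_id)) {
    fail("patient_id", which(duplicated(x$patient_id)), "has duplicate ids")
  }
  num_checks <- list(
    age = function(v) v > 0,
    prop_solid = function(v) v >= 0 & v <= 1,
    max_diameter = function(v) v > 0
  )
  for (col in names(num_checks)) {
    bad <- which(!num_checks[[col]](x[[col]]))
    if (length(bad)) fail(col, bad, "out of range")
  }
  bad <- which(!is.na(x$ca125) & x$ca125 <= 0)
  if (length(bad)) fail("ca125", bad, "must be positive when present")
  for (col in c("center_oncology", "shadows", "ascites", "gt10_locules")) {
    bad <- which(!x[[col]] %in% c(0L, 1L))
    if (length(bad)) fail(col, bad, "must be binary 0/1")
  }
  bad <- which(!as.character(x$papillations) %in% papillation_levels())
  if (length(bad)) fail("papillations", bad, "has unknown level")
  bad <- which(!as.character(x$outcome) %in% outcome_levels())
  if (length(bad)) fail("outcome", bad, "has unknown outcome level")

  x$papillations <- factor(as.character(x$papillations), levels = papillation_levels())
  x$outcome <- factor(as.character(x$outcome), levels = outcome_levels())
  x$ca125_missing <- is.na(x$ca125)
  absent <- setdiff(outcome_levels(), as.character(unique(x$outcome)))
  if (length(absent)) {
    warning(context, ": outcome classes absent: ", paste(absent, collapse = ", "))
  }
  class(x) <- c("ova_cohort", "data.frame")
  x
}
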