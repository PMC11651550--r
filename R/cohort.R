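#' Cohort table schema
#'
#' A cohort table holds one row per individual with the fields the audit
#' consumes. Scores are stored internally as probabilities in the open
#' interval (0, 1); the integer 1-99 display convention used for deployed
#' scores is a percentage rendering of the same quantity.
#'
#' Columns:
#' \describe{
#'   \item{id}{opaque identifier (character).}
#'   \item{age}{integer years, >= 0.}
#'   \item{sex}{`"M"` or `"F"`; never missing.}
#'   \item{simd_decile}{integer 1-10, 1 = most deprived; never missing.}
#'   \item{ethnicity}{`"white"`, `"nonwhite"` or missing (`NA`).}
#'   \item{urban_rural}{`"urban"`, `"rural"` or missing.}
#'   \item{mainland_island}{`"mainland"`, `"island"` or missing.}
#'   \item{score}{risk score, a probability strictly inside (0, 1).}
#'   \item{outcome}{0/1; 1 means an emergency admission or death occurred
#'     within one year of the prediction date.}
#'   \item{event_kind}{`"none"`, `"admission"` or `"death_without_admission"`;
#'     `"none"` iff `outcome == 0`.}
#'   \item{icd10_code}{primary-diagnosis (or primary cause-of-death) ICD-10
#'     code, present iff `outcome == 1`.}
#' }
#'
#' Missing categoricals are written to file as the sentinel token `"NA"`.
#'
#' @return Character vector of the canonical column names, in order.
#' @export
cohort_columns <- function() {
  c("id", "age", "sex", "simd_decile", "ethnicity", "urban_rural",
    "mainland_island", "score", "outcome", "event_kind", "icd10_code")
}

cohort_levels <- list(
  sex = c("M", "F"),
  ethnicity = c("white", "nonwhite"),
  urban_rural = c("urban", "rural"),
  mainland_island = c("mainland", "island"),
  event_kind = c("none", "admission", "death_without_admission")
)

# never-missing fields
cohort_required <- c("id", "age", "sex", "simd_decile", "score", "outcome",
                     "event_kind")

cohort_abort <- function(class, msg) {
  abort(msg, class = c(paste0("cohort_error_", class), "fairaudit_error"))
}

#' Validate a cohort table
#'
#' Checks the full schema contract of [cohort_columns()]: required columns,
#' category labels, numeric ranges (age >= 0, simd_decile in 1..10, score in
#' the open interval (0,1)), and the linkage invariant
#' `outcome == 0  <=>  event_kind == "none"  <=>  icd10_code missing`.
#'
#' @param table A data frame.
#' @param require_icd10 If `FALSE`, rows with `outcome == 1` may lack an
#'   ICD-10 code (event typing disabled).
#' @return The validated table as a tibble, categories normalised to the
#'   canonical tokens, row order preserved.
#' @export
validate_cohort <- function(table, require_icd10 = TRUE) {
  missing_cols <- setdiff(cohort_columns(), names(table))
  if (length(missing_cols)) {
    cohort_abort("missing_column",
                 paste0("Cohort file is missing required column(s): ",
                        paste(missing_cols, collapse = ", "), "."))
  }
  tbl <- tibble::as_tibble(table)[cohort_columns()]
  tbl$id <- as.character(tbl$id)
  tbl$age <- as.integer(tbl$age)
  tbl$simd_decile <- as.integer(tbl$simd_decile)
  tbl$score <- as.double(tbl$score)
  tbl$outcome <- as.integer(tbl$outcome)
  tbl$icd10_code <- as.character(tbl$icd10_code)
  for (col in names(cohort_levels)) {
    v <- trimws(as.character(tbl[[col]]))
    v[v %in% c("", "NA")] <- NA_character_
    bad <- which(!is.na(v) & !(v %in% cohort_levels[[col]]))
    if (length(bad)) {
      cohort_abort("bad_category",
                   sprintf("Invalid value '%s' for field '%s' at row %d.",
                           v[bad[1]], col, bad[1]))
    }
    tbl[[col]] <- v
  }
  for (col in cohort_required) {
    bad <- which(is.na(tbl[[col]]))
    if (length(bad)) {
      cohort_abort("missing_value",
                   sprintf("Field '%s' is missing at row %d but may never be missing.",
                           col, bad[1]))
    }
  }
  bad <- which(tbl$score <= 0 | tbl$score >= 1)
  if (length(bad)) {
    cohort_abort("score_range",
                 sprintf("Score %g at row %d is outside the open interval (0, 1).",
                         tbl$score[bad[1]], bad[1]))
  }
  bad <- which(tbl$age < 0)
  if (length(bad)) {
    cohort_abort("age_range", sprintf("Negative age at row %d.", bad[1]))
  }
  bad <- which(tbl$simd_decile < 1 | tbl$simd_decile > 10)
  if (length(bad)) {
    cohort_abort("simd_range",
                 sprintf("simd_decile %d at row %d is outside 1..10.",
                         tbl$simd_decile[bad[1]], bad[1]))
  }
  bad <- which(!(tbl$outcome %in% c(0L, 1L)))
  if (length(bad)) {
    cohort_abort("outcome_range", sprintf("Outcome at row %d is not 0/1.", bad[1]))
  }
  bad <- which((tbl$outcome == 0L) != (tbl$event_kind == "none"))
  if (length(bad)) {
    cohort_abort("event_kind_mismatch",
                 sprintf("Row %d: outcome and event_kind disagree (outcome %d, event_kind '%s').",
                         bad[1], tbl$outcome[bad[1]], tbl$event_kind[bad[1]]))
  }
  code <- trimws(tbl$icd10_code)
  code[!is.na(code) & code %in% c("", "NA")] <- NA_character_
  tbl$icd10_code <- code
  bad <- which(tbl$outcome == 0L & !is.na(tbl$icd10_code))
  if (length(bad)) {
    cohort_abort("icd10_unexpected",
                 sprintf("Row %d has icd10_code but outcome 0.", bad[1]))
  }
  if (require_icd10) {
    bad <- which(tbl$outcome == 1L & is.na(tbl$icd10_code))
    if (length(bad)) {
      cohort_abort("icd10_missing",
                   sprintf("Row %d has outcome 1 but no icd10_code (set require_icd10 = FALSE to allow).",
                           bad[1]))
    }
  }
  tbl
}

#' Read a cohort table from delimited text
#'
#' @param path Path to a delimited text file with a header row naming the
#'   [cohort_columns()] schema. Missing categoricals use the sentinel `"NA"`.
#' @param delim Field delimiter, default comma.
#' @param require_icd10 Passed to [validate_cohort()].
#' @return A validated cohort tibble, row order as on file.
#' @export
read_cohort <- function(path, delim = ",", require_icd10 = TRUE) {
  if (!file.exists(path)) {
    cohort_abort("file_not_found", paste0("Cohort file not found: ", path))
  }
  raw <- readr::read_delim(
    path, delim = delim, na = "NA", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  validate_cohort(raw, require_icd10 = require_icd10)
}

#' Write a cohort table to delimited text
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(t, p))` reproduces
#' `t` field-for-field. Missing categoricals are written as `"NA"`.
#'
#' @param table A valid cohort table.
#' @param path Output file path.
#' @param delim Field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, delim = ",") {
  tbl <- validate_cohort(table, require_icd10 = FALSE)
  readr::write_delim(tbl, path, delim = delim, na = "NA")
  invisible(path)
}
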