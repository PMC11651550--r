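#' Map from ICD-10 first letters to admission-type categories
#'
#' The default follows chapter letter-groups, with two groupings fixed by
#' convention: letters S, T, V, X, Y form the `external` category
#' (accidents, intentional self-harm, assault, and medical or surgical
#' complications) and letter R forms `abnormality_NEC` (symptoms, signs and
#' findings not elsewhere classified — essentially missing diagnostic
#' information). Every letter A-Z maps to exactly one category; codes with
#' an unmapped or invalid first character route to `"unknown"` with a
#' warning. Letter-level grouping is an approximation for letters shared
#' across chapters (e.g. D spans blood disorders and in-situ neoplasms).
#'
#' @param overrides Named character vector of letter -> category overrides.
#' @return Named character vector over LETTERS.
#' @export
admission_type_map <- function(overrides = NULL) {
  map <- c(
    A = "infectious", B = "infectious",
    C = "neoplasm", D = "neoplasm_blood",
    E = "endocrine", F = "mental_behavioural", G = "nervous",
    H = "eye_ear", I = "circulatory", J = "respiratory",
    K = "digestive", L = "skin", M = "musculoskeletal",
    N = "genitourinary", O = "obstetric", P = "perinatal",
    Q = "congenital", R = "abnormality_NEC",
    S = "external", T = "external",
    U = "special_use", V = "external", W = "other",
    X = "external", Y = "external", Z = "health_status"
  )
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), LETTERS)
    if (length(bad)) {
      abort(sprintf("Override keys must be single letters; got %s.",
                    paste(bad, collapse = ", ")),
            class = "fairaudit_error_config")
    }
    map[names(overrides)] <- overrides
  }
  map
}

#' Read or write an admission-type map as two-column text
#'
#' @param path File path; two delimited columns `letter`, `category`.
#' @param map Named character vector as from [admission_type_map()].
#' @return The map (read) or `path` invisibly (write).
#' @export
read_type_map <- function(path) {
  df <- readr::read_delim(path, delim = ",", show_col_types = FALSE,
                          progress = FALSE)
  admission_type_map(setNames(df$category, df$letter))
}

#' @rdname read_type_map
#' @export
write_type_map <- function(map, path) {
  readr::write_delim(
    tibble::tibble(letter = names(map), category = unname(map)),
    path, delim = ","
  )
  invisible(path)
}

#' Classify ICD-10 codes into admission-type categories
#'
#' Uses the uppercased first letter of each code; case-insensitive. Empty,
#' missing or non-alphabetic codes classify as `"unknown"` with a warning.
#'
#' @param codes Character vector of ICD-10 codes (e.g. `"J18.9"`).
#' @param map A letter-to-category map, see [admission_type_map()].
#' @return Character vector of categories.
#' @export
classify_admission_type <- function(codes, map = admission_type_map()) {
  first <- toupper(substr(trimws(as.character(codes)), 1, 1))
  out <- unname(map[first])
  bad <- is.na(out)
  if (any(bad)) {
    warn(sprintf("%d ICD-10 code(s) empty or unmappable; classified as 'unknown'.",
                 sum(bad)),
         class = "fairaudit_warning_unknown_code")
    out[bad] <- "unknown"
  }
  out
}

#' Decompose false negatives by admission type
#'
#' For one group, and separately for admissions and for deaths without a
#' prior admission, compares the composition of event types among all
#' events (proportions `A`) with the composition among low-score events —
#' those with `score < threshold`, the false negatives of the
#' score-below-threshold decision rule (proportions `B`). A positive
#' contrast `B - A` marks an admission type the score disproportionately
#' fails to anticipate. Intervals for `B - A` come from a nonparametric
#' bootstrap over the group's events (default 1000 replicates, percentile),
#' which respects the nesting of the low-score events within all events.
#'
#' @param table A cohort table.
#' @param rows Logical row mask selecting the group.
#' @param threshold Score threshold defining "low score", strict `<`;
#'   default 0.1.
#' @param map Letter-to-category map.
#' @param n_boot Bootstrap replicates.
#' @param seed Bootstrap seed, or NULL.
#' @param conf Confidence level.
#' @return A tibble with one row per (event_kind, category): counts
#'   `n_all`, `n_low`, proportions `A`, `B`, contrast `diff = B - A` and its
#'   interval. When the group has no low-score events of a kind, `B` and
#'   `diff` are `NA`.
#' @export
decomposition_table <- function(table, rows = NULL, threshold = 0.1,
                                map = admission_type_map(),
                                n_boot = 1000, seed = NULL, conf = 0.95) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie in (0, 1).", class = "fairaudit_error_config")
  }
  rows <- rows %||% rep(TRUE, nrow(table))
  sub <- table[rows & table$outcome == 1L, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort("Group contains no events.", class = "fairaudit_error_empty")
  }
  sub$category <- classify_admission_type(sub$icd10_code, map)
  alpha <- (1 - conf) / 2

  one_kind <- function(kind) {
    ev <- sub[sub$event_kind == kind, , drop = FALSE]
    if (nrow(ev) == 0) return(NULL)
    cats <- sort(unique(ev$category))
    low <- ev$score < threshold
    n_all <- as.numeric(table(factor(ev$category, levels = cats)))
    n_low <- as.numeric(table(factor(ev$category[low], levels = cats)))
    A <- n_all / sum(n_all)
    has_low <- any(low)
    B <- if (has_low) n_low / sum(n_low) else rep(NA_real_, length(cats))
    d <- B - A
    lo <- hi <- rep(NA_real_, length(cats))
    if (has_low && n_boot > 0) {
      reps <- with_seed(seed, {
        m <- matrix(NA_real_, n_boot, length(cats))
        n_ev <- nrow(ev)
        cat_int <- match(ev$category, cats)
        for (r in seq_len(n_boot)) {
          ii <- sample.int(n_ev, n_ev, replace = TRUE)
          ca <- cat_int[ii]; lw <- low[ii]
          ta <- tabulate(ca, nbins = length(cats))
          tb <- tabulate(ca[lw], nbins = length(cats))
          if (any(lw)) m[r, ] <- tb / sum(tb) - ta / sum(ta)
        }
        m
      })
      lo <- apply(reps, 2, quantile, probs = alpha, na.rm = TRUE,
                  names = FALSE)
      hi <- apply(reps, 2, quantile, probs = 1 - alpha, na.rm = TRUE,
                  names = FALSE)
    }
    tibble::tibble(
      event_kind = kind, category = cats,
      n_all = n_all, n_low = n_low,
      A = A, B = B, diff = d, lower = lo, upper = hi
    )
  }
  out <- dplyr::bind_rows(
    one_kind("admission"),
    one_kind("death_without_admission")
  )
  out
}
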