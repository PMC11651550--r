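#' Define a two-group comparison
#'
#' A group spec names a grouping variable and two disjoint membership
#' predicates; rows matching neither predicate are excluded from that
#' comparison (in particular, rows with a missing grouping variable).
#'
#' @param variable Name of the grouping variable (informative label).
#' @param label_a,label_b Names of the two compared groups.
#' @param predicate_a,predicate_b Functions taking the cohort table and
#'   returning a logical vector of membership (NA treated as FALSE).
#' @return An object of class `group_spec`.
#' @seealso [builtin_group_specs()] for the six standard comparisons.
#' @export
group_spec <- function(variable, label_a, label_b, predicate_a, predicate_b) {
  stopifnot(is.character(variable), is.character(label_a), is.character(label_b),
            is.function(predicate_a), is.function(predicate_b))
  if (identical(label_a, label_b)) {
    abort("Group labels must differ.", class = "fairaudit_error_groupspec")
  }
  structure(
    list(variable = variable, label_a = label_a, label_b = label_b,
         predicate_a = predicate_a, predicate_b = predicate_b),
    class = "group_spec"
  )
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf("<group_spec> %s: %s vs %s\n", x$variable, x$label_a, x$label_b))
  invisible(x)
}

#' The six built-in demographic comparisons
#'
#' Reproduces the standard comparison menu: sex (M vs F); age (over 65,
#' inclusive, vs under 25, inclusive — the 26-64 middle is excluded);
#' deprivation (most vs least deprived quintile, built from the top and
#' bottom two SIMD deciles); ethnicity (white vs nonwhite, missing excluded);
#' urban vs rural; mainland vs island. Missing values of the grouping
#' variable are always excluded.
#'
#' @return Named list of [group_spec()] objects.
#' @export
builtin_group_specs <- function() {
  list(
    sex = group_spec(
      "sex", "M", "F",
      function(t) t$sex == "M",
      function(t) t$sex == "F"
    ),
    age = group_spec(
      "age", "over65", "under25",
      function(t) t$age >= 65,
      function(t) t$age <= 25
    ),
    deprivation = group_spec(
      "deprivation", "most_deprived", "least_deprived",
      function(t) t$simd_decile %in% c(1L, 2L),
      function(t) t$simd_decile %in% c(9L, 10L)
    ),
    ethnicity = group_spec(
      "ethnicity", "white", "nonwhite",
      function(t) !is.na(t$ethnicity) & t$ethnicity == "white",
      function(t) !is.na(t$ethnicity) & t$ethnicity == "nonwhite"
    ),
    urban_rural = group_spec(
      "urban_rural", "urban", "rural",
      function(t) !is.na(t$urban_rural) & t$urban_rural == "urban",
      function(t) !is.na(t$urban_rural) & t$urban_rural == "rural"
    ),
    mainland_island = group_spec(
      "mainland_island", "mainland", "island",
      function(t) !is.na(t$mainland_island) & t$mainland_island == "mainland",
      function(t) !is.na(t$mainland_island) & t$mainland_island == "island"
    )
  )
}

#' Assign comparison labels to cohort rows
#'
#' @param table A cohort table.
#' @param spec A [group_spec()].
#' @return A factor of length `nrow(table)` with levels
#'   `c(label_a, label_b, "excluded")`. Rows matching neither predicate
#'   (including missing grouping values) are `"excluded"`.
#' @export
assign_group <- function(table, spec) {
  stopifnot(inherits(spec, "group_spec"))
  a <- spec$predicate_a(table)
  b <- spec$predicate_b(table)
  a[is.na(a)] <- FALSE
  b[is.na(b)] <- FALSE
  if (any(a & b)) {
    abort(sprintf("Group predicates for '%s' overlap at row %d.",
                  spec$variable, which(a & b)[1]),
          class = "fairaudit_error_groupspec")
  }
  out <- rep("excluded", nrow(table))
  out[a] <- spec$label_a
  out[b] <- spec$label_b
  factor(out, levels = c(spec$label_a, spec$label_b, "excluded"))
}

#' Descriptive summary of a cohort by group
#'
#' A Table-1-style summary: one column for the whole cohort (`All`) and one
#' per group label from each supplied spec. Percentages for each categorical
#' are computed over the whole (sub)group, so complementary categories plus
#' their missing row sum to 100 up to rounding.
#'
#' @param table A cohort table.
#' @param specs List of [group_spec()] objects, default the built-ins.
#' @return A tibble with a `statistic` column and one numeric column per
#'   group. Counts are in thousands; all other rows are percentages except
#'   mean/SD of age.
#' @export
summarize_cohort <- function(table, specs = builtin_group_specs()) {
  if (nrow(table) == 0) {
    abort("Cannot summarise an empty cohort.", class = "fairaudit_error_empty")
  }
  one_col <- function(rows) {
    sub <- table[rows, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0) {
      warn("Empty group in cohort summary; returning all-missing column.")
      return(rep(NA_real_, 14))
    }
    pct <- function(x) 100 * sum(x, na.rm = TRUE) / n
    c(
      n_thousand = n / 1000,
      pct_male = pct(sub$sex == "M"),
      age_mean = mean(sub$age),
      age_sd = sd(sub$age),
      pct_most_deprived = pct(sub$simd_decile %in% c(1L, 2L)),
      pct_least_deprived = pct(sub$simd_decile %in% c(9L, 10L)),
      pct_white = pct(sub$ethnicity == "white"),
      pct_nonwhite = pct(sub$ethnicity == "nonwhite"),
      pct_ethnicity_missing = pct(is.na(sub$ethnicity)),
      pct_urban = pct(sub$urban_rural == "urban"),
      pct_rural = pct(sub$urban_rural == "rural"),
      pct_mainland = pct(sub$mainland_island == "mainland"),
      pct_island = pct(sub$mainland_island == "island"),
      pct_event = pct(sub$outcome == 1L)
    )
  }
  cols <- list(All = one_col(rep(TRUE, nrow(table))))
  for (spec in specs) {
    g <- assign_group(table, spec)
    for (lab in c(spec$label_a, spec$label_b)) {
      cols[[lab]] <- one_col(g == lab)
    }
  }
  out <- tibble::tibble(statistic = names(cols[[1]]))
  for (nm in names(cols)) out[[nm]] <- unname(cols[[nm]])
  out
}
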