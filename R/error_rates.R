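#' False omission rate curve
#'
#' At each cutoff `c`, among individuals with `score < c` (predicted not to
#' have the event), the fraction that nonetheless experienced the event:
#' `P(Y = 1 | score < c)`. Cutoffs where no scores fall below `c` are
#' undefined (`NA` estimate, `n_effective` 0), never silently zero.
#' Pointwise 95% Wilson intervals.
#'
#' @param scores Numeric scores in (0, 1) for one group.
#' @param outcomes 0/1 outcomes.
#' @param grid Cutoff grid.
#' @param group_label Metadata label.
#' @param conf Confidence level.
#' @return A curve tibble, see [score_cdf()].
#' @export
for_curve <- function(scores, outcomes, grid = cutoff_grid(),
                      group_label = "group", conf = 0.95) {
  check_grid(grid)
  if (length(scores) == 0) {
    abort("Cannot compute a FOR curve for an empty group.",
          class = "fairaudit_error_empty")
  }
  ord <- order(scores)
  s <- scores[ord]
  y <- outcomes[ord]
  below <- count_below(s, grid)
  ev_below <- c(0, cumsum(y))[below + 1L]
  ci <- wilson_ci(ev_below, below, conf)
  curve_tibble(grid, ci$estimate, ci$lower, ci$upper, ci$se, below,
               "for", group_label)
}

#' False discovery rate curve
#'
#' At each cutoff `c`, among individuals with `score >= c` (predicted to
#' have the event), the fraction that did not experience it:
#' `P(Y = 0 | score >= c)`. Cutoffs no score reaches are undefined.
#' Pointwise 95% Wilson intervals.
#'
#' @inheritParams for_curve
#' @return A curve tibble.
#' @export
fdr_curve <- function(scores, outcomes, grid = cutoff_grid(),
                      group_label = "group", conf = 0.95) {
  check_grid(grid)
  if (length(scores) == 0) {
    abort("Cannot compute a FDR curve for an empty group.",
          class = "fairaudit_error_empty")
  }
  ord <- order(scores)
  s <- scores[ord]
  y <- outcomes[ord]
  n <- length(s)
  below <- count_below(s, grid)
  above <- n - below
  ev_below <- c(0, cumsum(y))[below + 1L]
  nonev_above <- (n - sum(y)) - (below - ev_below)
  ci <- wilson_ci(nonev_above, above, conf)
  curve_tibble(grid, ci$estimate, ci$lower, ci$upper, ci$se, above,
               "fdr", group_label)
}

#' Directly standardised (adjusted) FOR or FDR curve
#'
#' Computes the within-stratum FOR (or FDR) of a group over age-band x sex x
#' SIMD-decile strata and averages it under a fixed reference strata
#' distribution, removing between-group differences mediated by age, sex
#' and deprivation. Strata with an empty conditioning set at a cutoff (or
#' absent from the group) are dropped there, the remaining reference
#' weights renormalised, and the dropped reference mass reported in the
#' `dropped_mass` column. Pointwise intervals by stratified bootstrap
#' (resampling within the group's strata; percentile intervals).
#'
#' @param table A cohort table.
#' @param rows Logical row mask selecting the group.
#' @param metric `"for"` or `"fdr"`.
#' @param grid Cutoff grid.
#' @param reference Reference strata distribution: `"pooled_pair"` (default;
#'   the pooled distribution of the two compared groups, making a pair of
#'   adjusted curves commensurable), `"other_group"`, or `"self"` (which
#'   reproduces the raw curve up to empty-stratum handling). For
#'   `"pooled_pair"` and `"other_group"` the reference is restricted to the
#'   strata occupied by both groups and renormalised: without this common-
#'   support restriction the two curves of a pair would implicitly
#'   standardise to different distributions wherever the smaller group
#'   leaves strata empty, biasing their difference. Alternatively supply
#'   `ref_dist` directly.
#' @param other_rows Row mask of the comparison group; required for
#'   `"pooled_pair"` and `"other_group"`.
#' @param ref_dist Optional [strata_distribution()] tibble overriding
#'   `reference`.
#' @param age_bands Age band edges.
#' @param strata_vars Stratification dimensions, see
#'   [counterfactual_cdf()].
#' @param n_boot Bootstrap replicates, default 1000.
#' @param seed Bootstrap seed, or NULL.
#' @param group_label Metadata label.
#' @return A curve tibble with `adjusted = TRUE` and a `dropped_mass`
#'   column.
#' @export
adjusted_rate_curve <- function(table, rows, metric = c("for", "fdr"),
                                grid = cutoff_grid(),
                                reference = c("pooled_pair", "other_group",
                                              "self"),
                                other_rows = NULL, ref_dist = NULL,
                                age_bands = default_age_bands(),
                                strata_vars = c("age", "sex", "simd"),
                                n_boot = 1000, seed = NULL,
                                group_label = "group") {
  metric <- match.arg(metric)
  check_grid(grid)
  if (!any(rows)) {
    abort("Cannot compute an adjusted rate curve for an empty group.",
          class = "fairaudit_error_empty")
  }
  if (is.null(ref_dist)) {
    reference <- match.arg(reference)
    ref_dist <- switch(
      reference,
      self = strata_distribution(table, rows, age_bands, strata_vars),
      other_group = {
        if (is.null(other_rows)) {
          abort("`other_rows` is required for reference = 'other_group'.",
                class = "fairaudit_error_config")
        }
        strata_distribution(table, other_rows, age_bands, strata_vars)
      },
      pooled_pair = {
        if (is.null(other_rows)) {
          abort("`other_rows` is required for reference = 'pooled_pair'.",
                class = "fairaudit_error_config")
        }
        strata_distribution(table, rows | other_rows, age_bands,
                            strata_vars)
      }
    )
    if (reference %in% c("pooled_pair", "other_group")) {
      common <- intersect(
        make_strata(table[rows, , drop = FALSE], age_bands, strata_vars)$key,
        make_strata(table[other_rows, , drop = FALSE], age_bands,
                    strata_vars)$key)
      ref_dist <- ref_dist[ref_dist$stratum %in% common, , drop = FALSE]
      if (nrow(ref_dist) == 0) {
        abort("No overlap between reference strata and group strata.",
              class = "fairaudit_error_no_overlap")
      }
      ref_dist$weight <- ref_dist$weight / sum(ref_dist$weight)
    }
  }
  sub <- table[rows, , drop = FALSE]
  keys <- make_strata(sub, age_bands, strata_vars)$key
  w <- setNames(ref_dist$weight, ref_dist$stratum)
  binned <- bin_strata(sub$score, sub$outcome, keys, grid)
  binned <- binned[intersect(names(binned), names(w))]
  if (length(binned) == 0) {
    abort("No overlap between reference strata and group strata.",
          class = "fairaudit_error_no_overlap")
  }
  res <- strata_curve_boot(binned, w, grid, metric, n_boot = n_boot,
                           seed = seed)
  est <- res$estimate
  est[res$dropped_mass >= 1 - 1e-12] <- NA_real_
  curve_tibble(grid, est, res$lower, res$upper, res$se, res$n_effective,
               paste0("adjusted_", metric), group_label, adjusted = TRUE,
               dropped_mass = res$dropped_mass)
}
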