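curve_tibble <- function(grid, est, lower, upper, se, n_eff,
                         metric, group, adjusted = FALSE,
                         dropped_mass = NULL) {
  out <- tibble::tibble(
    cutoff = grid,
    estimate = est, lower = lower, upper = upper, se = se,
    n_effective = as.numeric(n_eff),
    metric = metric, group = group, adjusted = adjusted
  )
  if (!is.null(dropped_mass)) out$dropped_mass <- dropped_mass
  out
}

#' Score cumulative distribution (demographic parity) curve
#'
#' At each cutoff `c`, the fraction of the group's scores strictly below
#' `c`, with pointwise 95% Wilson intervals based on the group size. This is
#' the demographic-parity view of a score: a right-shifted CDF means
#' generally higher scores.
#'
#' @param scores Numeric vector of scores in (0, 1) for one group.
#' @param grid Cutoff grid, see [cutoff_grid()].
#' @param group_label Label stored in the curve metadata.
#' @param conf Confidence level.
#' @return A curve tibble with columns `cutoff`, `estimate`, `lower`,
#'   `upper`, `se`, `n_effective`, `metric`, `group`, `adjusted`.
#' @export
score_cdf <- function(scores, grid = cutoff_grid(), group_label = "group",
                      conf = 0.95) {
  check_grid(grid)
  if (length(scores) == 0) {
    abort("Cannot compute a score CDF for an empty group.",
          class = "fairaudit_error_empty")
  }
  n <- length(scores)
  below <- count_below(sort(scores), grid)
  ci <- wilson_ci(below, n, conf)
  curve_tibble(grid, ci$estimate, ci$lower, ci$upper, ci$se, n,
               "score_cdf", group_label)
}

#' Counterfactual score distribution by covariate reweighting
#'
#' The score CDF a target group `g` would show if its scores were drawn from
#' the comparison group `g'`, holding the target group's distribution over
#' age-band x sex x SIMD-decile strata fixed: at each cutoff the
#' within-stratum CDFs of `g'` are averaged under `g`'s strata weights.
#' Differences between this curve and `g`'s raw CDF isolate group effects
#' not mediated through age, sex and deprivation. Strata occupied by `g` but
#' empty in `g'` are dropped with a warning reporting the dropped mass, and
#' the remaining weights renormalised. Pointwise intervals come from a
#' stratified bootstrap (resampling within strata of `g'`).
#'
#' @param table A cohort table.
#' @param target,source Logical row masks for the target group `g` (weights)
#'   and source group `g'` (scores).
#' @param grid Cutoff grid.
#' @param age_bands Age band edges for stratification.
#' @param strata_vars Stratification dimensions, see
#'   [strata_distribution()]. When the grouping variable is itself one of
#'   the dimensions (age, sex, deprivation) it must be dropped here, since
#'   no stratum could otherwise be shared between the groups.
#' @param n_boot Bootstrap replicates (percentile intervals); default 1000.
#' @param seed Seed for the bootstrap, or NULL to use the current RNG state.
#' @param group_label Metadata label for the curve.
#' @return A curve tibble (see [score_cdf()]) with metric
#'   `"counterfactual_cdf"`.
#' @export
counterfactual_cdf <- function(table, target, source, grid = cutoff_grid(),
                               age_bands = default_age_bands(),
                               strata_vars = c("age", "sex", "simd"),
                               n_boot = 1000, seed = NULL,
                               group_label = "counterfactual") {
  check_grid(grid)
  if (!any(target) || !any(source)) {
    abort("Both target and source groups must be non-empty.",
          class = "fairaudit_error_empty")
  }
  wdist <- strata_distribution(table, target, age_bands, strata_vars)
  src <- table[source, , drop = FALSE]
  src_keys <- make_strata(src, age_bands, strata_vars)$key
  w <- setNames(wdist$weight, wdist$stratum)
  missing_strata <- setdiff(names(w), unique(src_keys))
  if (length(missing_strata)) {
    dropped <- sum(w[missing_strata])
    warn(sprintf(
      "%d target stratum/strata (mass %.4f) unoccupied in the source group; weights renormalised.",
      length(missing_strata), dropped),
      class = "fairaudit_warning_dropped_strata")
    w <- w[setdiff(names(w), missing_strata)]
    if (sum(w) <= 0) {
      abort("No stratum is occupied by both groups.",
            class = "fairaudit_error_no_overlap")
    }
    w <- w / sum(w)
  }
  binned <- bin_strata(src$score, NULL, src_keys, grid)
  binned <- binned[intersect(names(binned), names(w))]
  res <- strata_curve_boot(binned, w, grid, "cdf", n_boot = n_boot,
                           seed = seed)
  curve_tibble(grid, res$estimate, res$lower, res$upper, res$se,
               res$n_effective, "counterfactual_cdf", group_label,
               adjusted = TRUE)
}

#' Pointwise difference of two curves
#'
#' Estimate `a - b` at each cutoff, with a pointwise interval from
#' independent-groups variance addition applied to the input interval
#' half-widths (which are bootstrap-based whenever the input curve is):
#' the lower half-width of the difference is
#' `sqrt((a_est - a_lower)^2 + (b_upper - b_est)^2)` and symmetrically for
#' the upper, preserving any asymmetry of percentile intervals. Cutoffs
#' where either input is undefined are undefined.
#'
#' @param a,b Curve tibbles on identical grids.
#' @param conf Unused (intervals inherit the inputs' level); kept for
#'   signature stability.
#' @return A curve tibble with metric `"<metric_a> - <metric_b>"`.
#' @export
curve_difference <- function(a, b, conf = 0.95) {
  if (nrow(a) != nrow(b) || any(abs(a$cutoff - b$cutoff) > 1e-12)) {
    abort("Curves must share an identical cutoff grid.",
          class = "fairaudit_error_grid")
  }
  est <- a$estimate - b$estimate
  se <- sqrt(a$se^2 + b$se^2)
  half_lo <- sqrt((a$estimate - a$lower)^2 + (b$upper - b$estimate)^2)
  half_up <- sqrt((a$upper - a$estimate)^2 + (b$estimate - b$lower)^2)
  curve_tibble(
    a$cutoff, est, est - half_lo, est + half_up, se,
    pmin(a$n_effective, b$n_effective),
    metric = paste(a$metric[1], "-", b$metric[1]),
    group = paste(a$group[1], "-", b$group[1]),
    adjusted = a$adjusted[1] || b$adjusted[1]
  )
}

#' Write or read a curve as delimited text
#'
#' @param curve A curve tibble.
#' @param path File path.
#' @param delim Delimiter, default comma.
#' @return `path` invisibly (write); the curve tibble (read).
#' @export
write_curve <- function(curve, path, delim = ",") {
  readr::write_delim(curve, path, delim = delim, na = "NA")
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path, delim = ",") {
  readr::read_delim(path, delim = delim, na = "NA", show_col_types = FALSE,
                    progress = FALSE)
}
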