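check_two_classes <- function(outcomes) {
  if (length(outcomes) == 0 || all(outcomes == 1L) || all(outcomes == 0L)) {
    abort("Both outcome classes must be present.",
          class = "fairaudit_error_single_class")
  }
}

#' ROC curve points on a cutoff grid
#'
#' At each cutoff `c`, a positive prediction is `score >= c`:
#' TPR = P(score >= c | Y = 1) and FPR = P(score >= c | Y = 0).
#'
#' @param scores Numeric scores in (0, 1).
#' @param outcomes 0/1 outcomes.
#' @param grid Cutoff grid.
#' @return A tibble with columns `cutoff`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, outcomes, grid = cutoff_grid()) {
  check_grid(grid)
  check_two_classes(outcomes)
  pos <- sort(scores[outcomes == 1L])
  neg <- sort(scores[outcomes == 0L])
  tibble::tibble(
    cutoff = grid,
    fpr = 1 - count_below(neg, grid) / length(neg),
    tpr = 1 - count_below(pos, grid) / length(pos)
  )
}

#' AUROC with a rank-based standard error
#'
#' The estimate is the probability that a randomly chosen individual who
#' experienced the event scores higher than one who did not, computed as
#' (concordant pairs + half of tied pairs) / (n1 * n0) — the standardised
#' rank-sum (Mann-Whitney) statistic, appropriate for scores with display
#' granularity and hence ties. The standard error uses the asymptotically
#' valid placement-value (DeLong) variance estimator:
#' `var(placements of events)/n1 + var(placements of non-events)/n0`.
#'
#' @param scores Numeric scores.
#' @param outcomes 0/1 outcomes; both classes must be present.
#' @return A list with `estimate`, `se`, `n_event`, `n_nonevent`, and
#'   `se_method = "placement (DeLong)"`.
#' @export
auroc_with_se <- function(scores, outcomes) {
  check_two_classes(outcomes)
  pos <- outcomes == 1L
  n1 <- as.double(sum(pos)); n0 <- as.double(sum(!pos))
  r_all <- rank(scores, ties.method = "average")
  auc <- (sum(r_all[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # midrank placements: for an event i, the fraction of non-events scoring
  # below it (ties half-credit), and symmetrically for non-events
  r_pos <- rank(scores[pos], ties.method = "average")
  r_neg <- rank(scores[!pos], ties.method = "average")
  v10 <- (r_all[pos] - r_pos) / n0        # placements of events
  v01 <- 1 - (r_all[!pos] - r_neg) / n1   # placements of non-events
  s10 <- if (n1 > 1) var(v10) else 0
  s01 <- if (n0 > 1) var(v01) else 0
  list(
    estimate = auc,
    se = sqrt(s10 / n1 + s01 / n0),
    n_event = n1, n_nonevent = n0,
    se_method = "placement (DeLong)"
  )
}

#' Calibration (reliability) curve
#'
#' Bins the scores and plots, per bin, the mean score against the observed
#' event rate with pointwise 95% Wilson intervals. A well-calibrated score
#' has the curve on the identity: among individuals scored near `c`, about a
#' fraction `c` experience the event. Bins with fewer members than
#' `min_count` are omitted and reported via the `"omitted_bins"` attribute
#' (and a message).
#'
#' @param scores Numeric scores in (0, 1).
#' @param outcomes 0/1 outcomes.
#' @param bins Number of bins, default 20.
#' @param scheme `"width"` (equal-width bins over (0,1), default) or
#'   `"quantile"` (equal-count bins).
#' @param min_count Minimum bin membership, default 50.
#' @param conf Confidence level.
#' @return A tibble with columns `bin`, `score_mean` (x), `event_rate` (y),
#'   `lower`, `upper`, `se`, `n`; attribute `omitted_bins` lists dropped
#'   bins with their counts.
#' @export
calibration_curve <- function(scores, outcomes, bins = 20,
                              scheme = c("width", "quantile"),
                              min_count = 50, conf = 0.95) {
  scheme <- match.arg(scheme)
  if (length(scores) == 0) {
    abort("Cannot compute a calibration curve for an empty group.",
          class = "fairaudit_error_empty")
  }
  breaks <- if (scheme == "width") {
    seq(0, 1, length.out = bins + 1)
  } else {
    unique(quantile(scores, probs = seq(0, 1, length.out = bins + 1),
                    names = FALSE))
  }
  idx <- findInterval(scores, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  df <- tibble::tibble(bin = idx, score = scores, outcome = outcomes)
  agg <- dplyr::summarise(
    dplyr::group_by(df, .data$bin),
    score_mean = mean(.data$score),
    events = sum(.data$outcome),
    n = dplyr::n(), .groups = "drop"
  )
  keep <- agg$n >= min_count
  omitted <- agg[!keep, c("bin", "n")]
  if (nrow(omitted)) {
    inform(sprintf("Omitting %d calibration bin(s) with fewer than %d members.",
                   nrow(omitted), min_count))
  }
  agg <- agg[keep, , drop = FALSE]
  if (nrow(agg) == 0) {
    abort("All calibration bins fall below the minimum membership.",
          class = "fairaudit_error_empty")
  }
  ci <- wilson_ci(agg$events, agg$n, conf)
  out <- tibble::tibble(
    bin = agg$bin,
    score_mean = agg$score_mean,
    event_rate = ci$estimate,
    lower = ci$lower, upper = ci$upper, se = ci$se,
    n = agg$n
  )
  attr(out, "omitted_bins") <- omitted
  attr(out, "breaks") <- breaks
  out
}
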