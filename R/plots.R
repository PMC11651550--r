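#' Plot a pair of curves with a difference sub-panel
#'
#' Upper panel: the two group curves with pointwise confidence bands; lower
#' sub-panel: their difference with a zero reference line. The x-axis can be
#' log-scaled, the usual presentation for score CDFs concentrated at low
#' scores.
#'
#' @param a,b Curve tibbles on the same grid.
#' @param diff Optional precomputed [curve_difference()]; computed if NULL.
#' @param log_x Log-scale the cutoff axis (default TRUE).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_curve_pair <- function(a, b, diff = NULL, log_x = TRUE, title = NULL) {
  diff <- diff %||% curve_difference(a, b)
  top <- dplyr::bind_rows(a, b)
  top$panel <- top$metric
  diff$group <- "difference"
  diff$panel <- "difference"
  dat <- dplyr::bind_rows(top, diff)
  dat$panel <- factor(ifelse(dat$panel == "difference", "difference",
                             "curve"),
                      levels = c("curve", "difference"))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$cutoff,
                                         y = .data$estimate,
                                         colour = .data$group,
                                         fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = data.frame(panel = factor("difference",
                                                         levels = levels(dat$panel))),
                        ggplot2::aes(yintercept = 0),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "score cutoff", y = a$metric[1], title = title,
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a false-negative decomposition
#'
#' Proportion of each admission type among all events (`A`, x-axis) against
#' the over-representation among low-score events (`B - A`, y-axis) with
#' pointwise interval bars and a `y = 0` reference line; points above the
#' line are admission types the score disproportionately fails to
#' anticipate.
#'
#' @param dt A [decomposition_table()] tibble.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_decomposition <- function(dt, title = NULL) {
  dat <- dt[!is.na(dt$diff), , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$A, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper),
                           width = 0, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$category),
                       vjust = -0.6, size = 2.7, check_overlap = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$event_kind)) +
    ggplot2::labs(x = "proportion among all events (A)",
                  y = "B - A (low-score minus all)", title = title) +
    ggplot2::theme_minimal()
}

#' Plot calibration curves for one or more groups
#'
#' @param curves Named list of [calibration_curve()] tibbles.
#' @param title Plot title.
#' @return A ggplot object with the identity line as reference.
#' @export
plot_calibration <- function(curves, title = NULL) {
  dat <- dplyr::bind_rows(lapply(names(curves), function(nm) {
    dplyr::mutate(curves[[nm]], group = nm)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score_mean,
                                    y = .data$event_rate,
                                    colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40",
                         linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper),
                             size = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "mean predicted score", y = "observed event rate",
                  title = title, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot ROC curves for one or more groups
#'
#' @param rocs Named list of [roc_points()] tibbles.
#' @param aurocs Optional named list of [auroc_with_se()] results, added to
#'   the legend labels.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_roc <- function(rocs, aurocs = NULL, title = NULL) {
  dat <- dplyr::bind_rows(lapply(names(rocs), function(nm) {
    lab <- if (!is.null(aurocs[[nm]])) {
      sprintf("%s (AUROC %.3f ± %.3f)", nm, aurocs[[nm]]$estimate,
              aurocs[[nm]]$se)
    } else nm
    dplyr::mutate(rocs[[nm]], group = lab)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40",
                         linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = title, colour = NULL) +
    ggplot2::theme_minimal()
}
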