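# ggplot2 displays for the pipeline's result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano-style display of an association table
#'
#' Combined estimate against -log10 combined p, colored by the BH-adjusted
#' significance flag; falls back to the discovery estimates when the
#' combined fit has not been run.
#'
#' @param object An `assoc_table`.
#' @param alpha Reference level drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot assoc_table
#' @export
autoplot.assoc_table <- function(object, alpha = 0.05, ...) {
  has_combined <- "p_combined" %in% names(object)
  df <- tibble::as_tibble(object)
  if (has_combined) {
    df <- dplyr::filter(df, !is.na(.data$p_combined))
    df$estimate <- df$estimate_combined
    df$p <- df$p_combined
    df$flag <- df$significant_adjusted
    flag_lab <- "BH-adjusted p < alpha"
  } else {
    df$estimate <- df$estimate_discovery
    df$p <- df$p_discovery
    df$flag <- df$replicated
    flag_lab <- "replicated"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = -log10(.data$p),
                                   color = .data$flag)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = "estimate (BP-code units per intensity unit)",
                  y = expression(-log[10] ~ p), color = flag_lab) +
    ggplot2::theme_minimal()
}

#' ROC curve display
#'
#' @param object A `bp_roc` tibble from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bp_roc
#' @export
autoplot.bp_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Ablation importance display
#'
#' Mean accuracy delta (baseline minus ablated) per feature with +/- 1 SD
#' error bars across seeds.
#'
#' @param object An `importance_report` from [ablation_importance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot importance_report
#' @export
autoplot.importance_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$feature_id <- stats::reorder(df$feature_id, df$mean_delta)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature_id,
                                   y = .data$mean_delta)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_delta - .data$sd_delta,
      ymax = .data$mean_delta + .data$sd_delta), width = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "accuracy drop when ablated") +
    ggplot2::theme_minimal()
}

#' Accuracy trajectory display
#'
#' @param object An `accuracy_curve` from [accuracy_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot accuracy_curve
#' @export
autoplot.accuracy_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$step,
                                       y = .data$mean_accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$sd_accuracy,
      ymax = .data$mean_accuracy + .data$sd_accuracy), alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "metabolites added (combined-p rank order)",
                  y = "held-out accuracy") +
    ggplot2::theme_minimal()
}

#' Stage-wise abundance boxplots
#'
#' Feature abundance by 4-level blood pressure display stage, the standard
#' per-metabolite trend summary.
#'
#' @param data A staged analysis table (see [cohort_table()]).
#' @param features Feature columns to display.
#' @return A ggplot object, faceted by feature.
#' @export
plot_stage_abundance <- function(data, features) {
  missing <- setdiff(c(features, "bp_code4"), names(data))
  if (length(missing)) {
    stop("column(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    data[, c("bp_code4", features)],
    cols = dplyr::all_of(features),
    names_to = "feature_id", values_to = "abundance")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$bp_code4),
                                     y = .data$abundance)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~feature_id, scales = "free_y") +
    ggplot2::labs(x = "blood pressure stage (1-4)", y = "abundance") +
    ggplot2::theme_minimal()
}

#' Cumulative adjusted R-squared display
#'
#' @param trajectory Output of [cumulative_r2()].
#' @return A ggplot object.
#' @export
plot_cumulative_r2 <- function(trajectory) {
  ggplot2::ggplot(trajectory, ggplot2::aes(x = .data$step,
                                           y = .data$adj_r2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "metabolites added (combined-p rank order)",
                  y = expression(adjusted ~ R^2)) +
    ggplot2::theme_minimal()
}
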