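#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an informedness-vs-threshold curve
#'
#' The threshold scan as a curve of J over candidate thresholds, with the
#' optimum marked — the per-algorithm diagnostic for how peaked or flat the
#' informedness landscape is (sharply peaked algorithms are sensitive to the
#' choice of cutoff, flat ones are robust).
#'
#' @param object A `threshold_scan` from [optimize_threshold()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot threshold_scan
#' @export
autoplot.threshold_scan <- function(object, ...) {
  ggplot2::ggplot(object$scan, ggplot2::aes(x = .data$threshold, y = .data$informedness)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::geom_vline(
      xintercept = object$optimal_threshold,
      linetype = "dashed", color = "firebrick"
    ) +
    ggplot2::annotate("point",
      x = object$optimal_threshold, y = object$j_max,
      color = "firebrick"
    ) +
    ggplot2::labs(
      title = object$algorithm,
      subtitle = sprintf(
        "optimal threshold %.4g, J = %.3f",
        object$optimal_threshold, object$j_max
      ),
      x = "threshold score", y = "informedness (J)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a performance report
#'
#' Fraction of variants flagged deleterious per activity bin (sensitivity in
#' the deleterious bins, 1 - specificity in the neutral ones) together with
#' the mean consensus score per bin.
#'
#' @param object A `performance_report` from [evaluate_model()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot performance_report
#' @export
autoplot.performance_report <- function(object, ...) {
  d <- object$by_activity_bin |>
    tidyr::pivot_longer(
      c("fraction_deleterious", "mean_score"),
      names_to = "measure", values_to = "value"
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$value, fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c(fraction_deleterious = "#b2182b", mean_score = "#2166ac"),
      labels = c("fraction flagged deleterious", "mean consensus score")
    ) +
    ggplot2::labs(
      x = "in vitro activity bin", y = NULL, fill = NULL,
      title = "Consensus model vs graded functionality"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot cross-validation results
#'
#' Training and validation sensitivity/specificity per fold.
#'
#' @param object An `adme_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot adme_cv
#' @export
autoplot.adme_cv <- function(object, ...) {
  d <- object$fold_results |>
    dplyr::select(
      "fold", "train_sensitivity", "train_specificity",
      "val_sensitivity", "val_specificity"
    ) |>
    tidyr::pivot_longer(-"fold", names_to = "measure", values_to = "value") |>
    tidyr::separate("measure", into = c("split", "metric"), sep = "_")
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$fold), y = .data$value,
    fill = .data$metric, alpha = .data$split
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_alpha_manual(values = c(train = 1, val = 0.55)) +
    ggplot2::labs(
      x = "fold", y = NULL, fill = NULL, alpha = NULL,
      title = "Cross-validated consensus model performance"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
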