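#' Consensus score of a variant
#'
#' Each model component votes 1 (deleterious) or 0 (neutral) by its strict
#' threshold call; the consensus score is the mean vote over the components
#' with an available score, so it lies in \[0, 1\]: 1 means all available
#' algorithms flag the variant deleterious, 0 that all call it neutral, 0.5
#' that the panel is split. The score is missing only when every component
#' score is missing.
#'
#' @param data Variant tibble with the component score columns.
#' @param model A [consensus_model()].
#' @return Numeric vector of consensus scores (`NA` where no component has a
#'   score).
#' @export
consensus_score <- function(data, model) {
  stopifnot(inherits(model, "consensus_model"))
  calls <- call_matrix(data, model$components)
  score <- rowMeans(calls, na.rm = TRUE)
  score[rowSums(!is.na(calls)) == 0] <- NA_real_
  score
}

#' Dichotomize a consensus score
#'
#' Deleterious when the score reaches the cutoff (ties at exactly the cutoff
#' are flagged deleterious — for screening, the conservative side); missing
#' scores propagate.
#'
#' @param score Numeric vector of consensus scores in \[0, 1\].
#' @param cutoff Call cutoff in (0, 1).
#' @return Factor with levels `deleterious`, `neutral`.
#' @examples
#' consensus_call(c(0.8, 0.2, 0.5, NA))
#' @export
consensus_call <- function(score, cutoff = 0.5) {
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    stop("consensus scores must lie in [0, 1]", call. = FALSE)
  }
  factor(ifelse(score >= cutoff, "deleterious", "neutral"),
    levels = c("deleterious", "neutral")
  )
}

#' Score variants with a consensus model
#'
#' @param object A [consensus_model()].
#' @param newdata Variant tibble with the component score columns.
#' @param ... Unused.
#' @return A tibble: `variant_id`, one 0/1/NA call column per component
#'   (named by algorithm), `n_components` (available votes),
#'   `consensus_score`, `consensus_call`.
#' @export
predict.consensus_model <- function(object, newdata, ...) {
  calls <- call_matrix(newdata, object$components)
  score <- rowMeans(calls, na.rm = TRUE)
  score[rowSums(!is.na(calls)) == 0] <- NA_real_
  out <- tibble::as_tibble(calls)
  out <- dplyr::bind_cols(
    tibble::tibble(variant_id = newdata$variant_id),
    out,
    tibble::tibble(
      n_components = rowSums(!is.na(calls)),
      consensus_score = score,
      consensus_call = consensus_call(score, object$cutoff)
    )
  )
  out
}

#' Fraction of variants without a prediction
#'
#' Per algorithm, the fraction of variants whose score is missing (so no
#' call can be made); for the consensus model, the fraction of variants with
#' no available component at all — typically far smaller, since the other
#' components cover each algorithm's gaps.
#'
#' @param data Variant tibble.
#' @param model A [consensus_model()]; its components define the model row.
#' @param registry Registry restricting which score columns are reported;
#'   default: all registry columns present in `data`.
#' @return Tibble with `algorithm` (the model row is named
#'   `"consensus model"`) and `fraction_unpredicted`.
#' @export
prediction_coverage <- function(data, model = NULL,
                                registry = algorithm_registry()) {
  algs <- dataset_algorithms(data, registry)
  out <- tibble::tibble(
    algorithm = algs,
    fraction_unpredicted = vapply(
      algs, function(a) mean(is.na(data[[a]])), 0,
      USE.NAMES = FALSE
    )
  )
  if (!is.null(model)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      algorithm = "consensus model",
      fraction_unpredicted = mean(is.na(consensus_score(data, model)))
    ))
  }
  out
}

#' Evaluate a consensus model on labelled variants
#'
#' Produces the full evaluation surface for a model on a labelled dataset:
#'
#' * overall confusion counts and derived metrics (including informedness);
#' * per activity bin: n, fraction flagged deleterious, mean consensus score
#'   with its standard error (sample sd / sqrt(n));
#' * metrics restricted to the extreme bins (loss-of-function vs neutral),
#'   where a dichotomous call is best defined;
#' * metrics per minor-allele-frequency bin (variants without MAF omitted
#'   from this stratification only);
#' * prediction coverage per component and for the model;
#' * an ordinary least-squares fit of the per-bin mean consensus score
#'   against the bin-midpoint activity (midpoints 0.05, 0.30, 0.70, 0.95) —
#'   a 4-point summary of how quantitatively the score tracks measured
#'   functionality.
#'
#' @param data Variant tibble with `label`, `activity` and the component
#'   score columns (optionally `maf`).
#' @param model A [consensus_model()]; default the published five-component
#'   model.
#' @return A `performance_report` object with elements `overall`,
#'   `by_activity_bin`, `lof_neutral`, `by_maf_bin`, `coverage`,
#'   `score_activity_fit`, `n`, `predictions`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
evaluate_model <- function(data, model = published_model()) {
  stopifnot(nrow(data) > 0, "label" %in% names(data))
  pred <- predict(model, data)
  joined <- dplyr::bind_cols(
    data[, c("variant_id", "activity", "label")],
    pred[, c("consensus_score", "consensus_call")]
  )
  if ("maf" %in% names(data)) joined$maf <- data$maf else joined$maf <- NA_real_
  joined$bin <- activity_bin(joined$activity)

  overall <- classification_metrics(
    confusion_counts(joined$label, joined$consensus_call)
  )

  by_bin <- joined |>
    dplyr::group_by(bin = .data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      fraction_deleterious = mean(.data$consensus_call == "deleterious", na.rm = TRUE),
      mean_score = mean(.data$consensus_score, na.rm = TRUE),
      sem_score = stats::sd(.data$consensus_score, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$consensus_score))),
      .groups = "drop"
    ) |>
    tidyr::complete(bin = factor(levels(joined$bin), levels = levels(joined$bin)),
      fill = list(n = 0L)
    )

  extreme <- joined[joined$bin %in% c("lof", "neutral_bin"), ]
  lof_neutral <- classification_metrics(
    confusion_counts(extreme$label, extreme$consensus_call)
  )

  by_maf <- joined |>
    dplyr::filter(!is.na(.data$maf)) |>
    dplyr::mutate(maf_bin = maf_bin(.data$maf)) |>
    dplyr::group_by(.data$maf_bin) |>
    dplyr::group_modify(function(g, key) {
      classification_metrics(confusion_counts(g$label, g$consensus_call)) |>
        dplyr::mutate(n = nrow(g), .before = 1)
    }) |>
    dplyr::ungroup()

  mid <- activity_bin_midpoints()
  fit_data <- dplyr::filter(by_bin, .data$n > 0, !is.na(.data$mean_score))
  fit_data$midpoint <- mid[as.character(fit_data$bin)]
  if (nrow(fit_data) >= 3) {
    fit <- stats::lm(mean_score ~ midpoint, data = fit_data)
    sm <- summary(fit)
    score_activity_fit <- tibble::tibble(
      slope = stats::coef(fit)[["midpoint"]],
      intercept = stats::coef(fit)[["(Intercept)"]],
      r_squared = sm$r.squared,
      p_value = sm$coefficients["midpoint", "Pr(>|t|)"],
      n_bins = nrow(fit_data)
    )
  } else {
    score_activity_fit <- tibble::tibble(
      slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
      p_value = NA_real_, n_bins = nrow(fit_data)
    )
  }

  structure(
    list(
      overall = overall,
      by_activity_bin = by_bin,
      lof_neutral = lof_neutral,
      by_maf_bin = by_maf,
      coverage = prediction_coverage(
        data,
        model = model,
        registry = tibble::tibble(algorithm = model$components$algorithm)
      ),
      score_activity_fit = score_activity_fit,
      n = nrow(joined),
      predictions = joined
    ),
    class = "performance_report"
  )
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report> ", x$n, " variants\n", sep = "")
  cat(
    "  overall: sens ", format(x$overall$sensitivity, digits = 3),
    ", spec ", format(x$overall$specificity, digits = 3),
    ", accuracy ", format(x$overall$accuracy, digits = 3),
    ", J ", format(x$overall$informedness, digits = 3), "\n",
    sep = ""
  )
  cat(
    "  LOF vs neutral: sens ", format(x$lof_neutral$sensitivity, digits = 3),
    ", spec ", format(x$lof_neutral$specificity, digits = 3),
    ", J ", format(x$lof_neutral$informedness, digits = 3), "\n",
    sep = ""
  )
  cat(
    "  score vs activity: R^2 ",
    format(x$score_activity_fit$r_squared, digits = 3), " over ",
    x$score_activity_fit$n_bins, " bins\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn evaluate_model the per-activity-bin summary table.
#' @param x A `performance_report`.
#' @param ... Unused.
#' @method tidy performance_report
#' @export
tidy.performance_report <- function(x, ...) {
  x$by_activity_bin
}

#' @describeIn evaluate_model one-row summary: overall and extreme-bin
#'   metrics, coverage, and the score-vs-activity fit.
#' @method glance performance_report
#' @export
glance.performance_report <- function(x, ...) {
  model_cov <- x$coverage$fraction_unpredicted[
    x$coverage$algorithm == "consensus model"
  ]
  tibble::tibble(
    n = x$n,
    sensitivity = x$overall$sensitivity,
    specificity = x$overall$specificity,
    accuracy = x$overall$accuracy,
    informedness = x$overall$informedness,
    lof_neutral_sensitivity = x$lof_neutral$sensitivity,
    lof_neutral_specificity = x$lof_neutral$specificity,
    lof_neutral_informedness = x$lof_neutral$informedness,
    model_fraction_unpredicted = model_cov,
    score_activity_r_squared = x$score_activity_fit$r_squared
  )
}

#' Serialize a performance report
#'
#' Writes the report as JSON (overall, per-bin and per-MAF tables, coverage,
#' score-activity fit) for downstream consumption.
#'
#' @param report A `performance_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_performance_report <- function(report, path) {
  stopifnot(inherits(report, "performance_report"))
  jsonlite::write_json(
    list(
      n = report$n,
      overall = report$overall,
      by_activity_bin = report$by_activity_bin,
      lof_neutral = report$lof_neutral,
      by_maf_bin = report$by_maf_bin,
      coverage = report$coverage,
      score_activity_fit = report$score_activity_fit
    ),
    path,
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
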