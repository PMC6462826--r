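#' Candidate classification thresholds for a score
#'
#' Two policies are supported. `"midpoints"` places one candidate between
#' every pair of consecutive distinct observed scores, plus one candidate
#' below the minimum and one above the maximum (offset by half the smallest
#' gap); this enumerates every achievable operating point exactly, so the
#' scan optimum is the true optimum over all real thresholds. `"fixed_grid"`
#' reproduces an arithmetic sweep between the lowest and highest observed
#' scores with the given `step` (the literature convention of scanning in
#' small fixed increments); it is never better than the midpoint policy and
#' is provided for fidelity and for plotting on a regular grid.
#'
#' @param scores Numeric vector with at least two distinct finite values
#'   (`NA` ignored).
#' @param policy `"midpoints"` (default) or `"fixed_grid"`.
#' @param step Grid increment, required for `"fixed_grid"`.
#' @return Strictly increasing numeric vector of candidate thresholds.
#' @examples
#' candidate_thresholds(c(1, 2, 4))
#' candidate_thresholds(c(0, 1), policy = "fixed_grid", step = 0.5)
#' @export
candidate_thresholds <- function(scores, policy = c("midpoints", "fixed_grid"),
                                 step = NULL) {
  policy <- match.arg(policy)
  s <- sort(unique(scores[is.finite(scores)]))
  if (length(s) < 2) {
    stop("need at least two distinct finite scores to place thresholds",
      call. = FALSE
    )
  }
  if (policy == "midpoints") {
    half_gap <- min(diff(s)) / 2
    c(s[1] - half_gap, (utils::head(s, -1) + utils::tail(s, -1)) / 2, s[length(s)] + half_gap)
  } else {
    if (is.null(step) || !is.finite(step) || step <= 0) {
      stop("fixed_grid policy needs a positive step", call. = FALSE)
    }
    seq(s[1], s[length(s)], by = step)
  }
}

# sensitivity/specificity/J at every threshold in `thr` (strict calls)
scan_counts <- function(score, label_del, direction, thr) {
  n_pos <- sum(label_del)
  n_neg <- sum(!label_del)
  del_call <- if (direction == "greater") {
    function(t) score > t
  } else {
    function(t) score < t
  }
  tp <- vapply(thr, function(t) sum(del_call(t) & label_del), 0)
  fp <- vapply(thr, function(t) sum(del_call(t) & !label_del), 0)
  tibble::tibble(
    threshold = thr,
    sensitivity = tp / n_pos,
    specificity = (n_neg - fp) / n_neg,
    informedness = tp / n_pos + (n_neg - fp) / n_neg - 1
  )
}

#' Optimize a classification threshold by maximizing informedness
#'
#' Scans candidate thresholds for one algorithm's score column and returns
#' the threshold maximizing the Youden index
#' J = sensitivity + specificity - 1, evaluated with the algorithm's
#' deleteriousness direction and strict-inequality calls. Variants missing
#' this algorithm's score are excluded from the scan (per-algorithm
#' complete-case).
#'
#' Tie-breaking when several candidates attain the maximal J: the candidate
#' with the highest sensitivity wins; remaining ties go to the numerically
#' smallest threshold for `"greater"` directions and largest for `"less"`
#' (widening the deleterious-flagged region — the conservative choice for
#' screening).
#'
#' @param data Variant tibble with `label` and a score column named
#'   `algorithm`, e.g. from [read_variant_scores()] or [simulate_variants()].
#' @param algorithm Name of the score column / registry entry to optimize.
#' @param registry Algorithm registry supplying the direction.
#' @inheritParams candidate_thresholds
#' @return A `threshold_scan` object: list with `algorithm`, `direction`,
#'   `scan` (tibble of `threshold`, `sensitivity`, `specificity`,
#'   `informedness`), `optimal_threshold`, `j_max`, `sensitivity_at_opt`,
#'   `specificity_at_opt`, `n_used`, `policy`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' d <- tibble::tibble(
#'   label = c("neutral", "neutral", "deleterious", "deleterious"),
#'   CADD = c(1, 2, 3, 4)
#' )
#' glance(optimize_threshold(d, "CADD"))
#' @export
optimize_threshold <- function(data, algorithm, registry = algorithm_registry(),
                               policy = c("midpoints", "fixed_grid"),
                               step = NULL) {
  policy <- match.arg(policy)
  registry <- validate_registry(registry)
  if (!algorithm %in% registry$algorithm) {
    stop("algorithm '", algorithm, "' is not in the registry", call. = FALSE)
  }
  if (!algorithm %in% names(data)) {
    stop("no score column '", algorithm, "' in the data", call. = FALSE)
  }
  direction <- registry$direction[registry$algorithm == algorithm]
  keep <- !is.na(data[[algorithm]]) & !is.na(data$label)
  score <- data[[algorithm]][keep]
  label_del <- as.character(data$label[keep]) == "deleterious"
  if (length(score) == 0) {
    stop("all scores missing for '", algorithm, "'", call. = FALSE)
  }
  if (sum(label_del) == 0 || sum(!label_del) == 0) {
    stop("both classes must be present among variants scored by '",
      algorithm, "'",
      call. = FALSE
    )
  }
  thr <- candidate_thresholds(score, policy = policy, step = step)
  scan <- scan_counts(score, label_del, direction, thr)

  j_max <- max(scan$informedness)
  best <- which(scan$informedness == j_max)
  if (length(best) > 1) {
    best <- best[scan$sensitivity[best] == max(scan$sensitivity[best])]
  }
  if (length(best) > 1) {
    best <- if (direction == "greater") min(best) else max(best)
  }

  structure(
    list(
      algorithm = algorithm,
      direction = direction,
      scan = scan,
      optimal_threshold = scan$threshold[best],
      j_max = j_max,
      sensitivity_at_opt = scan$sensitivity[best],
      specificity_at_opt = scan$specificity[best],
      n_used = length(score),
      policy = policy
    ),
    class = "threshold_scan"
  )
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(
    "<threshold_scan> ", x$algorithm,
    " (deleterious if ", if (x$direction == "greater") ">" else "<", " threshold)\n",
    "  optimal threshold: ", format(x$optimal_threshold, digits = 4),
    "   J = ", format(x$j_max, digits = 3),
    "  (sens ", format(x$sensitivity_at_opt, digits = 3),
    ", spec ", format(x$specificity_at_opt, digits = 3), ")\n",
    "  ", nrow(x$scan), " candidates (", x$policy, "), ",
    x$n_used, " variants used\n",
    sep = ""
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn optimize_threshold the full informedness-vs-threshold curve,
#'   one row per candidate.
#' @param x A `threshold_scan`.
#' @param ... Unused.
#' @method tidy threshold_scan
#' @export
tidy.threshold_scan <- function(x, ...) {
  dplyr::mutate(x$scan, algorithm = x$algorithm, .before = 1)
}

#' @describeIn optimize_threshold one-row summary of the optimum.
#' @method glance threshold_scan
#' @export
glance.threshold_scan <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    direction = x$direction,
    optimal_threshold = x$optimal_threshold,
    j_max = x$j_max,
    sensitivity = x$sensitivity_at_opt,
    specificity = x$specificity_at_opt,
    n_used = x$n_used
  )
}

#' Optimize thresholds for several algorithms at once
#'
#' Applies [optimize_threshold()] to every requested score column and binds
#' the one-row summaries, keeping the full scans in a list-column.
#'
#' @inheritParams optimize_threshold
#' @param algorithms Character vector of algorithms; default: every registry
#'   algorithm with a score column in `data`.
#' @return A tibble with one row per algorithm: the [glance()] columns plus a
#'   list-column `scan` of `threshold_scan` objects.
#' @export
optimize_thresholds <- function(data, algorithms = NULL,
                                registry = algorithm_registry(),
                                policy = c("midpoints", "fixed_grid"),
                                step = NULL) {
  policy <- match.arg(policy)
  if (is.null(algorithms)) algorithms <- dataset_algorithms(data, registry)
  scans <- purrr::map(
    algorithms,
    ~ optimize_threshold(data, .x, registry, policy = policy, step = step)
  )
  out <- purrr::map_dfr(scans, glance)
  out$scan <- scans
  out
}

#' Informedness gained over the conventional threshold
#'
#' Compares the optimized threshold's informedness with the informedness the
#' conventional literature threshold achieves on the same variants:
#' delta = J(optimized) - J(conventional). Algorithms without a conventional
#' threshold (PhyloP, PhastCons) have no reference point; their row carries
#' `NA` for the conventional and delta values.
#'
#' @param data Variant tibble (the same data the scan was fitted on).
#' @param scan A `threshold_scan` from [optimize_threshold()].
#' @param registry Algorithm registry supplying the conventional threshold.
#' @return One-row tibble: `algorithm`, `conventional_threshold`,
#'   `conventional_j`, `optimized_threshold`, `optimized_j`, `delta`.
#' @export
delta_informedness <- function(data, scan, registry = algorithm_registry()) {
  registry <- validate_registry(registry)
  stopifnot(inherits(scan, "threshold_scan"))
  row <- registry[registry$algorithm == scan$algorithm, ]
  if (nrow(row) != 1) {
    stop("algorithm '", scan$algorithm, "' is not in the registry", call. = FALSE)
  }
  conv <- row$conventional_threshold
  if (is.na(conv)) {
    conv_j <- NA_real_
  } else {
    keep <- !is.na(data[[scan$algorithm]]) & !is.na(data$label)
    conv_j <- scan_counts(
      data[[scan$algorithm]][keep],
      as.character(data$label[keep]) == "deleterious",
      scan$direction, conv
    )$informedness
  }
  tibble::tibble(
    algorithm = scan$algorithm,
    conventional_threshold = conv,
    conventional_j = conv_j,
    optimized_threshold = scan$optimal_threshold,
    optimized_j = scan$j_max,
    delta = scan$j_max - conv_j
  )
}

#' Cross-fold stability of optimal thresholds
#'
#' Summarizes how much an algorithm's optimal threshold moves between
#' cross-validation folds as the absolute coefficient of variation
#' |CV| = |sd / mean| of the fold optima (see [cv_abs()]). Small values mean
#' the optimization is robust to which variants are in the training set.
#'
#' @param fold_thresholds A data frame with columns `algorithm` and
#'   `optimal_threshold`, one row per (algorithm, fold) — e.g. bound
#'   [glance()] rows of per-fold scans, or the `fold_thresholds` element of a
#'   [cross_validate()] result.
#' @return A tibble with `algorithm`, `n_folds`, `mean_threshold`,
#'   `cv_abs`.
#' @export
threshold_stability <- function(fold_thresholds) {
  stopifnot(all(c("algorithm", "optimal_threshold") %in% names(fold_thresholds)))
  fold_thresholds |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(
      n_folds = dplyr::n(),
      mean_threshold = mean(.data$optimal_threshold),
      cv_abs = cv_abs(.data$optimal_threshold),
      .groups = "drop"
    )
}
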