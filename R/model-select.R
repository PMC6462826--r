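#' Label-stratified k-fold assignment
#'
#' Randomly partitions variants into `k` folds while preserving the
#' deleterious/neutral proportions: within each label class the shuffled
#' variants are dealt round-robin, so per-class fold sizes differ by at most
#' one and every fold's class mix matches the global mix to within one
#' variant. Deterministic given `seed`; the global RNG state is left
#' untouched.
#'
#' @param data Variant tibble with `variant_id` and `label`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A tibble with `variant_id`, `label`, `fold` (integer in `1:k`).
#' @export
stratified_folds <- function(data, k = 5, seed = 1) {
  stopifnot(k >= 2)
  class_sizes <- table(factor(data$label, levels = c("deleterious", "neutral")))
  if (any(class_sizes < k)) {
    stop("every label class needs at least k = ", k, " variants", call. = FALSE)
  }
  withr::with_seed(seed, {
    assignment <- data |>
      dplyr::select("variant_id", "label") |>
      dplyr::group_by(.data$label) |>
      dplyr::group_modify(function(g, key) {
        g$fold <- rep_len(seq_len(k), nrow(g))[order(sample.int(nrow(g)))]
        g
      }) |>
      dplyr::ungroup()
  })
  # restore original row order
  assignment[match(data$variant_id, assignment$variant_id), c("variant_id", "label", "fold")]
}

#' Per-algorithm deleteriousness calls and correctness
#'
#' Classifies every variant with every component algorithm using
#' strict-inequality threshold calls in the component's direction, and marks
#' each call's agreement with the experimental label (the 0/1 correctness
#' score of the combination search). Missing scores give missing calls,
#' which are excluded from all correctness sums downstream.
#'
#' @param data Variant tibble with `label` and the component score columns.
#' @param components A data frame with columns `algorithm`, `threshold`,
#'   `direction` — e.g. the components of a [consensus_model()], or
#'   [optimize_thresholds()] output renamed.
#' @return A long tibble: `variant_id`, `algorithm`, `score`, `call`
#'   (`deleterious` / `neutral` / `NA`), `correct` (1, 0 or `NA`).
#' @export
component_calls <- function(data, components) {
  components <- as_components(components)
  missing_cols <- setdiff(components$algorithm, names(data))
  if (length(missing_cols) > 0) {
    stop("no score column for component(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  purrr::pmap_dfr(components, function(algorithm, threshold, direction) {
    score <- data[[algorithm]]
    del <- if (direction == "greater") score > threshold else score < threshold
    call <- ifelse(del, "deleterious", "neutral")
    tibble::tibble(
      variant_id = data$variant_id,
      algorithm = algorithm,
      score = score,
      call = call,
      correct = as.integer(call == as.character(data$label))
    )
  })
}

# n x m matrix of component calls: 1 deleterious, 0 neutral, NA missing
call_matrix <- function(data, components) {
  m <- sapply(seq_len(nrow(components)), function(j) {
    score <- data[[components$algorithm[j]]]
    if (components$direction[j] == "greater") {
      as.numeric(score > components$threshold[j])
    } else {
      as.numeric(score < components$threshold[j])
    }
  })
  m <- matrix(m, nrow = nrow(data), dimnames = list(NULL, components$algorithm))
  m
}

as_components <- function(components) {
  if (inherits(components, "consensus_model")) {
    return(components$components)
  }
  components <- tibble::as_tibble(components)
  if ("optimal_threshold" %in% names(components) && !"threshold" %in% names(components)) {
    components <- dplyr::rename(components, threshold = "optimal_threshold")
  }
  stopifnot(all(c("algorithm", "threshold", "direction") %in% names(components)))
  components[, c("algorithm", "threshold", "direction")]
}

#' Exhaustive search for the best algorithm combination
#'
#' Enumerates every non-empty subset of the candidate component algorithms
#' (2^m - 1 subsets, feasible up to the full 18-method panel via
#' incremental Gray-code updates of the per-variant call sums) and scores
#' each subset on the training labels. Objectives:
#'
#' * `consensus_informedness` (default): the Youden index of the subset's
#'   consensus call (see [consensus_score()]); variants whose consensus score
#'   is missing are excluded from the counts.
#' * `consensus_accuracy`: overall accuracy of the consensus call.
#' * `mean_component_correctness`: the summed 0/1 component correctness
#'   normalized by the number of available (algorithm, variant) calls —
#'   the per-call average agreement with the experimental labels. The
#'   unnormalized sum is monotone in subset size and would always select the
#'   full panel, so only normalized objectives are offered.
#'
#' Ties are broken toward the smaller subset, then lexicographically by
#' sorted algorithm names.
#'
#' @param data Variant tibble with `label` and the component score columns.
#' @param components Candidate components (`algorithm`, `threshold`,
#'   `direction`); the search is over subsets of these.
#' @param objective Objective to maximize.
#' @param max_size Optional cap on subset size (`l <= k` style constraint);
#'   `NULL` searches all sizes.
#' @param cutoff Consensus call cutoff, see [consensus_call()].
#' @return A `combination_result`: list with `subset` (character vector,
#'   sorted), `objective_name`, `objective_value`, `n_subsets` evaluated,
#'   and `components` (the winning rows).
#' @export
select_combination <- function(data, components,
                               objective = c(
                                 "consensus_informedness",
                                 "consensus_accuracy",
                                 "mean_component_correctness"
                               ),
                               max_size = NULL, cutoff = 0.5) {
  objective <- match.arg(objective)
  components <- as_components(components)
  m <- nrow(components)
  stopifnot(m >= 1, m <= 25)
  calls <- call_matrix(data, components)
  label_del <- as.character(data$label) == "deleterious"
  if (all(label_del) || !any(label_del)) {
    stop("both classes must be present to select a combination", call. = FALSE)
  }
  if (all(is.na(calls))) {
    stop("no valid component call on any variant", call. = FALSE)
  }

  del <- ifelse(is.na(calls), 0, calls) # 1 where called deleterious
  avail <- 1 - is.na(calls) # 1 where a call exists
  corr <- calls == label_del # per-call correctness
  corr_sum <- colSums(corr, na.rm = TRUE)
  avail_sum <- colSums(avail)

  n <- nrow(calls)
  sum_del <- numeric(n)
  sum_avail <- numeric(n)
  member <- logical(m)
  s_corr <- 0
  s_avail <- 0

  best_value <- -Inf
  best_size <- Inf
  best_key <- ""
  best_subset <- NULL
  n_eval <- 0L

  g_prev <- 0L
  for (i in seq_len(2^m - 1)) {
    g <- bitwXor(i, i %/% 2L)
    j <- as.integer(log2(bitwXor(g, g_prev))) + 1L
    g_prev <- g
    if (member[j]) {
      sum_del <- sum_del - del[, j]
      sum_avail <- sum_avail - avail[, j]
      s_corr <- s_corr - corr_sum[j]
      s_avail <- s_avail - avail_sum[j]
      member[j] <- FALSE
    } else {
      sum_del <- sum_del + del[, j]
      sum_avail <- sum_avail + avail[, j]
      s_corr <- s_corr + corr_sum[j]
      s_avail <- s_avail + avail_sum[j]
      member[j] <- TRUE
    }
    size <- sum(member)
    if (!is.null(max_size) && size > max_size) next
    n_eval <- n_eval + 1L

    if (objective == "mean_component_correctness") {
      value <- if (s_avail > 0) s_corr / s_avail else -Inf
    } else {
      valid <- sum_avail > 0
      # consensus call deleterious iff score >= cutoff  <=>  sum_del >= cutoff * sum_avail
      call_del <- valid & (sum_del >= cutoff * sum_avail)
      if (objective == "consensus_informedness") {
        np <- sum(label_del & valid)
        nn <- sum(!label_del & valid)
        if (np == 0 || nn == 0) next
        value <- sum(call_del & label_del) / np +
          sum(!call_del & !label_del & valid) / nn - 1
      } else {
        nv <- sum(valid)
        if (nv == 0) next
        value <- (sum(call_del & label_del) +
          sum(!call_del & !label_del & valid)) / nv
      }
    }

    if (value > best_value ||
      (value == best_value && size < best_size) ||
      (value == best_value && size == best_size &&
        paste(sort(components$algorithm[member]), collapse = "\r") < best_key)) {
      best_value <- value
      best_size <- size
      best_subset <- components$algorithm[member]
      best_key <- paste(sort(best_subset), collapse = "\r")
    }
  }

  if (is.null(best_subset)) {
    stop("no subset produced a defined objective value", call. = FALSE)
  }
  subset <- sort(best_subset)
  structure(
    list(
      subset = subset,
      objective_name = objective,
      objective_value = unname(best_value),
      n_subsets = n_eval,
      n_candidates = m,
      components = components[match(subset, components$algorithm), ]
    ),
    class = "combination_result"
  )
}

#' @export
print.combination_result <- function(x, ...) {
  cat(
    "<combination_result> ", length(x$subset), " of ", x$n_candidates,
    " algorithms\n  ",
    paste(x$subset, collapse = " + "), "\n  ",
    x$objective_name, " = ", format(x$objective_value, digits = 4),
    "  (", x$n_subsets, " subsets evaluated)\n",
    sep = ""
  )
  invisible(x)
}

#' Consensus deleteriousness model
#'
#' Bundles an ordered set of (algorithm, threshold, direction) components
#' with a consensus call cutoff. Each component votes deleterious (1) or
#' neutral (0) by a strict threshold call; the consensus score is the mean
#' vote over components with an available score, and the variant is called
#' deleterious when that score reaches `cutoff` (ties at exactly the cutoff
#' are flagged deleterious — conservative for screening).
#'
#' @param components Data frame with `algorithm`, `threshold`, `direction`.
#' @param cutoff Consensus call cutoff in (0, 1), default 0.5.
#' @param provenance Optional named list recording how the model was fitted
#'   (seed, k, objective, ...).
#' @return A `consensus_model` object; supports [generics::tidy()] (the
#'   component table) and [predict()] (per-variant scores and calls).
#' @seealso [published_model()], [cross_validate()], [evaluate_model()]
#' @export
consensus_model <- function(components, cutoff = 0.5, provenance = list()) {
  components <- as_components(components)
  if (nrow(components) == 0) stop("a model needs at least one component", call. = FALSE)
  if (anyDuplicated(components$algorithm)) {
    stop("component algorithm names must be unique", call. = FALSE)
  }
  if (!all(is.finite(components$threshold))) {
    stop("component thresholds must be finite", call. = FALSE)
  }
  if (!all(components$direction %in% c("less", "greater"))) {
    stop("component direction must be 'less' or 'greater'", call. = FALSE)
  }
  if (!(cutoff > 0 && cutoff < 1)) stop("cutoff must be in (0, 1)", call. = FALSE)
  structure(
    list(components = components, cutoff = cutoff, provenance = provenance),
    class = "consensus_model"
  )
}

#' @export
print.consensus_model <- function(x, ...) {
  cat("<consensus_model> ", nrow(x$components), " components, call cutoff ",
    x$cutoff, "\n",
    sep = ""
  )
  sign <- ifelse(x$components$direction == "greater", ">", "<")
  cat(paste0(
    "  ", format(x$components$algorithm), "  deleterious if ", sign, " ",
    format(x$components$threshold, digits = 4)
  ), sep = "\n")
  if (length(x$provenance) > 0) {
    cat(
      "  provenance:",
      paste(names(x$provenance), unlist(x$provenance), sep = "=", collapse = ", "),
      "\n"
    )
  }
  invisible(x)
}

#' @describeIn consensus_model component table as a tibble.
#' @param x A `consensus_model`.
#' @param ... Unused.
#' @method tidy consensus_model
#' @export
tidy.consensus_model <- function(x, ...) {
  dplyr::mutate(x$components, cutoff = x$cutoff)
}

#' The fixed published five-component ADME model
#'
#' The consensus model selected on the pharmacogenetic training data:
#' LRT, MutationAssessor, PROVEAN, VEST3 and CADD at their ADME-optimized
#' thresholds, with the default 0.5 consensus call cutoff. Use it to score
#' new ADME variants without refitting.
#'
#' @return A [consensus_model()].
#' @examples
#' published_model()
#' @export
published_model <- function() {
  reg <- algorithm_registry()
  comp <- reg[
    match(
      c("LRT", "MutationAssessor", "PROVEAN", "VEST3", "CADD"),
      reg$algorithm
    ),
    c("algorithm", "optimized_threshold", "direction")
  ]
  names(comp)[2] <- "threshold"
  consensus_model(comp, cutoff = 0.5, provenance = list(source = "published"))
}

#' Read or write a consensus model as YAML
#'
#' @param model A [consensus_model()].
#' @param path Path to a YAML file.
#' @return `read_consensus_model()` returns a `consensus_model`;
#'   `write_consensus_model()` returns `path` invisibly.
#' @export
write_consensus_model <- function(model, path) {
  stopifnot(inherits(model, "consensus_model"))
  yaml::write_yaml(
    list(
      cutoff = model$cutoff,
      provenance = model$provenance,
      components = purrr::pmap(
        model$components,
        function(algorithm, threshold, direction) {
          list(algorithm = algorithm, threshold = threshold, direction = direction)
        }
      )
    ),
    path
  )
  invisible(path)
}

#' @rdname write_consensus_model
#' @export
read_consensus_model <- function(path) {
  spec <- yaml::read_yaml(path)
  comp <- purrr::map_dfr(spec$components, tibble::as_tibble)
  consensus_model(comp,
    cutoff = spec$cutoff %||% 0.5,
    provenance = spec$provenance %||% list()
  )
}

#' Stratified cross-validated model fitting
#'
#' The full training procedure: variants are partitioned into `k`
#' label-stratified folds; within each training split every algorithm's
#' threshold is re-optimized by informedness ([optimize_threshold()]) and the
#' best algorithm combination is found by exhaustive search
#' ([select_combination()]); the fold model is then evaluated on its held-out
#' validation fold. The final aggregated model uses the modal selected
#' subset across folds (ties toward smaller subsets, then lexicographic) with
#' each component's threshold averaged over the fold optima.
#'
#' @inheritParams select_combination
#' @inheritParams optimize_thresholds
#' @param k Number of folds.
#' @param seed Integer seed driving the fold assignment.
#' @return An `adme_cv` object: list with
#'   * `model` — the aggregated [consensus_model()];
#'   * `folds` — the fold assignment tibble;
#'   * `fold_results` — per-fold tibble: selected subset (list-column),
#'     objective value, train/validation sensitivity, specificity and J;
#'   * `fold_thresholds` — per (fold, algorithm) optimal thresholds and J;
#'   * `fold_delta` — per (fold, algorithm) informedness gain over the
#'     conventional threshold;
#'   * `stability` — per-algorithm |CV| of fold thresholds;
#'   * `k`, `seed`, `objective`, `policy`, `cutoff`.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
cross_validate <- function(data, registry = algorithm_registry(), k = 5,
                           seed = 1,
                           objective = c(
                             "consensus_informedness",
                             "consensus_accuracy",
                             "mean_component_correctness"
                           ),
                           algorithms = NULL,
                           policy = c("midpoints", "fixed_grid"), step = NULL,
                           max_size = NULL, cutoff = 0.5) {
  objective <- match.arg(objective)
  policy <- match.arg(policy)
  registry <- validate_registry(registry)
  if (is.null(algorithms)) algorithms <- dataset_algorithms(data, registry)
  folds <- stratified_folds(data, k = k, seed = seed)
  data <- dplyr::left_join(data, folds[, c("variant_id", "fold")], by = "variant_id")

  fold_rows <- list()
  thr_rows <- list()
  delta_rows <- list()
  for (f in seq_len(k)) {
    train <- data[data$fold != f, , drop = FALSE]
    val <- data[data$fold == f, , drop = FALSE]
    scans <- optimize_thresholds(train, algorithms, registry,
      policy = policy, step = step
    )
    thr_rows[[f]] <- dplyr::mutate(
      dplyr::select(scans, -"scan"),
      fold = f, .before = 1
    )
    delta_rows[[f]] <- purrr::map_dfr(
      scans$scan,
      ~ delta_informedness(train, .x, registry)
    ) |> dplyr::mutate(fold = f, .before = 1)

    comps <- tibble::tibble(
      algorithm = scans$algorithm,
      threshold = scans$optimal_threshold,
      direction = scans$direction
    )
    sel <- select_combination(train, comps,
      objective = objective,
      max_size = max_size, cutoff = cutoff
    )
    fold_model <- consensus_model(sel$components, cutoff = cutoff)
    train_metrics <- model_confusion(train, fold_model)
    val_metrics <- model_confusion(val, fold_model)
    fold_rows[[f]] <- tibble::tibble(
      fold = f,
      subset = list(sel$subset),
      subset_size = length(sel$subset),
      objective_value = sel$objective_value,
      n_train = nrow(train), n_val = nrow(val),
      train_sensitivity = sensitivity(train_metrics),
      train_specificity = specificity(train_metrics),
      train_informedness = informedness(train_metrics),
      val_sensitivity = sensitivity(val_metrics),
      val_specificity = specificity(val_metrics),
      val_informedness = informedness(val_metrics)
    )
  }
  fold_results <- dplyr::bind_rows(fold_rows)
  fold_thresholds <- dplyr::bind_rows(thr_rows)
  fold_delta <- dplyr::bind_rows(delta_rows)

  # modal subset across folds; ties toward smaller, then lexicographic
  keys <- vapply(fold_results$subset, function(s) paste(sort(s), collapse = "\r"), "")
  tab <- table(keys)
  winners <- names(tab)[tab == max(tab)]
  sizes <- vapply(strsplit(winners, "\r", fixed = TRUE), length, 0L)
  winners <- winners[sizes == min(sizes)]
  modal <- sort(strsplit(min(winners), "\r", fixed = TRUE)[[1]])

  agg_thresholds <- fold_thresholds |>
    dplyr::filter(.data$algorithm %in% modal) |>
    dplyr::group_by(.data$algorithm, .data$direction) |>
    dplyr::summarise(threshold = mean(.data$optimal_threshold), .groups = "drop")
  model <- consensus_model(
    agg_thresholds[, c("algorithm", "threshold", "direction")],
    cutoff = cutoff,
    provenance = list(
      fitted_by = "cross_validate", k = k, seed = seed,
      objective = objective, policy = policy
    )
  )

  structure(
    list(
      model = model,
      folds = folds,
      fold_results = fold_results,
      fold_thresholds = fold_thresholds,
      fold_delta = fold_delta,
      stability = threshold_stability(fold_thresholds),
      k = k, seed = seed, objective = objective, policy = policy,
      cutoff = cutoff
    ),
    class = "adme_cv"
  )
}

# confusion of a consensus model's calls on a variant tibble
model_confusion <- function(data, model) {
  pred <- predict(model, data)
  confusion_counts(data$label, pred$consensus_call)
}

#' @export
print.adme_cv <- function(x, ...) {
  g <- glance(x)
  cat("<adme_cv> ", x$k, "-fold stratified cross-validation (seed ", x$seed,
    ", objective ", x$objective, ")\n",
    sep = ""
  )
  cat(
    "  training:   sensitivity ", format(g$train_sensitivity_mean, digits = 3),
    " ± ", format(g$train_sensitivity_sd, digits = 2),
    ", specificity ", format(g$train_specificity_mean, digits = 3),
    " ± ", format(g$train_specificity_sd, digits = 2), "\n",
    sep = ""
  )
  cat(
    "  validation: sensitivity ", format(g$val_sensitivity_mean, digits = 3),
    " ± ", format(g$val_sensitivity_sd, digits = 2),
    ", specificity ", format(g$val_specificity_mean, digits = 3),
    " ± ", format(g$val_specificity_sd, digits = 2), "\n",
    sep = ""
  )
  cat(
    "  aggregated model:",
    paste(x$model$components$algorithm, collapse = " + "), "\n"
  )
  invisible(x)
}

#' @describeIn cross_validate per-fold results, subsets comma-collapsed.
#' @param x An `adme_cv` object.
#' @param ... Unused.
#' @method tidy adme_cv
#' @export
tidy.adme_cv <- function(x, ...) {
  out <- x$fold_results
  out$subset <- vapply(out$subset, paste, "", collapse = ",")
  out
}

#' @describeIn cross_validate one-row mean/SD summary across folds.
#' @method glance adme_cv
#' @export
glance.adme_cv <- function(x, ...) {
  fr <- x$fold_results
  tibble::tibble(
    k = x$k, seed = x$seed, objective = x$objective,
    model_size = nrow(x$model$components),
    train_sensitivity_mean = mean(fr$train_sensitivity),
    train_sensitivity_sd = stats::sd(fr$train_sensitivity),
    train_specificity_mean = mean(fr$train_specificity),
    train_specificity_sd = stats::sd(fr$train_specificity),
    val_sensitivity_mean = mean(fr$val_sensitivity),
    val_sensitivity_sd = stats::sd(fr$val_sensitivity),
    val_specificity_mean = mean(fr$val_specificity),
    val_specificity_sd = stats::sd(fr$val_specificity)
  )
}
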