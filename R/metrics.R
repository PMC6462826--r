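#' Confusion counts for deleterious / neutral calls
#'
#' True positives and false negatives are deleterious variants called
#' deleterious or neutral respectively; true negatives and false positives
#' are neutral variants called neutral or deleterious. Missing calls (`NA`)
#' are excluded from all four counts — a variant only enters the confusion
#' matrix when it has both a label and a non-missing call.
#'
#' @param label Factor or character vector of experimental labels
#'   (`deleterious` / `neutral`).
#' @param call Factor or character vector of predicted calls
#'   (`deleterious` / `neutral` / `NA`).
#' @return A one-row tibble with integer columns `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_counts(
#'   c("deleterious", "deleterious", "neutral", "neutral"),
#'   c("deleterious", "neutral", "neutral", "deleterious")
#' )
#' @export
confusion_counts <- function(label, call) {
  if (length(label) != length(call)) {
    stop("label and call must have equal length", call. = FALSE)
  }
  label <- as.character(label)
  call <- as.character(call)
  keep <- !is.na(call) & !is.na(label)
  label <- label[keep]
  call <- call[keep]
  tibble::tibble(
    tp = sum(label == "deleterious" & call == "deleterious"),
    fp = sum(label == "neutral" & call == "deleterious"),
    tn = sum(label == "neutral" & call == "neutral"),
    fn = sum(label == "deleterious" & call == "neutral")
  )
}

#' Classification metrics from confusion counts
#'
#' Exact ratios: sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
#' PPV = TP / (TP + FP), NPV = TN / (TN + FN), accuracy =
#' (TP + TN) / (TP + TN + FP + FN), and informedness (Youden index)
#' J = sensitivity + specificity - 1, interpretable as the probability that a
#' classification is informed rather than chance.
#'
#' A metric whose denominator is zero is undefined and returned as `NA_real_`
#' — an explicit signal, deliberately distinct from the value 0; callers
#' decide how to handle it.
#'
#' @param counts A one-row data frame (or list) with `tp`, `fp`, `tn`, `fn`,
#'   as produced by [confusion_counts()].
#' @return A numeric scalar (or `NA_real_` when undefined).
#' @examples
#' cc <- tibble::tibble(tp = 101, fn = 8, tn = 66, fp = 5)
#' sensitivity(cc) # 101/109
#' informedness(cc)
#' @name classification-metrics
NULL

ratio_or_na <- function(num, den) {
  if (den == 0) NA_real_ else num / den
}

#' @rdname classification-metrics
#' @export
sensitivity <- function(counts) ratio_or_na(counts$tp, counts$tp + counts$fn)

#' @rdname classification-metrics
#' @export
specificity <- function(counts) ratio_or_na(counts$tn, counts$tn + counts$fp)

#' @rdname classification-metrics
#' @export
ppv <- function(counts) ratio_or_na(counts$tp, counts$tp + counts$fp)

#' @rdname classification-metrics
#' @export
npv <- function(counts) ratio_or_na(counts$tn, counts$tn + counts$fn)

#' @rdname classification-metrics
#' @export
accuracy <- function(counts) {
  ratio_or_na(counts$tp + counts$tn, counts$tp + counts$tn + counts$fp + counts$fn)
}

#' @rdname classification-metrics
#' @export
informedness <- function(counts) {
  se <- sensitivity(counts)
  sp <- specificity(counts)
  if (is.na(se) || is.na(sp)) NA_real_ else se + sp - 1
}

#' All classification metrics as one row
#'
#' @inheritParams classification-metrics
#' @return A one-row tibble with the four counts and `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`, `informedness` (`NA` where
#'   undefined).
#' @export
classification_metrics <- function(counts) {
  tibble::tibble(
    tp = counts$tp, fp = counts$fp, tn = counts$tn, fn = counts$fn,
    sensitivity = sensitivity(counts),
    specificity = specificity(counts),
    ppv = ppv(counts),
    npv = npv(counts),
    accuracy = accuracy(counts),
    informedness = informedness(counts)
  )
}

#' ROC operating points for one score
#'
#' Sweeps a strict threshold over the observed scores, oriented so that "more
#' deleterious" values sort first: for `direction = "greater"` a variant is
#' called deleterious when its score is strictly above the threshold, for
#' `"less"` strictly below. The curve has one operating point per distinct
#' observed score plus the (0, 0) and (1, 1) endpoints; variants with missing
#' scores are dropped.
#'
#' @param score Numeric score vector (may contain `NA`).
#' @param label Labels (`deleterious` / `neutral`), same length.
#' @param direction `"greater"` or `"less"`: side on which the score flags
#'   deleteriousness.
#' @return A tibble with columns `threshold` (in original score units;
#'   `Inf`/`-Inf` at the endpoints), `fpr`, `tpr`, each non-decreasing from
#'   (0, 0) to (1, 1).
#' @examples
#' roc_points(c(1, 2, 3, 4), c("neutral", "neutral", "deleterious", "deleterious"),
#'   direction = "greater"
#' )
#' @export
roc_points <- function(score, label, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  label <- as.character(label)
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]
  label <- label[keep]
  n_pos <- sum(label == "deleterious")
  n_neg <- sum(label == "neutral")
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_points needs at least one deleterious and one neutral variant",
      call. = FALSE
    )
  }
  oriented <- if (direction == "greater") score else -score
  # one strict-call operating point per distinct oriented score, descending;
  # the point at the maximum is (0,0), the appended endpoint (1,1).
  # cumulative counts over the sorted scores give each point in O(n log n):
  # at threshold v (strict >) the calls are exactly the scores sorted before
  # the first occurrence of v
  ord <- order(oriented, decreasing = TRUE)
  o <- oriented[ord]
  ld <- label[ord] == "deleterious"
  first_occ <- which(!duplicated(o))
  thr <- o[first_occ]
  tpr <- c(0, cumsum(ld))[first_occ] / n_pos
  fpr <- c(0, cumsum(!ld))[first_occ] / n_neg
  thr_orig <- if (direction == "greater") thr else -thr
  tibble::tibble(
    threshold = c(thr_orig, if (direction == "greater") -Inf else Inf),
    fpr = c(fpr, 1),
    tpr = c(tpr, 1)
  )
}

#' Area under the ROC curve
#'
#' Trapezoidal area under a [roc_points()] curve. Equals the rank-sum
#' (Mann-Whitney) statistic: the probability that a randomly chosen
#' deleterious variant out-scores a randomly chosen neutral one in the
#' deleterious direction, ties counted half.
#'
#' @param roc A tibble from [roc_points()], or `NULL` if `score`/`label` are
#'   given directly.
#' @param score,label,direction Alternative input, forwarded to
#'   [roc_points()].
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(score = c(1, 2, 3, 4), label = c("neutral", "neutral", "deleterious", "deleterious"))
#' @export
roc_auc <- function(roc = NULL, score = NULL, label = NULL,
                    direction = "greater") {
  if (is.null(roc)) {
    roc <- roc_points(score, label, direction)
  }
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Absolute coefficient of variation
#'
#' |CV| = |sample standard deviation / mean|, the dispersion measure used to
#' summarize the stability of fold-optimal thresholds across cross-validation
#' folds. Uses the n - 1 (sample) standard deviation, appropriate for the
#' small number of folds. Undefined (`NA_real_`) when the mean is zero.
#'
#' @param values Numeric vector, length >= 2.
#' @return Non-negative scalar, or `NA_real_` if the mean is 0.
#' @examples
#' cv_abs(c(1.0, 1.1, 0.9, 1.0, 1.0))
#' @export
cv_abs <- function(values) {
  if (length(values) < 2) {
    stop("cv_abs needs at least two values", call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) {
    return(NA_real_)
  }
  abs(stats::sd(values) / m)
}
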