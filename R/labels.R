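#' Dichotomize in vitro activity into deleterious / neutral
#'
#' A variant is labelled deleterious when its in vitro activity (intrinsic
#' clearance as a fraction of wild type) is reduced more than 2-fold, i.e.
#' strictly below `cutoff` (default 0.5). The label is derived only from
#' activity, never from predictor scores. Activities above 1 are valid
#' (gain-of-function in vitro) and map to neutral.
#'
#' @param activity Numeric vector of activities, as fractions of wild-type
#'   intrinsic clearance; must be non-negative. `NA` propagates.
#' @param cutoff Activity below which a variant counts as deleterious.
#' @return A factor with levels `deleterious`, `neutral`.
#' @examples
#' label_from_activity(c(0.49, 0.5, 1.0))
#' @export
label_from_activity <- function(activity, cutoff = 0.5) {
  if (any(activity < 0, na.rm = TRUE)) {
    stop("activity must be non-negative (fraction of wild-type clearance)",
      call. = FALSE
    )
  }
  factor(ifelse(activity < cutoff, "deleterious", "neutral"),
    levels = c("deleterious", "neutral")
  )
}

#' Bin activity into graded functionality classes
#'
#' Bins follow the strict `<10%` / `>90%` wording used for loss-of-function
#' and neutral variants: `lof` = \[0, 0.10), `decreased` = \[0.10, 0.50),
#' `moderate` = \[0.50, 0.90\], `neutral_bin` = (0.90, Inf). The bins
#' partition the non-negative activity axis; 0.50 falls in `moderate` because
#' deleterious means strictly more than a 2-fold reduction.
#'
#' @inheritParams label_from_activity
#' @return A factor with levels `lof`, `decreased`, `moderate`, `neutral_bin`.
#' @examples
#' activity_bin(c(0.05, 0.10, 0.5, 0.9, 0.95))
#' @export
activity_bin <- function(activity) {
  if (any(activity < 0, na.rm = TRUE)) {
    stop("activity must be non-negative", call. = FALSE)
  }
  out <- dplyr::case_when(
    activity < 0.10 ~ "lof",
    activity < 0.50 ~ "decreased",
    activity <= 0.90 ~ "moderate",
    activity > 0.90 ~ "neutral_bin"
  )
  factor(out, levels = c("lof", "decreased", "moderate", "neutral_bin"))
}

#' Midpoints of the activity bins
#'
#' Representative activities used as the x-axis when regressing the mean
#' consensus score on functionality (see [evaluate_model()]).
#'
#' @return Named numeric vector of length 4.
#' @export
activity_bin_midpoints <- function() {
  c(lof = 0.05, decreased = 0.30, moderate = 0.70, neutral_bin = 0.95)
}

#' Bin minor allele frequencies
#'
#' `very_rare` for MAF < 0.1%, `rare` for 0.1% <= MAF < 1%, `common` for
#' MAF >= 1%. Missing MAF returns `NA` (such variants are simply omitted from
#' MAF-stratified reports).
#'
#' @param maf Numeric vector of minor allele frequencies in \[0, 1\].
#' @return A factor with levels `very_rare`, `rare`, `common`.
#' @examples
#' maf_bin(c(0.0005, 0.005, 0.05, NA))
#' @export
maf_bin <- function(maf) {
  if (any(maf < 0 | maf > 1, na.rm = TRUE)) {
    stop("maf must lie in [0, 1]", call. = FALSE)
  }
  out <- dplyr::case_when(
    maf < 0.001 ~ "very_rare",
    maf < 0.01 ~ "rare",
    maf >= 0.01 ~ "common"
  )
  factor(out, levels = c("very_rare", "rare", "common"))
}
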