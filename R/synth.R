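#' Default synthetic algorithm panel
#'
#' Mirrors the 18-method registry: directions and nominal score ranges come
#' from [algorithm_registry()]; each method gets a target AUC matching its
#' reported discriminative power on pharmacogenetic data (from a CADD-like
#' 0.81 down to a FATHMM-like 0.51) and a missingness rate patterned on the
#' observed coverage gaps (5% for SIFT, FATHMM and PROVEAN; 0 for the
#' genome-wide scores that cover every SNV; 2% for the rest).
#'
#' @return A tibble with `algorithm`, `direction`, `range_low`, `range_high`,
#'   `target_auc`, `missing_rate`, suitable for [simulate_variants()].
#' @export
synthetic_algorithms <- function() {
  reg <- algorithm_registry()
  auc <- c(
    "SIFT" = 0.74, "PolyPhen-2" = 0.77, "LRT" = 0.75,
    "MutationAssessor" = 0.78, "FATHMM" = 0.51, "FATHMM-MKL" = 0.73,
    "PROVEAN" = 0.76, "VEST3" = 0.80, "GERP++" = 0.67, "SiPhy" = 0.63,
    "PhyloP (vertebrate)" = 0.64, "PhyloP (mammalian)" = 0.64,
    "PhastCons (vertebrate)" = 0.58, "PhastCons (mammalian)" = 0.61,
    "CADD" = 0.81, "DANN" = 0.75, "MetaSVM" = 0.68, "MetaLR" = 0.68
  )
  miss <- c(
    "SIFT" = 0.05, "FATHMM" = 0.05, "PROVEAN" = 0.05,
    "PolyPhen-2" = 0.02, "FATHMM-MKL" = 0.02, "VEST3" = 0.02,
    "MetaSVM" = 0.02, "MetaLR" = 0.02
  )
  tibble::tibble(
    algorithm = reg$algorithm,
    direction = reg$direction,
    range_low = reg$range_low,
    range_high = reg$range_high,
    target_auc = unname(auc[reg$algorithm]),
    missing_rate = unname(ifelse(is.na(miss[reg$algorithm]), 0, miss[reg$algorithm]))
  )
}

#' Binormal separation for a target AUC
#'
#' Under the equal-variance binormal model (neutral scores ~ N(0, 1),
#' deleterious ~ N(d, 1)), AUC = Phi(d / sqrt(2)); inverting gives
#' d = sqrt(2) * qnorm(AUC).
#'
#' @param auc Target AUC in (0.5, 1).
#' @return Class separation `d` in standard-deviation units.
#' @export
auc_to_separation <- function(auc) {
  stopifnot(all(auc > 0.5 & auc < 1))
  sqrt(2) * stats::qnorm(auc)
}

#' Maximal informedness of an equal-variance binormal score
#'
#' For classes separated by `d` standard deviations the Youden-optimal
#' threshold sits at `d / 2` and the maximal informedness is
#' 2 * Phi(d / 2) - 1 — the closed-form oracle that parameter-recovery tests
#' check the threshold scan against.
#'
#' @param d Non-negative separation in standard-deviation units.
#' @return Maximal informedness in \[0, 1).
#' @examples
#' expected_max_informedness(2) # about 0.683
#' @export
expected_max_informedness <- function(d) {
  stopifnot(all(d >= 0))
  2 * stats::pnorm(d / 2) - 1
}

#' Simulate an annotated ADME variant table with known truth
#'
#' Generates a dataset with the structure of a real annotated score table —
#' graded activity bins, per-algorithm scores with algorithm-specific scale,
#' orientation, discriminative power and missingness, and a log-uniform
#' minor-allele-frequency distribution — from an equal-variance binormal
#' generative model whose optimal thresholds and maximal informedness have
#' closed forms, so every downstream stage can be validated against analytic
#' ground truth.
#'
#' Per variant: an activity bin is drawn from `bin_weights`, the activity
#' uniformly within the bin's interval (the neutral bin extends to 1.2,
#' admitting mild gain-of-function), and the label follows
#' [label_from_activity()]. Per algorithm `a` with target AUC `A_a`, the raw
#' score is `d_a * is_deleterious + sqrt(rho) * z + sqrt(1 - rho) * e`, with
#' `d_a = sqrt(2) * qnorm(A_a)`, a shared standard-normal latent factor `z`
#' (predictors share conservation-derived features, so their errors
#' correlate) and independent noise `e`. Raw scores are mapped affinely onto
#' the algorithm's nominal range, negated first for algorithms whose low
#' scores mean deleterious; missingness is Bernoulli per algorithm.
#'
#' @param n_variants Number of variants (default 337, the size of a
#'   realistic curated pharmacogenetic dataset).
#' @param bin_weights Probabilities of the four activity bins (lof,
#'   decreased, moderate, neutral_bin); must sum to 1. The default matches
#'   the composition of curated ADME activity data (about a third severe
#'   loss-of-function, a fifth fully neutral).
#' @param algorithms Panel tibble as from [synthetic_algorithms()].
#' @param latent_correlation Shared-factor variance fraction rho in \[0, 1).
#' @param maf_log10_range Range of log10 MAF for the log-uniform draw.
#' @param seed Integer seed; the generator is fully reproducible and leaves
#'   the global RNG untouched.
#' @return A list with
#'   * `data`: variant tibble (`variant_id`, `gene`, `activity`, `maf`,
#'     `label`, one score column per algorithm) compatible with every
#'     fitting/evaluation function;
#'   * `truth`: per-algorithm tibble with `target_auc`, separation `d`,
#'     `raw_threshold` (d/2), `mapped_threshold` (same point in score units),
#'     `expected_j_max`;
#'   * `config`: the generating parameters.
#' @examples
#' sim <- simulate_variants(n_variants = 100, seed = 7)
#' dplyr::count(sim$data, label)
#' @export
simulate_variants <- function(n_variants = 337,
                              bin_weights = c(
                                lof = 0.32, decreased = 0.28,
                                moderate = 0.19, neutral_bin = 0.21
                              ),
                              algorithms = synthetic_algorithms(),
                              latent_correlation = 0.3,
                              maf_log10_range = c(-4, -0.7),
                              seed = 1) {
  stopifnot(n_variants >= 1)
  if (abs(sum(bin_weights) - 1) > 1e-9) {
    stop("bin_weights must sum to 1", call. = FALSE)
  }
  if (length(bin_weights) != 4) stop("bin_weights must have 4 entries", call. = FALSE)
  if (is.null(names(bin_weights))) {
    names(bin_weights) <- c("lof", "decreased", "moderate", "neutral_bin")
  }
  if (!(latent_correlation >= 0 && latent_correlation < 1)) {
    stop("latent_correlation must lie in [0, 1)", call. = FALSE)
  }
  if (!all(algorithms$target_auc > 0.5 & algorithms$target_auc < 1)) {
    stop("target_auc must lie in (0.5, 1)", call. = FALSE)
  }
  if (!all(algorithms$missing_rate >= 0 & algorithms$missing_rate < 1)) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }

  bin_lo <- c(lof = 0, decreased = 0.1, moderate = 0.5, neutral_bin = 0.9)
  bin_hi <- c(lof = 0.1, decreased = 0.5, moderate = 0.9, neutral_bin = 1.2)
  genes <- c(
    "CYP2D6", "CYP2C9", "CYP2C19", "CYP2B6", "CYP3A4", "CYP2A6",
    "CYP1A2", "NAT1", "NAT2", "TPMT", "DPYD", "UGT1A1", "SLCO1B1",
    "ABCB1", "ABCG2", "NUDT15", "CYP2C8", "CYP2E1"
  )

  rho <- latent_correlation
  withr::with_seed(seed, {
    bins <- sample(names(bin_weights), n_variants, replace = TRUE, prob = bin_weights)
    activity <- stats::runif(n_variants, bin_lo[bins], bin_hi[bins])
    label <- label_from_activity(activity)
    del <- label == "deleterious"
    z <- stats::rnorm(n_variants)

    data <- tibble::tibble(
      variant_id = sprintf("var%05d", seq_len(n_variants)),
      gene = sample(genes, n_variants, replace = TRUE),
      activity = activity,
      maf = 10^stats::runif(n_variants, maf_log10_range[1], maf_log10_range[2]),
      label = label
    )

    truth <- algorithms
    truth$d <- auc_to_separation(truth$target_auc)
    truth$raw_threshold <- truth$d / 2
    truth$expected_j_max <- expected_max_informedness(truth$d)
    truth$mapped_threshold <- NA_real_

    for (i in seq_len(nrow(algorithms))) {
      a <- algorithms[i, ]
      d <- truth$d[i]
      raw <- d * del + sqrt(rho) * z +
        sqrt(1 - rho) * stats::rnorm(n_variants)
      oriented <- if (a$direction == "greater") raw else -raw
      # fixed raw support so the affine map (and hence the mapped truth)
      # does not depend on the realized sample
      support <- if (a$direction == "greater") c(-4, d + 4) else c(-(d + 4), 4)
      rescale <- function(x) {
        a$range_low + (x - support[1]) / diff(support) *
          (a$range_high - a$range_low)
      }
      score <- rescale(oriented)
      opt_raw <- if (a$direction == "greater") d / 2 else -d / 2
      truth$mapped_threshold[i] <- rescale(opt_raw)
      if (a$missing_rate > 0) {
        score[stats::runif(n_variants) < a$missing_rate] <- NA_real_
      }
      data[[a$algorithm]] <- score
    }
  })

  list(
    data = data,
    truth = truth[, c(
      "algorithm", "direction", "target_auc", "missing_rate", "d",
      "raw_threshold", "mapped_threshold", "expected_j_max"
    )],
    config = list(
      n_variants = n_variants, bin_weights = bin_weights,
      latent_correlation = latent_correlation,
      maf_log10_range = maf_log10_range, seed = seed
    )
  )
}

#' Write simulation ground truth as YAML
#'
#' @param sim A list from [simulate_variants()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_simulation_truth <- function(sim, path) {
  yaml::write_yaml(
    list(
      config = sim$config,
      truth = purrr::transpose(as.list(sim$truth))
    ),
    path
  )
  invisible(path)
}
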