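#' Built-in registry of prediction algorithms
#'
#' Returns the panel of 18 in silico deleteriousness predictors the framework
#' calibrates: eight functionality prediction algorithms (SIFT, PolyPhen-2,
#' LRT, MutationAssessor, FATHMM, FATHMM-MKL, PROVEAN, VEST3), six
#' evolutionary conservation scores (GERP++, SiPhy, PhyloP and PhastCons each
#' on vertebrate and mammalian alignments) and four ensemble scores (CADD,
#' DANN, MetaSVM, MetaLR). Each entry records the direction in which the
#' score indicates deleteriousness, the conventional literature threshold
#' (absent for PhyloP and PhastCons, for which no standard cutoffs exist),
#' the ADME-optimized threshold derived from pharmacogenetic in vitro data,
#' the nominal score range, and the dbNSFP-style input column name.
#'
#' Calls are always strict inequalities in the stated direction: an algorithm
#' with `direction == "less"` flags a variant as deleterious when its score is
#' strictly below the threshold, `"greater"` when strictly above.
#'
#' Nominal ranges follow the score definitions as distributed through dbNSFP
#' (probabilities on \[0, 1\], PROVEAN on roughly \[-14, 14\], PHRED-scaled
#' CADD on \[0, 99\], and so on); they bound threshold grids, not the data.
#'
#' @return A tibble with one row per algorithm and columns `algorithm`,
#'   `category` (`"functionality"`, `"conservation"` or `"ensemble"`),
#'   `direction` (`"less"` or `"greater"`), `conventional_threshold` (`NA`
#'   where no literature default exists), `optimized_threshold`, `range_low`,
#'   `range_high`, `input_column`.
#' @examples
#' algorithm_registry()
#' @seealso [published_model()] for the fixed five-component consensus model.
#' @export
algorithm_registry <- function() {
  reg <- tibble::tribble(
    ~algorithm,              ~category,       ~direction, ~conventional_threshold, ~optimized_threshold, ~range_low, ~range_high, ~input_column,
    "SIFT",                  "functionality", "less",     0.05,                    0.0376,               0,          1,           "SIFT_score",
    "PolyPhen-2",            "functionality", "greater",  0.447,                   0.3841,               0,          1,           "Polyphen2_HDIV_score",
    "LRT",                   "functionality", "less",     0.001,                   0.0025,               0,          1,           "LRT_score",
    "MutationAssessor",      "functionality", "greater",  1.9,                     2.0566,               -5.17,      6.49,        "MutationAssessor_score",
    "FATHMM",                "functionality", "less",     -1.5,                    0.4866,               -16.13,     10.64,       "FATHMM_score",
    "FATHMM-MKL",            "functionality", "greater",  0.73,                    0.3982,               0,          1,           "fathmm-MKL_coding_score",
    "PROVEAN",               "functionality", "less",     -2.5,                    -3.286,               -14,        14,          "PROVEAN_score",
    "VEST3",                 "functionality", "greater",  0.9,                     0.4534,               0,          1,           "VEST3_score",
    "GERP++",                "conservation",  "greater",  4.4,                     1.2482,               -12.3,      6.17,        "GERP++_RS",
    "SiPhy",                 "conservation",  "greater",  12.17,                   7.2442,               0,          37.9,        "SiPhy_29way_logOdds",
    "PhyloP (vertebrate)",   "conservation",  "greater",  NA,                      0.5216,               -20,        10.003,      "phyloP100way_vertebrate",
    "PhyloP (mammalian)",    "conservation",  "greater",  NA,                      0.0461,               -13.282,    1.199,       "phyloP20way_mammalian",
    "PhastCons (vertebrate)", "conservation", "greater",  NA,                      0.07,                 0,          1,           "phastCons100way_vertebrate",
    "PhastCons (mammalian)", "conservation",  "greater",  NA,                      0.1872,               0,          1,           "phastCons20way_mammalian",
    "CADD",                  "ensemble",      "greater",  15,                      19.19,                0,          99,          "CADD_phred",
    "DANN",                  "ensemble",      "greater",  0.99,                    0.9688,               0,          1,           "DANN_score",
    "MetaSVM",               "ensemble",      "greater",  0,                       -0.3371,              -2,         3,           "MetaSVM_score",
    "MetaLR",                "ensemble",      "greater",  0.5,                     0.4039,               0,          1,           "MetaLR_score"
  )
  validate_registry(reg)
}

#' Validate an algorithm registry
#'
#' Checks the structural invariants every registry must satisfy: unique
#' algorithm names, directions in `{less, greater}`, a well-ordered nominal
#' range, and all stored thresholds inside that range.
#'
#' @param registry A data frame shaped like [algorithm_registry()].
#' @return The registry, invisibly coerced to a tibble, if valid; otherwise an
#'   error.
#' @export
validate_registry <- function(registry) {
  required <- c(
    "algorithm", "category", "direction", "conventional_threshold",
    "optimized_threshold", "range_low", "range_high", "input_column"
  )
  missing_cols <- setdiff(required, names(registry))
  if (length(missing_cols) > 0) {
    stop("registry is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  registry <- tibble::as_tibble(registry)
  if (anyDuplicated(registry$algorithm)) {
    stop("registry algorithm names must be unique", call. = FALSE)
  }
  if (!all(registry$direction %in% c("less", "greater"))) {
    stop("registry direction must be 'less' or 'greater'", call. = FALSE)
  }
  if (!all(registry$range_low < registry$range_high)) {
    stop("registry nominal range must satisfy range_low < range_high", call. = FALSE)
  }
  in_range <- function(x) {
    is.na(x) | (x >= registry$range_low & x <= registry$range_high)
  }
  if (!all(in_range(registry$conventional_threshold)) ||
    !all(in_range(registry$optimized_threshold))) {
    stop("registry thresholds must lie within the nominal range", call. = FALSE)
  }
  registry
}

#' Read or write a registry as YAML
#'
#' Registries are serialized as a YAML list of per-algorithm records so that
#' alternative panels (different thresholds, extra predictors) can be shared
#' between runs.
#'
#' @param path Path to a YAML file.
#' @return `read_algorithm_registry()` returns a registry tibble;
#'   `write_algorithm_registry()` returns `path` invisibly.
#' @export
read_algorithm_registry <- function(path) {
  entries <- yaml::read_yaml(path)
  reg <- purrr::map_dfr(entries, function(e) {
    tibble::tibble(
      algorithm = e$algorithm,
      category = e$category,
      direction = e$direction,
      conventional_threshold = if (is.null(e$conventional_threshold)) NA_real_ else as.numeric(e$conventional_threshold),
      optimized_threshold = if (is.null(e$optimized_threshold)) NA_real_ else as.numeric(e$optimized_threshold),
      range_low = as.numeric(e$range_low),
      range_high = as.numeric(e$range_high),
      input_column = e$input_column
    )
  })
  validate_registry(reg)
}

#' @rdname read_algorithm_registry
#' @param registry A registry tibble, see [algorithm_registry()].
#' @export
write_algorithm_registry <- function(registry, path) {
  registry <- validate_registry(registry)
  entries <- purrr::pmap(registry, function(algorithm, category, direction,
                                            conventional_threshold,
                                            optimized_threshold,
                                            range_low, range_high,
                                            input_column) {
    e <- list(
      algorithm = algorithm, category = category, direction = direction,
      range_low = range_low, range_high = range_high,
      input_column = input_column
    )
    if (!is.na(conventional_threshold)) e$conventional_threshold <- conventional_threshold
    if (!is.na(optimized_threshold)) e$optimized_threshold <- optimized_threshold
    e
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
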