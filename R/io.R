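#' Read an annotated variant score table
#'
#' Loads a tab-separated table with one row per single-nucleotide variant:
#' required columns `variant_id` and `activity` (in vitro activity as a
#' fraction of wild-type intrinsic clearance), optional metadata columns
#' (`gene`, `rsid`, `build`, `chrom`, `pos`, `ref`, `alt`, `aa_change`,
#' `maf`, `label_override`) and one column of scores per registry algorithm.
#' This is the dialect produced by ANNOVAR/dbNSFP annotation; score columns
#' may carry either the registry's algorithm names or annotation-tool header
#' names (resolved through `column_map` or the registry's `input_column`).
#'
#' Missing scores are encoded by the sentinels in `na` (`"."` and the empty
#' string by default, the ANNOVAR convention). Variants for which no score
#' could be retrieved by any algorithm are excluded at load and counted in
#' the load report (`attr(x, "load_report")`). A `label_override` column
#' (values `deleterious` / `neutral`, empty for no override) replaces the
#' activity-derived label for individual variants — used e.g. for named
#' common variants curated as neutral despite borderline assay values.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param registry Algorithm registry tibble; defaults to the built-in panel.
#' @param column_map Optional named character vector or YAML file path mapping
#'   algorithm names to input column names, e.g. `c(SIFT = "SIFT_score")`.
#'   Takes precedence over both the algorithm name and the registry's
#'   `input_column`.
#' @param na Character vector of missing-value sentinels for score cells.
#' @param activity_cutoff Activity below which a variant is labelled
#'   deleterious (see [label_from_activity()]).
#' @return A tibble with one row per retained variant: metadata columns,
#'   `activity`, `maf` (NA where absent), `label` (factor), and one numeric
#'   column per registry algorithm found in the file, named by algorithm.
#'   Attribute `load_report` is a list with `n_excluded` and `excluded_ids`.
#' @seealso [write_variant_scores()], [simulate_variants()]
#' @export
read_variant_scores <- function(path, registry = algorithm_registry(),
                                column_map = NULL, na = c(".", ""),
                                activity_cutoff = 0.5) {
  registry <- validate_registry(registry)
  if (is.character(column_map) && length(column_map) == 1 && file.exists(column_map)) {
    column_map <- read_column_map(column_map)
  }
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, comment = "#"
  )
  for (col in c("variant_id", "activity")) {
    if (!col %in% names(raw)) {
      stop("required column '", col, "' is missing from ", path, call. = FALSE)
    }
  }
  if (anyDuplicated(raw$variant_id)) {
    dups <- unique(raw$variant_id[duplicated(raw$variant_id)])
    stop("duplicate variant_id value(s): ", paste(dups, collapse = ", "),
      call. = FALSE
    )
  }

  # resolve which file column carries each algorithm's scores
  score_cols <- resolve_score_columns(names(raw), registry, column_map)
  if (length(score_cols) == 0) {
    stop("no score column matches any registry algorithm", call. = FALSE)
  }

  parse_num <- function(x, col) {
    x[x %in% na] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      stop(
        "cannot parse '", x[bad[1]], "' as a number in column '", col,
        "', row ", bad[1],
        call. = FALSE
      )
    }
    out
  }

  out <- tibble::tibble(variant_id = raw$variant_id)
  for (col in c("gene", "rsid", "build", "chrom", "ref", "alt", "aa_change")) {
    if (col %in% names(raw)) out[[col]] <- dplyr::na_if(raw[[col]], "")
  }
  if ("pos" %in% names(raw)) out$pos <- parse_num(raw$pos, "pos")
  out$activity <- parse_num(raw$activity, "activity")
  if (anyNA(out$activity)) {
    stop("column 'activity' has missing values; every variant needs an activity",
      call. = FALSE
    )
  }
  out$maf <- if ("maf" %in% names(raw)) parse_num(raw$maf, "maf") else NA_real_
  if (any(out$maf < 0 | out$maf > 1, na.rm = TRUE)) {
    stop("maf values must lie in [0, 1]", call. = FALSE)
  }

  out$label <- label_from_activity(out$activity, cutoff = activity_cutoff)
  if ("label_override" %in% names(raw)) {
    ov <- dplyr::na_if(raw$label_override, "")
    bad <- setdiff(stats::na.omit(unique(ov)), c("deleterious", "neutral"))
    if (length(bad) > 0) {
      stop("label_override values must be 'deleterious' or 'neutral', got: ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    out$label[!is.na(ov)] <- ov[!is.na(ov)]
  }

  for (alg in names(score_cols)) {
    out[[alg]] <- parse_num(raw[[score_cols[[alg]]]], score_cols[[alg]])
  }

  algs <- names(score_cols)
  all_missing <- rowSums(!is.na(as.matrix(out[algs]))) == 0
  report <- list(
    n_excluded = sum(all_missing),
    excluded_ids = out$variant_id[all_missing]
  )
  if (report$n_excluded > 0) {
    message(
      report$n_excluded,
      " variant(s) excluded: no score from any prediction method"
    )
  }
  out <- out[!all_missing, , drop = FALSE]
  attr(out, "load_report") <- report
  out
}

resolve_score_columns <- function(file_cols, registry, column_map) {
  cols <- character(0)
  for (i in seq_len(nrow(registry))) {
    alg <- registry$algorithm[i]
    candidate <- if (!is.null(column_map) && alg %in% names(column_map)) {
      column_map[[alg]]
    } else if (alg %in% file_cols) {
      alg
    } else if (registry$input_column[i] %in% file_cols) {
      registry$input_column[i]
    } else {
      NA_character_
    }
    if (!is.na(candidate)) {
      if (!candidate %in% file_cols) {
        stop("mapped column '", candidate, "' for algorithm '", alg,
          "' not found in file",
          call. = FALSE
        )
      }
      cols[[alg]] <- candidate
    }
  }
  cols
}

#' Write a variant score table
#'
#' Inverse of [read_variant_scores()]: writes a tab-separated table with `.`
#' for missing cells. The `label` column is not written (it is derived from
#' activity on load).
#'
#' @param data A variant tibble as returned by [read_variant_scores()] or
#'   [simulate_variants()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_scores <- function(data, path) {
  out <- dplyr::select(data, -dplyr::any_of("label"))
  readr::write_tsv(out, path, na = ".")
  invisible(path)
}

#' Read a column-name map from YAML
#'
#' The YAML file holds a flat mapping from registry algorithm names to the
#' score column headers used by the annotation tool, e.g.
#' `SIFT: SIFT_score`.
#'
#' @param path Path to a YAML file.
#' @return A named character vector.
#' @export
read_column_map <- function(path) {
  m <- yaml::read_yaml(path)
  unlist(m)
}

#' Algorithms present in a variant table
#'
#' @param data A variant tibble.
#' @param registry Algorithm registry.
#' @return Character vector of registry algorithms that have a score column
#'   in `data`.
#' @export
dataset_algorithms <- function(data, registry = algorithm_registry()) {
  intersect(registry$algorithm, names(data))
}
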