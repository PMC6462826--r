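make_components <- function(algorithms, thresholds, directions = "greater") {
  tibble::tibble(
    algorithm = algorithms, threshold = thresholds,
    direction = rep_len(directions, length(algorithms))
  )
}

test_that("stratified folds preserve class proportions to within one variant", {
  d <- tibble::tibble(
    variant_id = as.character(1:20),
    label = rep(c("deleterious", "neutral"), each = 10)
  )
  f <- stratified_folds(d, k = 5, seed = 1)
  counts <- table(f$label, f$fold)
  expect_true(all(counts == 2)) # 10 of each class over 5 folds

  # uneven classes: per-fold counts within 1 of n_class / k
  d2 <- tibble::tibble(
    variant_id = as.character(1:180),
    label = rep(c("deleterious", "neutral"), times = c(109, 71))
  )
  f2 <- stratified_folds(d2, k = 5, seed = 3)
  counts2 <- table(f2$label, f2$fold)
  expect_true(all(abs(counts2["deleterious", ] - 109 / 5) <= 1))
  expect_true(all(abs(counts2["neutral", ] - 71 / 5) <= 1))
  # folds partition the dataset
  expect_setequal(f2$variant_id, d2$variant_id)

  # determinism and seed sensitivity
  expect_identical(f2, stratified_folds(d2, k = 5, seed = 3))
  expect_false(identical(f2$fold, stratified_folds(d2, k = 5, seed = 4)$fold))

  expect_error(stratified_folds(d[1:6, ], k = 5), "at least k")
})

test_that("component calls apply strict published-direction thresholds", {
  d <- tibble::tibble(
    variant_id = c("a", "b", "c"),
    label = c("deleterious", "neutral", "deleterious"),
    SIFT = c(0.01, 0.5, NA),
    CADD = c(25, 10, 19.19)
  )
  comp <- tidy(published_model())
  calls <- component_calls(d, comp[comp$algorithm %in% c("CADD"), ])
  # CADD 25 > 19.19 deleterious; 10 neutral; exactly 19.19 is not above (strict)
  expect_equal(calls$call, c("deleterious", "neutral", "neutral"))
  expect_equal(calls$correct, c(1L, 1L, 0L))

  sift <- component_calls(
    d,
    make_components("SIFT", 0.0376, "less")
  )
  expect_equal(sift$call, c("deleterious", "neutral", NA))
  expect_true(is.na(sift$correct[3]))
})

test_that("one perfect algorithm is selected alone", {
  withr::with_seed(2, {
    d <- tibble::tibble(
      variant_id = as.character(1:40),
      label = rep(c("deleterious", "neutral"), each = 20),
      perfect = c(rnorm(20, 10), rnorm(20, -10)),
      noisy1 = rnorm(40),
      noisy2 = rnorm(40)
    )
  })
  comp <- make_components(c("perfect", "noisy1", "noisy2"), c(0, 0, 0))
  sel <- select_combination(d, comp)
  expect_equal(sel$subset, "perfect")
  expect_equal(sel$objective_value, 1)
  expect_equal(sel$n_subsets, 7) # 2^3 - 1 subsets visited
})

test_that("gray-code enumeration equals naive per-subset re-scoring", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- 12
      m <- 4
      d <- tibble::tibble(
        variant_id = as.character(1:n),
        label = sample(c("deleterious", "neutral"), n,
          replace = TRUE, prob = c(0.6, 0.4)
        )
      )
      if (length(unique(d$label)) == 1) d$label[1] <- setdiff(c("deleterious", "neutral"), d$label[1])
      for (j in 1:m) {
        s <- rnorm(n, mean = (d$label == "deleterious") * runif(1, 0, 2))
        s[runif(n) < 0.15] <- NA
        d[[paste0("alg", j)]] <- s
      }
    })
    comp <- make_components(paste0("alg", 1:m), rep(0.5, m))
    for (obj in c("consensus_informedness", "consensus_accuracy", "mean_component_correctness")) {
      sel <- select_combination(d, comp, objective = obj)
      oracle <- oracle_best_subset(d, comp, obj)
      expect_equal(sel$subset, oracle$subset)
      expect_equal(sel$objective_value, oracle$value)
    }
  }
})

test_that("mean component correctness of a singleton equals its accuracy", {
  withr::with_seed(21, {
    d <- tibble::tibble(
      variant_id = as.character(1:30),
      label = sample(c("deleterious", "neutral"), 30, replace = TRUE),
      only = rnorm(30, mean = (label == "deleterious"))
    )
    d$only[c(3, 9)] <- NA
  })
  comp <- make_components("only", 0.4)
  sel <- select_combination(d, comp, objective = "mean_component_correctness")
  calls <- component_calls(d, comp)
  expect_equal(sel$objective_value, mean(calls$correct, na.rm = TRUE))
  # which equals the singleton's accuracy over its non-missing calls
  cc <- confusion_counts(d$label, calls$call)
  expect_equal(sel$objective_value, accuracy(cc))
})

test_that("consensus model construction validates its components", {
  comp <- make_components(c("a", "b"), c(1, 2))
  m <- consensus_model(comp, cutoff = 0.5)
  expect_s3_class(m, "consensus_model")
  expect_equal(tidy(m)$cutoff, c(0.5, 0.5))
  expect_error(consensus_model(comp[0, ]), "at least one")
  expect_error(consensus_model(make_components(c("a", "a"), c(1, 2))), "unique")
  expect_error(consensus_model(make_components("a", Inf)), "finite")
  expect_error(consensus_model(comp, cutoff = 1.2), "cutoff")
})

test_that("the published model carries the five components at their thresholds", {
  pm <- published_model()
  expect_equal(nrow(pm$components), 5)
  comp <- pm$components
  expect_setequal(
    comp$algorithm,
    c("LRT", "MutationAssessor", "PROVEAN", "VEST3", "CADD")
  )
  get <- function(a, col) comp[[col]][comp$algorithm == a]
  expect_equal(get("LRT", "threshold"), 0.0025)
  expect_equal(get("LRT", "direction"), "less")
  expect_equal(get("MutationAssessor", "threshold"), 2.0566)
  expect_equal(get("MutationAssessor", "direction"), "greater")
  expect_equal(get("PROVEAN", "threshold"), -3.286)
  expect_equal(get("PROVEAN", "direction"), "less")
  expect_equal(get("VEST3", "threshold"), 0.4534)
  expect_equal(get("CADD", "threshold"), 19.19)
  expect_equal(pm$cutoff, 0.5)
})

test_that("consensus model YAML round-trips", {
  pm <- published_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_consensus_model(pm, path)
  pm2 <- read_consensus_model(path)
  expect_equal(pm2$components, pm$components)
  expect_equal(pm2$cutoff, pm$cutoff)
})

test_that("cross-validation is reproducible and aggregates fold results", {
  sim <- simulate_variants(
    n_variants = 250, seed = 11,
    algorithms = synthetic_algorithms()[c(3, 4, 7, 8, 15), ]
  )
  cv1 <- cross_validate(sim$data, k = 5, seed = 5)
  cv2 <- cross_validate(sim$data, k = 5, seed = 5)
  expect_identical(tidy(cv1), tidy(cv2))
  expect_identical(cv1$model$components, cv2$model$components)

  expect_equal(nrow(cv1$fold_results), 5)
  # aggregated thresholds are the fold means for the modal subset
  for (a in cv1$model$components$algorithm) {
    expect_equal(
      cv1$model$components$threshold[cv1$model$components$algorithm == a],
      mean(cv1$fold_thresholds$optimal_threshold[cv1$fold_thresholds$algorithm == a])
    )
  }
  # validation metrics are defined and within [0, 1]
  expect_true(all(cv1$fold_results$val_sensitivity >= 0 &
    cv1$fold_results$val_sensitivity <= 1))
  # union of folds is the dataset, folds disjoint
  expect_setequal(cv1$folds$variant_id, sim$data$variant_id)
  expect_equal(anyDuplicated(cv1$folds$variant_id), 0)
})

test_that("strong components are selected over weak ones under cross-validation", {
  panel <- tibble::tibble(
    algorithm = paste0("alg", 1:5),
    direction = "greater",
    range_low = 0, range_high = 1,
    target_auc = c(0.9, 0.85, 0.8, 0.6, 0.55),
    missing_rate = 0
  )
  reg <- tibble::tibble(
    algorithm = panel$algorithm, category = "functionality",
    direction = "greater", conventional_threshold = NA_real_,
    optimized_threshold = NA_real_, range_low = 0, range_high = 1,
    input_column = panel$algorithm
  )
  hits <- purrr::map_int(1:10, function(seed) {
    sim <- simulate_variants(
      n_variants = 400, algorithms = panel,
      latent_correlation = 0, seed = seed
    )
    cv <- cross_validate(sim$data, registry = reg, k = 5, seed = seed)
    sum(c("alg1", "alg2", "alg3") %in% cv$model$components$algorithm)
  })
  expect_gte(sum(hits == 3), 8)
})

test_that("validation performance tracks training performance on well-specified data", {
  gaps <- purrr::map_dfr(1:10, function(seed) {
    sim <- simulate_variants(
      n_variants = 300, seed = seed,
      algorithms = synthetic_algorithms()[c(4, 8, 15), ]
    )
    cv <- cross_validate(sim$data, k = 5, seed = seed)
    g <- glance(cv)
    tibble::tibble(
      sens_gap = abs(g$val_sensitivity_mean - g$train_sensitivity_mean),
      sens_sd = g$val_sensitivity_sd,
      spec_gap = abs(g$val_specificity_mean - g$train_specificity_mean),
      spec_sd = g$val_specificity_sd
    )
  })
  expect_true(all(gaps$sens_gap <= pmax(3 * gaps$sens_sd, 0.05)))
  expect_true(all(gaps$spec_gap <= pmax(3 * gaps$spec_sd, 0.05)))
})
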