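two_column_model <- function() {
  consensus_model(tibble::tibble(
    algorithm = c("s1", "s2"),
    threshold = c(0.5, 0.5),
    direction = "greater"
  ))
}

test_that("consensus score averages available component votes", {
  pm <- published_model()
  d <- tibble::tibble(
    variant_id = c("all_del", "split", "three_of_five", "none"),
    label = "deleterious",
    LRT = c(0.0001, 0.9, 0.0001, NA), # del if < 0.0025
    MutationAssessor = c(5, 5, 5, NA), # del if > 2.0566
    PROVEAN = c(-8, -8, -8, NA), # del if < -3.286
    VEST3 = c(0.9, 0.1, 0.1, NA), # del if > 0.4534
    CADD = c(30, NA, 2, NA) # del if > 19.19
  )
  s <- consensus_score(d, pm)
  # unanimous deleterious -> 1; 2 of 4 available -> 0.5; 3 of 5 -> 0.6
  expect_equal(s, c(1, 0.5, 0.6, NA))
  expect_equal(
    as.character(consensus_call(s)),
    c("deleterious", "deleterious", "deleterious", NA)
  )
})

test_that("consensus score is bounded and monotone in component votes", {
  model <- two_column_model()
  withr::with_seed(31, {
    d <- tibble::tibble(
      variant_id = as.character(1:50),
      label = "neutral",
      s1 = runif(50),
      s2 = runif(50)
    )
    d$s1[runif(50) < 0.2] <- NA
  })
  s <- consensus_score(d, model)
  expect_true(all(s >= 0 & s <= 1, na.rm = TRUE))
  # flipping any single neutral vote to deleterious never lowers the score
  for (i in c(2, 17, 40)) {
    d2 <- d
    if (!is.na(d2$s2[i]) && d2$s2[i] <= 0.5) d2$s2[i] <- 0.9
    expect_gte(consensus_score(d2, model)[i], ifelse(is.na(s[i]), 0, s[i]))
  }
})

test_that("ties at the cutoff are flagged deleterious, and bounds checked", {
  expect_equal(as.character(consensus_call(c(0.8, 0.2, 0.5))),
    c("deleterious", "neutral", "deleterious"))
  expect_error(consensus_call(1.2), "\\[0, 1\\]")
})

test_that("a single-component model reduces to that algorithm's calls", {
  withr::with_seed(8, {
    d <- tibble::tibble(
      variant_id = as.character(1:30),
      label = sample(c("deleterious", "neutral"), 30, replace = TRUE),
      s1 = rnorm(30)
    )
  })
  model <- consensus_model(tibble::tibble(
    algorithm = "s1", threshold = 0.2, direction = "greater"
  ))
  pred <- predict(model, d)
  direct <- ifelse(d$s1 > 0.2, "deleterious", "neutral")
  expect_equal(as.character(pred$consensus_call), direct)
})

test_that("evaluation report matches a hand-computed toy example", {
  d <- tibble::tibble(
    variant_id = paste0("v", 1:8),
    activity = c(0.05, 0.08, 0.3, 0.45, 0.6, 0.8, 0.95, 1.0),
    maf = c(0.0005, 0.002, 0.05, NA, 0.0002, 0.003, 0.02, 0.0001),
    label = label_from_activity(activity),
    s1 = c(1, 1, 1, 0, 1, 0, 0, 0), # votes via threshold 0.5, greater
    s2 = c(1, 1, 0, 0, 0, 0, 1, 0)
  )
  rep <- evaluate_model(d, two_column_model())

  # overall: consensus score = rowMeans; call deleterious iff >= 0.5
  # scores: 1, 1, .5, 0, .5, 0, .5, 0 -> calls D D D N D N D N
  # labels: D D D D N N N N -> tp 3, fn 1, fp 2, tn 2
  expect_equal(rep$overall$tp, 3)
  expect_equal(rep$overall$fn, 1)
  expect_equal(rep$overall$fp, 2)
  expect_equal(rep$overall$tn, 2)
  expect_equal(rep$overall$sensitivity, 3 / 4)
  expect_equal(rep$overall$specificity, 1 / 2)
  expect_equal(rep$overall$informedness, 0.25)

  bins <- rep$by_activity_bin
  expect_equal(bins$n, c(2L, 2L, 2L, 2L))
  expect_equal(bins$fraction_deleterious, c(1, 0.5, 0.5, 0.5))
  expect_equal(bins$mean_score, c(1, 0.25, 0.25, 0.25))
  expect_equal(
    bins$sem_score,
    c(0, sd(c(0.5, 0)) / sqrt(2), sd(c(0.5, 0)) / sqrt(2), sd(c(0.5, 0)) / sqrt(2))
  )

  # extreme-bin metrics: lof (v1 D, v2 D) and neutral_bin (v7 N, v8 N)
  expect_equal(rep$lof_neutral$sensitivity, 1)
  expect_equal(rep$lof_neutral$specificity, 0.5)
  expect_equal(rep$lof_neutral$informedness, 0.5)

  # per-bin n sums to the dataset size
  expect_equal(sum(bins$n), nrow(d))

  # MAF stratification drops v4 (no MAF)
  expect_equal(sum(rep$by_maf_bin$n), 7)

  # report metrics agree with an independent confusion recomputation
  pred <- predict(two_column_model(), d)
  cc <- confusion_counts(d$label, pred$consensus_call)
  expect_equal(rep$overall$informedness, informedness(cc))
})

test_that("a perfect model on noise-free data yields J = 1 everywhere", {
  d <- tibble::tibble(
    variant_id = as.character(1:20),
    activity = rep(c(0.02, 1.0), each = 10),
    maf = rep(c(0.0005, 0.02), 10),
    label = label_from_activity(activity),
    s1 = rep(c(1, 0), each = 10),
    s2 = rep(c(1, 0), each = 10)
  )
  rep <- evaluate_model(d, two_column_model())
  expect_equal(rep$overall$informedness, 1)
  expect_equal(rep$lof_neutral$informedness, 1)
  expect_equal(rep$by_activity_bin$fraction_deleterious[1], 1)
  expect_equal(rep$by_activity_bin$fraction_deleterious[4], 0)
  expect_true(all(rep$by_maf_bin$informedness == 1))
})

test_that("coverage reports per-algorithm and model-level missingness", {
  d <- tibble::tibble(
    variant_id = as.character(1:20),
    activity = runif(20),
    label = label_from_activity(activity),
    s1 = c(rep(NA, 1), runif(19)), # 5% missing
    s2 = c(NA, runif(19))
  )
  model <- two_column_model()
  cov <- prediction_coverage(d, model,
    registry = tibble::tibble(algorithm = c("s1", "s2"))
  )
  expect_equal(cov$fraction_unpredicted[cov$algorithm == "s1"], 0.05)
  # variant 1 is missing both components -> model misses 1/20
  expect_equal(
    cov$fraction_unpredicted[cov$algorithm == "consensus model"], 0.05
  )

  d$s2[1] <- 0.7 # now the other component covers the gap
  cov2 <- prediction_coverage(d, model,
    registry = tibble::tibble(algorithm = c("s1", "s2"))
  )
  expect_equal(
    cov2$fraction_unpredicted[cov2$algorithm == "consensus model"], 0
  )

  d$s1 <- runif(20)
  d$s2 <- runif(20)
  cov3 <- prediction_coverage(d, model,
    registry = tibble::tibble(algorithm = c("s1", "s2"))
  )
  expect_true(all(cov3$fraction_unpredicted == 0))
})

test_that("mean consensus score decreases from LOF to neutral on synthetic data", {
  # scores are generated from the deleterious/neutral class, so the two
  # deleterious bins (lof, decreased) must each out-score the two neutral
  # bins (moderate, neutral_bin)
  for (seed in 1:10) {
    panel <- synthetic_algorithms()[c(3, 4, 7, 8, 15), ]
    panel$target_auc <- 0.85
    panel$missing_rate <- 0
    sim <- simulate_variants(n_variants = 1000, algorithms = panel, seed = seed)
    thresholds <- optimize_thresholds(sim$data)
    model <- consensus_model(thresholds)
    rep <- evaluate_model(sim$data, model)
    ms <- rep$by_activity_bin$mean_score
    names(ms) <- as.character(rep$by_activity_bin$bin)
    expect_gt(min(ms[c("lof", "decreased")]), max(ms[c("moderate", "neutral_bin")]))
  }
})
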