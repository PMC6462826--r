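# Independent brute-force oracles used to check the fast implementations.
# These deliberately re-derive everything from first principles (explicit
# loops, direct counting) and share no code with the package internals.

# J at one strict threshold, by direct counting
oracle_j_at <- function(score, label, direction, t) {
  del_call <- if (direction == "greater") score > t else score < t
  tp <- sum(del_call & label == "deleterious")
  fn <- sum(!del_call & label == "deleterious")
  tn <- sum(!del_call & label == "neutral")
  fp <- sum(del_call & label == "neutral")
  tp / (tp + fn) + tn / (tn + fp) - 1
}

# maximum J over all real thresholds: sweeping a dense threshold set that
# contains a representative of every achievable operating point
oracle_max_j <- function(score, label, direction) {
  s <- sort(unique(score))
  eps <- min(diff(c(s[1] - 1, s))) / 4
  grid <- sort(unique(c(s - eps, s + eps, (utils::head(s, -1) + utils::tail(s, -1)) / 2)))
  max(vapply(grid, function(t) oracle_j_at(score, label, direction, t), 0))
}

# AUC via the Mann-Whitney rank statistic, ties counted half
oracle_rank_auc <- function(score, label, direction) {
  oriented <- if (direction == "greater") score else -score
  d <- oriented[label == "deleterious"]
  n <- oriented[label == "neutral"]
  wins <- 0
  for (x in d) {
    wins <- wins + sum(x > n) + 0.5 * sum(x == n)
  }
  wins / (length(d) * length(n))
}

# naive per-subset re-scoring of the combination search, identical
# objective definitions and tie-breaking, no incremental tricks
oracle_best_subset <- function(data, components, objective, cutoff = 0.5) {
  m <- nrow(components)
  label <- as.character(data$label)
  best <- NULL
  for (size in seq_len(m)) {
    for (idx in utils::combn(m, size, simplify = FALSE)) {
      comp <- components[idx, ]
      votes <- sapply(seq_len(nrow(comp)), function(j) {
        s <- data[[comp$algorithm[j]]]
        if (comp$direction[j] == "greater") {
          as.numeric(s > comp$threshold[j])
        } else {
          as.numeric(s < comp$threshold[j])
        }
      })
      votes <- matrix(votes, nrow = nrow(data))
      n_avail <- rowSums(!is.na(votes))
      cons <- rowSums(votes, na.rm = TRUE) / n_avail
      cons[n_avail == 0] <- NA
      call <- ifelse(is.na(cons), NA, ifelse(cons >= cutoff, "deleterious", "neutral"))
      if (objective == "mean_component_correctness") {
        correct <- votes == (label == "deleterious")
        value <- sum(correct, na.rm = TRUE) / sum(!is.na(votes))
      } else {
        valid <- !is.na(call)
        tp <- sum(valid & call == "deleterious" & label == "deleterious")
        tn <- sum(valid & call == "neutral" & label == "neutral")
        np <- sum(valid & label == "deleterious")
        nn <- sum(valid & label == "neutral")
        if (objective == "consensus_informedness") {
          if (np == 0 || nn == 0) next
          value <- tp / np + tn / nn - 1
        } else {
          value <- (tp + tn) / sum(valid)
        }
      }
      key <- paste(sort(comp$algorithm), collapse = "\r")
      if (is.null(best) || value > best$value ||
        (value == best$value && size < best$size) ||
        (value == best$value && size == best$size && key < best$key)) {
        best <- list(
          value = value, size = size, key = key,
          subset = sort(comp$algorithm)
        )
      }
    }
  }
  best
}

# small random labelled score set with both classes guaranteed
random_instance <- function(n, seed) {
  withr::with_seed(seed, {
    label <- c(
      "deleterious", "neutral",
      sample(c("deleterious", "neutral"), n - 2, replace = TRUE)
    )
    score <- round(stats::rnorm(n, mean = (label == "deleterious")), 2)
    tibble::tibble(label = label, score = score)
  })
}
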