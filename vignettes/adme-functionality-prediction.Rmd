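---
title: "Calibrating deleteriousness predictors for ADME genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating deleteriousness predictors for ADME genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admeopt)
library(dplyr)
```

## Why ADME genes need their own calibration

Variant-effect predictors lean heavily on evolutionary conservation and are
parameterized on disease mutations in constrained genes. Pharmacogenes are
different: they are polymorphic, weakly conserved, and their clinically
relevant "deleterious" endpoint is a quantitative loss of enzymatic or
transport activity, not a Mendelian phenotype. Applied with their stock
thresholds, standard tools either flag nearly everything (conservation-free
regions score low across the board) or nearly nothing. `admeopt` does not
build a new predictor; it re-calibrates existing ones against in vitro
activity data and fuses the best-performing subset into a consensus call.

## The data model

The unit of analysis is a single-nucleotide variant with

* `activity`: in vitro intrinsic clearance as a fraction of the wild-type
  allele (dimensionless, ≥ 0; values above 1 are valid gain-of-function
  observations). The label is **deleterious** iff activity < 0.5, i.e. a
  strictly more than 2-fold reduction; the label derives only from the assay,
  never from predictor scores. A per-variant `label_override` column
  supports curated exceptions (e.g. common variants established as neutral
  despite borderline assays) without hard-coding any variant identity.
* graded activity bins used for reporting: `lof` [0, 0.10), `decreased`
  [0.10, 0.50), `moderate` [0.50, 0.90], `neutral_bin` (0.90, ∞). The
  boundary placement follows the strict "< 10%" / "> 90%" reading; 0.50
  belongs to `moderate` because deleterious means *strictly more* than
  2-fold. These four bins partition the activity axis.
* `maf` bins: very rare < 0.1%, rare [0.1%, 1%), common ≥ 1%. Variants
  without a MAF are dropped from MAF-stratified reports only.
* one score column per algorithm, with `.`/empty as missing (the ANNOVAR
  convention). A variant scored by *no* algorithm carries no usable signal
  and is excluded at load (counted in the load report).

The 18-entry registry (`algorithm_registry()`) records each method's
deleteriousness direction and both threshold generations. Directions and
thresholds are data, not code: calls everywhere are strict inequalities in
the registry direction, so alternative panels can be supplied as YAML.

## Threshold optimization

For one algorithm, the scan evaluates J(x) = sens(x) + spec(x) − 1 at
candidate thresholds x and keeps the global maximum. Two candidate policies
exist:

* `midpoints` (default): one candidate between each pair of consecutive
  distinct observed scores plus one beyond each extreme. Strict-inequality
  calls are constant between observed scores, so this enumerates **every**
  achievable operating point — the scan optimum is the exact optimum over
  all real thresholds, with no step-size to choose. This also makes the
  strict-vs-non-strict call convention immaterial at the optimum.
* `fixed_grid`: an arithmetic sweep between the observed extremes at a
  user-chosen step (the convention of scanning in increments of 0.01–0.05).
  It can only ever visit a subset of the operating points, so it is
  dominated by `midpoints`; it is kept for fidelity and for regular-grid
  plots. Because the historical per-method increments are not documented,
  no per-algorithm default step is guessed — `step` must be given
  explicitly.

Ties at the maximal J are resolved toward the highest sensitivity, then
toward the candidate that widens the deleterious-flagged region (smallest
threshold for greater-direction scores, largest for less-direction). In a
screening setting a false alarm is cheaper than a missed loss-of-function
allele, so the conservative side of an exact tie is to flag more.

Variants missing the algorithm's score are excluded from that algorithm's
scan only (per-algorithm complete-case), mirroring how coverage gaps occur
in practice. `delta_informedness()` reports the gain of the optimized over
the conventional threshold on the same variants; PhyloP and PhastCons have
no literature default, so their gain is reported as not available rather
than zero.

## Cross-validation and combination search

`stratified_folds()` shuffles within each label class (seeded, restoring the
global RNG) and deals round-robin, so per-class fold sizes differ by at most
one; `cross_validate()` then re-fits thresholds *and* model composition on
each training split and scores the held-out fold, which keeps the reported
validation sensitivity/specificity honest about the full fitting pipeline,
not just the final thresholds.

The combination search enumerates all 2^m − 1 non-empty subsets of the m
candidate algorithms, feasible at m = 18 via Gray-code updates of the
per-variant vote sums (one component added or removed per step). The
objective deserves a note: the natural "sum of per-algorithm correct calls"
criterion is monotone non-decreasing in subset size — adding any algorithm
adds non-negative terms — so maximizing it literally always selects the full
panel. The package therefore optimizes a *normalized* criterion and makes
the choice explicit:

* `consensus_informedness` (default): J of the subset's consensus call,
  consistent with the Youden-centric calibration of the single algorithms
  and robust to the class imbalance of activity datasets;
* `consensus_accuracy`: overall accuracy of the consensus call;
* `mean_component_correctness`: the summed 0/1 correctness divided by the
  number of available calls — the normalized reading of the literal sum.

Ties break toward smaller subsets (parsimony), then lexicographically, so
selection is deterministic. The aggregated model across folds uses the modal
selected subset and, per component, the arithmetic mean of its fold-optimal
thresholds; `threshold_stability()` reports the |CV| (sample sd / mean) of
the fold optima — sample sd because k = 5 values are few.

## Consensus scoring and evaluation

Each component votes 1/0 by its strict threshold call; the consensus score
is the mean vote over available components, so it is bounded in [0, 1],
monotone in any single vote, and missing only when every component is. The
dichotomous call is deleterious iff score ≥ cutoff (default 0.5); an exact
half-split panel is flagged deleterious, again the conservative screening
side. With the five-component model and full coverage, ties at exactly 0.5
cannot arise; they can with missing components, which is why the rule is
stated.

`evaluate_model()` reports: overall confusion metrics; per-activity-bin
counts, fraction flagged and mean score ± s.e.m. (sample sd / √n); metrics
restricted to the extreme bins (`lof` vs `neutral_bin`), where dichotomous
evaluation is best defined; MAF-stratified metrics; coverage per component
and for the model; and an ordinary least-squares fit of the per-bin mean
score against bin-midpoint activity (midpoints 0.05, 0.30, 0.70, 0.95).
The 4-point OLS is an acknowledged simplification of "score tracks
functionality": it summarizes a mean-per-bin profile, not a per-variant
regression, and its R² should be read as descriptive.

Metrics with a zero denominator (e.g. sensitivity with no deleterious
variants in a stratum) return `NA_real_` — R's explicit undefined signal,
deliberately distinct from 0 — and callers decide how to treat them.

## The synthetic-data generator

`simulate_variants()` produces datasets with the structure of an annotated
pharmacogenetic score table and analytic ground truth:

* activity bins drawn with weights (0.32, 0.28, 0.19, 0.21), matching the
  composition of curated ADME activity data (about 109/337 severe
  loss-of-function and 71/337 fully neutral variants; the split of the
  middle mass between the two intermediate bins is chosen once as roughly
  3:2); activity uniform within the bin, the neutral bin extending to 1.2
  to admit mild gain-of-function;
* per-algorithm scores from an equal-variance binormal model: neutral
  scores ~ N(0, 1), deleterious ~ N(d, 1) with d = √2 · Φ⁻¹(AUC), mapped
  affinely onto each algorithm's nominal range (negated first for
  less-direction methods). Under this model the Youden-optimal threshold is
  d/2 and the maximal informedness 2Φ(d/2) − 1, so threshold recovery and
  J estimation are testable against closed forms;
* a shared latent factor (default ρ = 0.3) correlating the algorithms'
  errors, as real predictors share conservation-derived features; ρ = 0
  gives independent errors for ensemble-gain experiments;
* target AUCs for the default panel mirroring the methods' reported
  discriminative power on pharmacogenetic data (0.51–0.81) and missingness
  patterned on observed coverage (5% for SIFT/FATHMM/PROVEAN, 0 for the
  genome-wide scores);
* MAF log-uniform over 10⁻⁴–10⁻⁰·⁷, reproducing the rarity-dominated
  frequency spectrum.

What it does **not** emulate: graded score-activity coupling within a class
(scores depend on the binary label only, so the two deleterious bins share
one score distribution), substrate-specific assay effects,
inter-experimental noise in the activity values themselves, real allele
frequencies, or gene-level structure. Green tests on synthetic data
therefore demonstrate the correctness of the optimization, selection and
evaluation machinery — not the real-data performance of any particular
threshold set.

## Numerical and testing choices

* Candidate enumeration, vote sums and confusion counts are integer-exact in
  double arithmetic, so optima and tie-breaks are reproducible bit-for-bit;
  all randomness flows through explicit seeds (`withr::with_seed`), and the
  full simulate–train–evaluate pipeline is deterministic given a seed.
* AUC is the trapezoid under the strict-call ROC, equal to the Mann–Whitney
  rank statistic with ties counted half; the test suite checks this identity
  and cross-checks against an independent ROC implementation.
* Degenerate inputs fail loudly: single-class scans, all-missing scores,
  classes smaller than k, thresholds outside an algorithm's nominal range
  and malformed tables are errors, not warnings.
* Test problem sizes: oracle-equivalence checks run on ≥ 100 random
  instances of n ≤ 50 (and m = 6 algorithms for the subset search, where
  naive re-scoring is cheap); parameter recovery uses 2,000 variants per
  class (threshold within 0.15 sd, J within 0.04); AUC calibration uses
  10,000 variants; pipeline-level simulations use 250–400 variants at the
  study's scale of 337. These sizes keep every stochastic check comfortably
  inside its stated tolerance.

## Known limitations

* Activity is taken as pre-normalized input; defining the wild-type
  reference allele per gene is upstream curation, as is any genome-build
  liftover (coordinates are carried as optional metadata only).
* Indels, frameshifts and synonymous variants are out of scope: the
  framework consumes missense-style per-variant scores.
* The consensus is an unweighted vote; no per-component weighting, greedy
  search, nested cross-validation, or confidence intervals on AUC are
  provided.
* With few folds, the modal-subset rule can hide genuine between-fold
  disagreement; inspect `fold_results$subset` before trusting the
  aggregated composition.
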