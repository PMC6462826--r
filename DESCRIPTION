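Package: admeopt
Title: Pharmacogene-Optimized Functionality Prediction for ADME Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates in silico deleteriousness predictors for variants in
    drug absorption, distribution, metabolism and excretion (ADME) genes,
    where disease-trained defaults perform poorly. Per-algorithm
    classification thresholds are optimized by maximizing the Youden index
    (informedness) against in vitro intrinsic-clearance data, algorithm
    combinations are searched exhaustively under stratified cross-validation,
    and the selected components are fused into a consensus deleteriousness
    score. Ships the fixed published five-component consensus model, a
    binormal synthetic-data generator with closed-form ground truth for
    validation, evaluation stratified by activity and allele-frequency bins,
    and readers for ANNOVAR/dbNSFP-style annotated score tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
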