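Package: fcbench
Title: Fold-Change Estimators and Their Stress Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registry of fold-change estimators for two-group comparisons
    (ratio of arithmetic means or medians, geometric mean / mean of logs,
    median of logs, and all-combinations pairwise ratios with bootstrap
    variants), a signed symmetric-fold error metric, synthetic two-group
    generators over identity, uniform, normal, log-normal and mixed
    distribution families with known true fold changes, and reproducible
    simulation experiments that quantify when the arithmetic-mean-based
    fold change fails: unequal group variances, mixed group distributions,
    and globally permuted expression matrices.  Includes a bridge to
    two-group significance testing (Wilcoxon-Mann-Whitney, Welch t),
    Spearman concordance of effect size with significance, and Box-Cox /
    Tukey-ladder distribution profiling of expression matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
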