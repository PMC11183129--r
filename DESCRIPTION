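Package: mscortex
Title: Morphometric Similarity Networks of the Cerebral Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Case-control analysis of morphometric similarity (MS) networks
    built from multi-feature cortical morphometry. Provides a synthetic
    two-group, multi-site cohort generator; empirical-Bayes (ComBat-style)
    site harmonization; per-subject MS matrix construction with node and
    subnetwork summaries; edge-level inference via the network-based
    statistic with permutation family-wise error control; sparsity-
    thresholded binary graph metrics with a small-worldness threshold
    selection rule; and covariate-adjusted group comparisons with
    Benjamini-Hochberg false discovery rate control plus Spearman clinical
    associations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
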