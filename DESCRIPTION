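Package: sspconcord
Title: Consistency of Intrinsic Breast-Cancer Subtype Single-Sample Predictors
Version: 0.1.0
Authors@R: person("Maintainer", "sspconcord", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Nearest-centroid single-sample prediction of the five intrinsic
    breast-cancer molecular subtypes (luminal A, luminal B, normal breast-like,
    HER2-enriched, basal-like) from log2 expression matrices, under three
    systemic-bias adjustment regimes (none, gene mean-centring, and
    distance-weighted discrimination), together with pairwise agreement
    statistics (unweighted Cohen's kappa with large-sample confidence
    intervals), subtype-by-clinical-feature association tables, Kaplan-Meier
    and log-rank survival comparison, and a fully parameterized synthetic
    cohort generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
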