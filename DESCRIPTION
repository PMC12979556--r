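Package: nichescape
Title: Spatial Niche, Co-Localization and Malignancy Analysis for
    Spot-Based Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable implementations of the spatial statistics used to
    dissect the tumor microenvironment in spot-based (Visium-style)
    spatial transcriptomics: k-means composition clusters ("niches") from
    deconvolved cell-type weights with Calinski-Harabasz / gap-statistic /
    elbow selection of the cluster number, exact hypergeometric (Veech)
    cell-type co-occurrence within niches, a Ripley cross-K/L
    co-localization suite with Monte-Carlo independence envelopes,
    Aggregation Index and Cohen's d effect sizes, a CNV-similarity
    malignant-cell classifier, per-spot single-sample gene-set enrichment
    scoring, and a synthetic-data generator with planted ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
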