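Package: magale
Title: Data-Driven Meta-Analytic Grouping and ALE Meta-Analysis of
    Neuroimaging Activation Foci
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Coordinate-based meta-analysis toolkit that groups neuroimaging
    experiments by the spatial similarity of their modeled-activation (MA)
    maps rather than by a priori diagnostic or task categories.  Per
    experiment, activation foci are convolved with sample-size-dependent
    Gaussian kernels on a 2 mm grey-matter grid; experiments are clustered by
    Spearman correlation of their MA maps (correlation distance, average
    linkage) with multi-metric selection of the number of groups and
    subsample stability analysis; each retained meta-analytic grouping (MAG)
    is then submitted to an activation likelihood estimation (ALE)
    meta-analysis with permutation-based cluster-level family-wise error
    control; finally, over- and under-representation of diagnoses, task and
    sample characteristics across MAGs is assessed with exact binomial,
    chi-square and Kruskal-Wallis statistics.  A seeded synthetic-corpus
    generator with planted topographic groups makes every stage testable
    without access to any proprietary foci database.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
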