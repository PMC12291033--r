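Package: crossassay
Title: Multiblock PLS Integration of Multiassay LC-MS Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates two or more LC-MS feature-intensity tables measured
    on the same samples using a multiblock partial least squares (MB-PLS)
    model against a continuous or binary phenotype.  Feature selection uses
    multiblock variable importance in projection (MB-VIP) with permutation
    derived empirical p-values and a benchmarking procedure that picks the
    significance cutoff.  Selected features are clustered on intensity
    correlation, linked into isotopologue and adduct structural groups
    within and across assays by exact-mass and retention-time matching, and
    optionally annotated against region-of-interest (ROI) reference lists.
    Includes a seeded synthetic multiassay data generator with full ground
    truth for every stage of the workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    pROC
Config/testthat/edition: 3
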