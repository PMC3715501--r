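Package: rigscan
Title: Standardized Relative Information Gain for Gene-Gene Interaction
    Detection in Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects k-th order gene-gene interactions in case-control SNP
    data with entropy statistics on genotype-by-status contingency tables.
    The relative information gain (normalized mutual information) of every
    SNP combination is standardized against a permutation null distribution
    of the per-dataset maximum, giving family-wise error control and a
    score that is comparable across interaction orders. Includes scree and
    multidimensional-scaling visualizations, a two-locus penetrance-model
    simulator for power studies, and a multifactor dimensionality
    reduction (MDR) baseline with balanced accuracy and cross-validation
    consistency.
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
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
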