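Package: founderkit
Title: Genealogical Founder-Effect Statistics and Rare Founder-Variant Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise regional founder effects from deep
    genealogies and genotype panels. Implements pedigree reading, validation
    and cleaning (genealogical completeness, first-degree pruning,
    recent-immigrant removal), kinship and inbreeding coefficients with
    per-decade bootstrap confidence intervals, the ancestors' diversity
    ratio (ADR), a rare pathogenic variant screen based on the relative
    frequency difference between population clusters, and a classification
    of candidate variants into founder, familial, or multiple-introduction
    origins from identity-by-descent segment sharing. A synthetic demography
    and gene-dropping simulator generates internally consistent pedigree,
    genotype and IBD-segment bundles with known ground truth so that every
    stage of the pipeline can be validated without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    IRanges,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
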