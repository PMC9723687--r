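Package: rarescape
Title: Null-Model Inference of Community Assembly in Rare and Common Microbial Biospheres
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the ecological processes (variable selection, homogeneous
    selection, dispersal limitation, homogenizing dispersal, undominated) that
    structure rare and common fractions of microbial communities from amplicon
    feature tables and a phylogeny. Implements abundance-weighted beta mean
    nearest taxon distance (betaMNTD) and its tip-shuffling standardization
    (betaNTI), the abundance-based Raup-Crick statistic on Bray-Curtis
    dissimilarity (RC-bray), fixed and sample-specific (h-index style) rarity
    cutoffs with Chao1-based completeness recalibration, classification of taxa
    into rarity/commonness types, a Sloan neutral community model fit, and a
    synthetic-data generator with known ground-truth assembly regimes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    minpack.lm,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse
Config/testthat/edition: 3
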