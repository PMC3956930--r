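Package: rgccam
Title: Rare Genomic Changes from Conserved Amino Acids with Multiple
    Substitutions (RGC_CAM) for Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies alignment columns whose amino-acid replacements
    require two or more nucleotide substitutions under a genetic code
    (RGC_CAM sites) and evaluates their phylogenetic quality. Builds the
    minimum-nucleotide-substitution distance matrix between all amino-acid
    pairs from any genetic code table, classifies aligned protein columns
    as RGC_CAM, RGC_non-CAM or uninformative, maps informative sites to the
    bipartitions they support, scores per-site homoplasy with Fitch
    parsimony against a reference tree and over all small-tree topologies,
    computes internode certainty (IC/ICA) and tree certainty (TC/TCA) from
    bipartition support counts, and runs the associated statistical
    comparisons (Fisher's exact test on support contingency tables,
    seeded site binning and Wilcoxon rank-sum tests on bin-mean homoplasy).
    A seeded simulator plants labelled RGC_CAM and RGC_non-CAM sites per
    bipartition so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
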