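Package: flankfx
Title: Local Position Effects of Targeted Mouse Mutations from RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis workflow for surveying local ("position") effects of
    targeted mouse knockout alleles on neighboring gene expression.
    Provides differential-expression calling for pooled no-replicate
    HOM/WT RNA-seq library pairs under a negative-binomial model with a
    cross-gene dispersion trend, a strand-aware +/-500 kb flanking-gene
    survey with spatial topography, a genome-wide empirical null with
    chi-square comparisons, an exon-pattern classifier that confirms
    targeting of gene-trap (TRAP) and deletion (DEL) alleles, a
    regulatory-element disruption scoring rule over TFBS and ChIP-peak
    intervals, and a synthetic-data generator so the whole pipeline runs
    and is validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
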