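Package: redar
Title: Coverage-Based Discovery and Screening of RNA Elements from RNA-seq
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transcribed, unannotated regions of a genome ("RNA
    elements", REs) directly from RNA-seq read-coverage tracks, without
    transcript assembly. Mean coverage is computed over fixed 10 bp bins,
    bins exceeding a reads-per-million threshold outside annotated exons
    are merged across gaps of up to 150 bp into novel REs, and merged
    elements are classified as intronic, near-exon or orphan by their
    distance to annotated exons. Downstream tools quantify REs in RPKM,
    call expressed REs at a median-RPKM threshold, test repeat-family
    enrichment with hypergeometric tests and Bonferroni correction,
    classify maternal/paternal transmission of zygotic REs, sweep
    positive-predictive-value parameter grids, and intersect exonic RE
    calls with reference expression databases. A deterministic synthetic
    fixture generator produces toy genomes, annotations, repeat tracks and
    noisy coverage with planted ground-truth elements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
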