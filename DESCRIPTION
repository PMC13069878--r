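Package: m6apost
Title: Post-Processing and Comparative Analysis of Site-Level m6A Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of site-level N6-methyladenosine (m6A)
    predictions in the m6Anet 'data.site_proba.csv' format. Provides
    descriptive summaries of modified sites, transcripts and genes
    (biotype frequencies, k-mer/DRACH usage, transcript length and
    chromosome distributions, metagene profiles over 5'UTR/CDS/3'UTR),
    exon-structure- and strand-aware projection of transcript coordinates
    to genomic coordinates with BED export, interval-based annotation
    against user-supplied BED features, and comparative analysis between
    conditions via a per-transcript weighted modification ratio with
    log2 ratios, Wilcoxon rank-sum differential-methylation testing and
    integration with differential gene-expression results into six
    functional categories. Includes a deterministic synthetic-data
    generator emulating all input formats for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    grDevices,
    graphics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
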