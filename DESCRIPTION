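Package: conjscreen
Title: Transposon Insertion Screens and Exclusion Statistics for Conjugative Plasmids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and scores transposon-directed insertion sequencing
    (TraDIS) screens for plasmid-borne conjugation exclusion factors:
    synthetic multi-replicon references, Tn5 insertion libraries,
    conjugation selection and junction-read synthesis; tag trimming,
    exact-seed junction mapping, per-gene insertion indices and
    output/input ratio candidate calling. Also computes mating-assay
    transfer frequencies and exclusion indices with the accompanying
    statistical treatment (Bartlett, one-way ANOVA, Tukey-Kramer,
    compact letter display on log10 frequencies), infers surface
    exclusion groups from sfx x traN exclusion-index matrices, and
    reproduces the comparative-genomics steps (homolog hit filtering,
    global protein alignment with percent identity, greedy identity
    clustering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    pheatmap,
    methods,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
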