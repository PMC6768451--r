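Package: clonescan
Title: Expressed Divergence Analysis Between Clonal Transcriptomes
Version: 0.1.0
Authors@R:
    person("clonescan", "developers", email = "clonescan@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for quantifying expressed genetic
    divergence between two clonal lineages from transcriptome data:
    contaminant and rRNA filtering with a seeded local aligner,
    bi-directional fixed-variant calling from read pileups, reciprocal
    best hit orthology, Nei-Gojobori (NG86) Ka/Ks estimation with Fisher
    exact selection classification, heterozygosity estimation, Fisher
    exact pathway enrichment, and empirical-Bayes negative-binomial
    differential expression. Ships a synthetic clone-pair transcriptome
    generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
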