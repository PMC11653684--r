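Package: splicedyn
Title: Splicing Dynamics of Cassette Exons: PSI Quantification, Dynamic and
    Tissue-Specific Exon Calling, and Flanking-Intron Motif Analysis
Version: 0.1.0
Authors@R: person("Muscle Splicing", "Maintainers", email = "maintainers@splicedyn.dev",
    role = c("aut", "cre"))
Description: Tools for exon-level alternative-splicing analysis from junction
    counts: percent-spliced-in (PSI) quantification with missing-value
    imputation and event filtering, differential cassette-exon calling between
    conditions and across ordered developmental stages using quasi-binomial
    generalized linear models with quasi-likelihood ratio F-tests,
    tissue-specificity scoring via a robust-entropy (modH) statistic,
    microexon and nonsense-mediated-decay annotation of cassette exons from
    gene models and sequence, IUPAC motif scanning with positional enrichment
    profiles over flanking introns, and a seeded beta-binomial simulator that
    generates junction counts, gene models and sequences with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    splines,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
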