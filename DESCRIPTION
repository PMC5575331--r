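Package: vigsome
Title: Transcriptome Response Profiling for Virus-Induced Gene Silencing
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for characterizing how plant
    transcriptomes respond to virus-induced gene silencing (VIGS) vectors.
    Implements small-RNA read preprocessing, unique-tag counting, TPM
    normalization and negative-binomial differential expression; candidate
    miRNA discovery by precursor folding and hairpin evaluation; PHAS locus
    detection by 189-nt sliding-window phase-register analysis with
    hypergeometric phasing p-values and phasing scores; degradome (PARE)
    cleavage-site scoring with CleaveLand-style categories and permutation
    p-values; long noncoding RNA classification by ORF length and coding
    potential; and alternative-splicing event extraction with Type I/II
    change classification.  A seeded synthetic-data generator plants ground
    truth (miRNA hairpins, phased siRNA loci, cleavage sites, expression and
    splicing switches) so every stage can be exercised end to end with known
    answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
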