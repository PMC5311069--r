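Package: clonexpand
Title: Clonal Expansion Analysis of Paired T Cell Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies antigen-driven clonal expansion between an ex vivo
    blood T cell receptor (TCR) repertoire and paired in vitro cultures
    (medium, carrier protein, antigen) via a log2 stimulation index, and
    characterizes the expanded clonotype set by V/J gene-usage skew against
    a resampling null, by pre-expansion abundance enrichment with a
    two-proportion z-test, and by Levenshtein-distance clustering of CDR3
    amino-acid sequences with center-star alignments and sequence logos.
    Ships a synthetic paired-repertoire generator with known ground truth
    (heavy-tailed clone sizes, division-time growth model, planted CDR3
    families) so every analysis stage is verifiable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
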