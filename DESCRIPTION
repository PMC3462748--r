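Package: pepmine
Title: Neuropeptide Precursor Discovery and Maturation from Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico neuropeptidome discovery pipeline for arthropod
    transcriptomes. Mines nucleotide contigs for neuropeptide precursor
    candidates by local alignment of curated reference peptides against
    six-frame translations, screens candidates by three classical precursor
    criteria (signal peptide, prohormone processing sites, length under 300
    residues), predicts prohormone convertase cleavage sites and
    post-translational modifications (C-terminal amidation, N-terminal
    pyroglutamate, tyrosine sulfation) to emit mature peptides with
    family-motif annotation, and reproduces the downstream quantitation used
    in settlement studies: 2^-ddCt developmental expression profiling with
    ANOVA/Tukey testing and arcsine-transformed metamorphosis bioassay
    analysis. Includes seeded generators for synthetic precursors,
    transcriptomes, qPCR Ct tables and settlement counts with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    rlang,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
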