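Package: ligandr
Title: Downstream Analysis of Immunopeptidomics Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of HLA ligandome (immunopeptidome)
    identification results. Reads peptide identification tables and UniProt-dialect
    FASTA databases, maps peptides onto their parent proteins, computes per-residue
    peptide coverage arrays and an L1 coverage distance between experiments, compares
    experiments by peptide/protein overlap, Jaccard index and classical
    multidimensional scaling, integrates gene expression, subcellular-compartment and
    organism-of-origin layers with the identified peptidome, extracts flanking-region
    n-mers and summarizes them as position frequency matrices, and provides a seeded
    synthetic-data generator with machine-readable ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
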