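Package: mitovult
Title: Comparative Mitogenome Characterization for Vultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative characterization of avian mitochondrial
    genomes, built around the mitogenome of the Asian king vulture
    (Sarcogyps calvus) and its comparison with other Old World (Gypini) and
    New World (Cathartidae) vultures. Provides gene-table parsing and
    validation, nucleotide composition and protein-coding-gene span
    statistics, codon counting and relative synonymous codon usage (RSCU)
    under the vertebrate mitochondrial code, perfect-microsatellite (SSR)
    scanning with per-region censuses, detection and side-chain chemical
    classification of group-conserved amino-acid substitution sites,
    uncorrected pairwise distances with pairwise deletion, and seeded
    synthetic-data generators with exposed ground truth for end-to-end
    testing. All user-facing functions take and return data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
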