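# Packaged data: transcriptions of the published Asian king vulture
# mitogenome gene table and the two substitution-site tables, shipped as
# plain TSV under inst/extdata so every analysis stage can be exercised
# without downloading anything.

extdata <- function(file) {
  system.file("extdata", file, package = "mitovult", mustWork = TRUE)
}

#' Asian king vulture mitogenome gene table
#'
#' The annotated feature table of the Sarcogyps calvus mitogenome
#' (GenBank OR896160; 17,750 bp): 13 protein-coding genes, 22 tRNAs,
#' 2 rRNAs and 2 control regions, with declared lengths, strands and
#' start/stop codons. One transcription note: the published ND3 row prints
#' coordinates spanning 351 bp against a declared length of 354 bp (and
#' the published protein-coding total of 11,407 bp requires 354); the
#' packaged table uses the 354-bp span, keeping the table internally
#' consistent.
#'
#' @return A feature tibble (see [read_feature_table()]), 39 rows.
#' @export
vulture_features <- function() {
  read_feature_table(extdata("sarcogyps_calvus_features.tsv"))
}

read_site_fixture <- function(file) {
  readr::read_tsv(
    extdata(file),
    col_types = readr::cols(
      gene = readr::col_character(),
      position = readr::col_integer(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
}

#' Group-conserved substitution sites: Gypini versus Cathartidae
#'
#' The 67 published alignment sites at which the Old World vulture group
#' (Gypini) and the New World vulture group (Cathartidae) are each
#' monomorphic for residues in different side-chain chemical classes.
#' `residue_a`/`printed_class_a` are the Gypini residue and its published
#' class label; `_b` the Cathartidae side. The printed labels are retained
#' verbatim so the classifier can be audited against them.
#'
#' @return A tibble with columns `gene`, `position`, `residue_a`,
#'   `residue_b`, `printed_class_a`, `printed_class_b` (67 rows).
#' @export
vulture_group_sites <- function() {
  read_site_fixture("gypini_cathartidae_sites.tsv")
}

#' Substitution sites private to Sarcogyps calvus within Gypini
#'
#' The 43 published sites distinguishing S. calvus from the other Gypini,
#' with the published residues and class labels kept verbatim
#' (`residue_a` = the other Gypini, `residue_b` = S. calvus). Note one
#' documented inconsistency in the source table: the ND3 position-108 row
#' labels threonine as Hydrophobic, whereas every property scheme in use
#' (including this package's) places T in Polar uncharged.
#'
#' @return A tibble with columns `gene`, `position`, `residue_a`,
#'   `residue_b`, `printed_class_a`, `printed_class_b` (43 rows).
#' @export
vulture_focal_sites <- function() {
  read_site_fixture("sarcogyps_gypini_sites.tsv")
}
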