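#' Genetic code tables
#'
#' Returns the codon-to-amino-acid map for a genetic code as a 64-row tibble.
#' The default is the vertebrate mitochondrial code, in which AGA and AGG are
#' stop codons (so the stop family has four members: TAA, TAG, AGA, AGG),
#' ATA codes for Met and TGA for Trp. The standard nuclear code is available
#' for comparison, since codon-usage software differs in how it treats
#' AGA/AGG when summarizing mitochondrial genes.
#'
#' Codons are written in the DNA alphabet; stop codons carry the amino-acid
#' symbol `"*"`. The tibble carries a `start_codons` attribute listing the
#' initiation codons admitted by the code (for the vertebrate mitochondrial
#' code this includes GTG, the initiation codon observed for COX1 in the
#' Asian king vulture, alongside ATG and the ATA/ATT/ATC alternatives).
#'
#' @param name `"vertebrate_mito"` (default) or `"standard"`.
#' @return A tibble with columns `codon` and `amino_acid` (64 rows), with
#'   attributes `code_name`, `start_codons` and `stop_codons`.
#' @examples
#' code <- genetic_code()
#' subset(as.data.frame(code), amino_acid == "*")
#' @export
genetic_code <- function(name = c("vertebrate_mito", "standard")) {
  name <- match.arg(name)
  id <- switch(name, vertebrate_mito = "2", standard = "1")
  map <- Biostrings::getGeneticCode(id)
  tbl <- tibble(codon = names(map), amino_acid = unname(map)) |>
    arrange(.data$codon)
  starts <- union("ATG", attr(map, "alt_init_codons"))
  if (name == "vertebrate_mito") starts <- union(starts, "GTG")
  attr(tbl, "code_name") <- name
  attr(tbl, "start_codons") <- sort(starts)
  attr(tbl, "stop_codons") <- sort(tbl$codon[tbl$amino_acid == "*"])
  tbl
}

#' Synonymous-codon families of a genetic code
#'
#' Groups the 64 codons by the amino acid they encode; the stop codons form
#' their own family (symbol `"*"`). Family sizes under the vertebrate
#' mitochondrial code range from 2 (e.g. Met: ATA/ATG) to 6 (Leu, Ser), with
#' a 4-codon stop family.
#'
#' @param code A code tibble from [genetic_code()].
#' @return A tibble with columns `amino_acid`, `codon`, `family_size`.
#' @export
code_families <- function(code = genetic_code()) {
  code |>
    group_by(.data$amino_acid) |>
    mutate(family_size = n()) |>
    ungroup() |>
    select("amino_acid", "codon", "family_size") |>
    arrange(.data$amino_acid, .data$codon)
}

code_lookup <- function(code) {
  setNames(code$amino_acid, code$codon)
}
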