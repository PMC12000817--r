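# Codon counting and relative synonymous codon usage (RSCU).

#' Count codons across coding sequences
#'
#' Counts in-frame, non-overlapping triplets from position 1 of each
#' oriented coding sequence. Trailing partial codons are ignored, and any
#' codon containing `N` is skipped (tallied in the `n_ambiguous` attribute).
#' With `include_stops = FALSE`, codons that are stops under the supplied
#' code are excluded from the table (useful when comparing against
#' software that drops terminators before computing usage).
#'
#' @param cds Character vector of oriented coding sequences, or a tibble
#'   from [extract_cds()].
#' @param include_stops Count stop codons too (default `TRUE`; under the
#'   vertebrate mitochondrial code the terminator family is TAA/TAG/AGA/AGG
#'   and its usage is itself of interest).
#' @param code A code tibble from [genetic_code()].
#' @return A 64-row tibble with columns `codon` and `count` (zero-filled),
#'   carrying attributes `n_ambiguous` (codons skipped for containing N)
#'   and `genes` (names of the sequences counted).
#' @examples
#' count_codons("ATGAAATAA") |> dplyr::filter(count > 0)
#' @export
count_codons <- function(cds, include_stops = TRUE, code = genetic_code()) {
  if (is.data.frame(cds)) {
    genes <- cds$name
    cds <- cds$cds
  } else {
    genes <- names(cds) %||% paste0("cds", seq_along(cds))
  }
  codons <- unlist(lapply(toupper(cds), function(s) {
    n_codons <- nchar(s) %/% 3L
    substring(s, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  }))
  n_ambiguous <- sum(!codons %in% ALL_CODONS)
  codons <- codons[codons %in% ALL_CODONS]
  if (!include_stops) {
    codons <- codons[!codons %in% attr(code, "stop_codons")]
  }
  tab <- table(factor(codons, levels = ALL_CODONS))
  out <- tibble(codon = ALL_CODONS, count = as.integer(tab))
  attr(out, "n_ambiguous") <- n_ambiguous
  attr(out, "genes") <- genes
  out
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its observed count divided by the mean count over its
#' synonymous family, so a value of 1 means no bias, above 1 positive bias
#' and below 1 negative bias; family RSCUs sum to the family size whenever
#' the family is used at all. Families are defined by the supplied genetic
#' code; under the vertebrate mitochondrial code the stop codons TAA, TAG,
#' AGA and AGG form their own 4-codon family. Codons of entirely unused
#' families carry value 0 and `family_unused = TRUE` rather than an error.
#'
#' @param usage A codon-count tibble from [count_codons()].
#' @param code A code tibble from [genetic_code()].
#' @param rna Render codons in the RNA alphabet (UAA, ...) for report
#'   parity with publication figures. Default DNA.
#' @return A tibble of class `rscu_table` with columns `codon`,
#'   `amino_acid`, `count`, `family_size`, `rscu`, `family_unused`.
#' @export
rscu <- function(usage, code = genetic_code(), rna = FALSE) {
  fam <- code_families(code)
  out <- fam |>
    left_join(usage, by = "codon") |>
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count)) |>
    group_by(.data$amino_acid) |>
    mutate(
      family_total = sum(.data$count),
      family_unused = .data$family_total == 0L,
      rscu = ifelse(
        .data$family_unused, 0,
        .data$count / (.data$family_total / .data$family_size)
      )
    ) |>
    ungroup() |>
    select(
      "codon", "amino_acid", "count", "family_size", "rscu", "family_unused"
    ) |>
    arrange(.data$amino_acid, .data$codon)
  if (rna) out$codon <- chartr("T", "U", out$codon)
  class(out) <- c("rscu_table", class(out))
  out
}

#' Rank codons by usage
#'
#' Sorts codons by count, descending; ties are broken lexicographically by
#' codon so the ranking is deterministic.
#'
#' @param x A tibble with `codon` and `count` columns ([count_codons()] or
#'   [rscu()] output).
#' @param n Optionally return only the top `n` codons.
#' @return The input rows, sorted; subset to `n` rows if requested.
#' @export
rank_codons <- function(x, n = NULL) {
  out <- x |> arrange(desc(.data$count), .data$codon)
  if (!is.null(n)) out <- head(out, n)
  out
}
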