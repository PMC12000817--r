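# Gene-table arithmetic and sequence-level characterization: lengths,
# nucleotide composition, protein-coding span, observed start/stop codons,
# translation under the vertebrate mitochondrial code.

#' Normalize a raw feature row
#'
#' Annotation tables print minus-strand features with their coordinates
#' high-to-low; this puts every feature into the single internal
#' representation `start <= end` plus a strand symbol, and computes the
#' length as `end - start + 1` (coordinates are 1-based inclusive
#' throughout the package).
#'
#' @param start,end Integer coordinates, in either order.
#' @param strand `"+"` or any dash glyph for minus.
#' @param ftype Optional feature type token (see [read_feature_table()]).
#' @return A one-row tibble with `start`, `end`, `strand`, `length` (and
#'   `ftype` when supplied).
#' @examples
#' normalize_feature(4076, 2934, "-") # length 1143
#' @export
normalize_feature <- function(start, end, strand, ftype = NULL) {
  start <- parse_coord(as.character(start))
  end <- parse_coord(as.character(end))
  if (start < 1L || end < 1L) abort("coordinates must be >= 1")
  strand <- parse_strand(strand)
  lo <- min(start, end)
  hi <- max(start, end)
  out <- tibble(
    start = lo, end = hi, strand = strand, length = hi - lo + 1L
  )
  if (!is.null(ftype)) out$ftype <- parse_ftype(ftype)
  out
}

#' Validate a feature table, report-only
#'
#' Returns one finding per problem found; it never raises on findings, so a
#' table transcribed verbatim from a publication can be audited without
#' being "fixed". Checked: declared length versus computed
#' `end - start + 1`; CDS lengths not divisible by 3 (incomplete stop
#' codons, common in mitogenomes); overlapping feature pairs
#' (informational: mitochondrial gene tables legitimately contain small
#' overlaps); features extending past the genome end when a length is
#' supplied.
#'
#' @param features A feature tibble from [read_feature_table()].
#' @param genome_length Optional genome length in bp for bounds checking.
#' @return A tibble with columns `feature`, `kind` (`length_mismatch`,
#'   `cds_length_not_triplet`, `overlap`, `out_of_bounds`), `severity`
#'   (`warning` or `info`) and `message`; zero rows when nothing was found.
#' @export
validate_feature_table <- function(features, genome_length = NULL) {
  findings <- list()
  mism <- features |>
    filter(!is.na(.data$declared_length), .data$declared_length != .data$length)
  if (nrow(mism) > 0L) {
    findings$mismatch <- tibble(
      feature = mism$name, kind = "length_mismatch", severity = "warning",
      message = sprintf(
        "declared length %d but coordinates span %d bp",
        mism$declared_length, mism$length
      )
    )
  }
  cds3 <- features |> filter(.data$ftype == "CDS", .data$length %% 3L != 0L)
  if (nrow(cds3) > 0L) {
    findings$cds3 <- tibble(
      feature = cds3$name, kind = "cds_length_not_triplet", severity = "info",
      message = sprintf(
        "length %d not divisible by 3 (%d trailing nt)",
        cds3$length, cds3$length %% 3L
      )
    )
  }
  n <- nrow(features)
  if (n > 1L) {
    pairs <- which(
      outer(features$start, features$end, `<=`) &
        outer(features$end, features$start, `>=`) &
        upper.tri(matrix(TRUE, n, n)),
      arr.ind = TRUE
    )
    if (nrow(pairs) > 0L) {
      findings$overlap <- tibble(
        feature = features$name[pairs[, 1L]],
        kind = "overlap", severity = "info",
        message = sprintf(
          "overlaps %s (%d..%d vs %d..%d)",
          features$name[pairs[, 2L]],
          features$start[pairs[, 1L]], features$end[pairs[, 1L]],
          features$start[pairs[, 2L]], features$end[pairs[, 2L]]
        )
      )
    }
  }
  if (!is.null(genome_length)) {
    oob <- features |> filter(.data$end > genome_length)
    if (nrow(oob) > 0L) {
      findings$oob <- tibble(
        feature = oob$name, kind = "out_of_bounds", severity = "warning",
        message = sprintf(
          "feature ends at %d but genome is %d bp", oob$end, genome_length
        )
      )
    }
  }
  if (length(findings) == 0L) {
    return(tibble(
      feature = character(), kind = character(), severity = character(),
      message = character()
    ))
  }
  bind_rows(findings)
}

#' Genome length from a sequence or a feature table
#'
#' The sequence length wins when a genome record is supplied; otherwise the
#' maximum feature end coordinate is used (annotation tables for complete
#' mitogenomes end at the final base).
#'
#' @param features A feature tibble.
#' @param genome Optional genome record (tibble from [read_fasta()] or a
#'   bare sequence string).
#' @return Length in bp (integer).
#' @export
genome_length_of <- function(features, genome = NULL) {
  if (!is.null(genome)) return(nchar(as_sequence(genome)))
  if (is.null(features) || nrow(features) == 0L) {
    abort("need a genome sequence or a non-empty feature table")
  }
  max(features$end)
}

#' Nucleotide composition (AT% / GC%)
#'
#' Percentages of A+T and G+C over the non-N positions of each sequence,
#' rounded half-up to one decimal. `N` bases are excluded from the
#' denominator.
#'
#' @param x A sequence tibble from [read_fasta()] or a character vector of
#'   sequences.
#' @return A tibble with columns `identifier`, `at_percent`, `gc_percent`,
#'   `n_excluded`.
#' @examples
#' composition("ACGT") # 50.0 / 50.0
#' @export
composition <- function(x) {
  if (is.character(x)) {
    x <- tibble(
      identifier = if (is.null(names(x))) paste0("seq", seq_along(x)) else names(x),
      sequence = toupper(x)
    )
  }
  stopifnot(is.data.frame(x), "sequence" %in% names(x))
  rows <- purrr::map2_dfr(x$identifier, x$sequence, function(id, s) {
    s <- toupper(s)
    counts <- table(factor(seq_chars(s), levels = c(DNA_BASES, "N")))
    used <- sum(counts[DNA_BASES])
    if (used == 0L) {
      abort(sprintf("sequence '%s' has no unambiguous bases", id))
    }
    tibble(
      identifier = id,
      at_percent = round_half_up(100 * (counts[["A"]] + counts[["T"]]) / used, 1),
      gc_percent = round_half_up(100 * (counts[["G"]] + counts[["C"]]) / used, 1),
      n_excluded = as.integer(counts[["N"]])
    )
  })
  rows
}

#' Protein-coding span of a gene table
#'
#' Sums the computed lengths of all CDS features and expresses the sum as a
#' percentage of the genome length (rounded half-up to two decimals).
#' Overlapping bases are NOT deduplicated: the span is the plain sum of
#' per-gene lengths, which is how mitogenome reports conventionally state
#' the protein-coding fraction.
#'
#' @param features A feature tibble containing at least one CDS.
#' @param genome_length Genome length in bp.
#' @return A one-row tibble with `pcg_total_bp` and `pcg_fraction`.
#' @export
pcg_span_stats <- function(features, genome_length) {
  cds <- features |> filter(.data$ftype == "CDS")
  if (nrow(cds) == 0L) abort("feature table contains no CDS")
  total <- sum(cds$length)
  tibble(
    pcg_total_bp = total,
    pcg_fraction = round_half_up(100 * total / genome_length, 2)
  )
}

#' Extract oriented coding sequences
#'
#' Cuts each CDS out of the genome (1-based inclusive coordinates),
#' reverse-complements minus-strand features, and reports the observed
#' start codon (first 3 nt) and observed stop codon. When the CDS length is
#' not a multiple of 3 the trailing 1-2 nt are reported as an incomplete
#' stop (`stop_complete = FALSE`); such stops are completed by
#' polyadenylation in vivo and are left as-is here.
#'
#' @param genome A genome record ([read_fasta()] tibble or sequence string).
#' @param features A feature tibble; only CDS rows are extracted unless
#'   `all_types = TRUE`.
#' @param all_types Extract every feature, not just CDS.
#' @return A tibble with columns `name`, `ftype`, `strand`, `length`, `cds`
#'   (oriented sequence), `observed_start_codon`, `observed_stop_codon`,
#'   `stop_complete`.
#' @export
extract_cds <- function(genome, features, all_types = FALSE) {
  s <- as_sequence(genome)
  n <- nchar(s)
  feats <- if (all_types) features else filter(features, .data$ftype == "CDS")
  if (any(feats$end > n | feats$start < 1L)) {
    bad <- feats$name[feats$end > n | feats$start < 1L][1L]
    abort(sprintf("feature '%s' is out of genome bounds", bad))
  }
  seqs <- substring(s, feats$start, feats$end)
  minus <- feats$strand == "-"
  seqs[minus] <- vapply(seqs[minus], revcomp, character(1), USE.NAMES = FALSE)
  len <- nchar(seqs)
  tail_len <- ifelse(len %% 3L == 0L, 3L, len %% 3L)
  tibble(
    name = feats$name, ftype = feats$ftype, strand = feats$strand,
    length = len, cds = seqs,
    observed_start_codon = substr(seqs, 1L, 3L),
    observed_stop_codon = substring(seqs, len - tail_len + 1L, len),
    stop_complete = len %% 3L == 0L
  )
}

#' Translate coding sequences
#'
#' Codon-by-codon translation under a genetic code. The terminal stop codon
#' is not included in the protein; internal stop codons are reported as
#' findings (`internal_stops` list-column of codon positions), not errors,
#' because annotation slips and incomplete stops make them informative. A
#' trailing partial codon is ignored and flagged.
#'
#' @param cds Character vector of oriented coding sequences, or a tibble
#'   from [extract_cds()].
#' @param code A code tibble from [genetic_code()].
#' @return A tibble with columns `name`, `protein`, `n_codons`,
#'   `starts_with_start_codon`, `terminal_stop` (the stop codon, or `NA`),
#'   `internal_stops` (list of codon indices), `incomplete_tail`.
#' @examples
#' translate_cds("ATGTGAAGA")$protein # "MW": TGA = Trp, AGA = stop
#' @export
translate_cds <- function(cds, code = genetic_code()) {
  if (is.data.frame(cds)) {
    nm <- cds$name
    cds <- cds$cds
  } else {
    nm <- if (is.null(names(cds))) paste0("cds", seq_along(cds)) else names(cds)
  }
  lookup <- code_lookup(code)
  stops <- attr(code, "stop_codons")
  starts <- attr(code, "start_codons")
  purrr::map2_dfr(nm, cds, function(id, s) {
    s <- toupper(s)
    len <- nchar(s)
    if (len < 3L) abort(sprintf("'%s': coding sequence shorter than one codon", id))
    n_codons <- len %/% 3L
    codons <- substring(s, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
    aa <- unname(lookup[codons])
    aa[is.na(aa)] <- "X" # codons containing N
    terminal_stop <- NA_character_
    if (aa[n_codons] == "*") {
      terminal_stop <- codons[n_codons]
      aa <- aa[-n_codons]
      codons <- codons[-n_codons]
    }
    tibble(
      name = id,
      protein = paste(aa, collapse = ""),
      n_codons = n_codons,
      starts_with_start_codon = substr(s, 1L, 3L) %in% starts,
      terminal_stop = terminal_stop,
      internal_stops = list(which(aa == "*")),
      incomplete_tail = len %% 3L != 0L
    )
  })
}

#' Full genome profile
#'
#' One call reproducing the standard characterization of an annotated
#' mitogenome: genome length, AT/GC composition, per-type feature counts,
#' protein-coding span, and per-feature records with observed start/stop
#' codons when a sequence is supplied.
#'
#' @param features A feature tibble from [read_feature_table()].
#' @param genome Optional genome record; enables composition and observed
#'   codons.
#' @param code Genetic code for start-codon checking.
#' @return An object of class `mito_profile`: a list with `summary` (one
#'   row), `per_feature`, and `findings` (from [validate_feature_table()]).
#'   [generics::tidy()] returns the per-feature table, [generics::glance()]
#'   the summary row.
#' @export
genome_profile <- function(features, genome = NULL, code = genetic_code()) {
  glen <- genome_length_of(features, genome)
  span <- pcg_span_stats(features, glen)
  counts <- features |> count(.data$ftype)
  n_of <- function(t) {
    v <- counts$n[counts$ftype == t]
    if (length(v) == 0L) 0L else v
  }
  summary <- tibble(
    genome_length = glen,
    n_cds = n_of("CDS"), n_trna = n_of("tRNA"), n_rrna = n_of("rRNA"),
    n_control_region = n_of("control_region"),
    pcg_total_bp = span$pcg_total_bp, pcg_fraction = span$pcg_fraction
  )
  per_feature <- features |>
    select("name", "ftype", "strand", "start", "end", "length")
  if (!is.null(genome)) {
    comp <- composition(if (is.data.frame(genome)) genome else tibble(
      identifier = "genome", sequence = as_sequence(genome)
    ))
    summary$at_percent <- comp$at_percent[[1L]]
    summary$gc_percent <- comp$gc_percent[[1L]]
    obs <- extract_cds(genome, features) |>
      select("name", "observed_start_codon", "observed_stop_codon", "stop_complete")
    per_feature <- left_join(per_feature, obs, by = "name")
  }
  out <- list(
    summary = summary,
    per_feature = per_feature,
    findings = validate_feature_table(features, glen)
  )
  class(out) <- "mito_profile"
  out
}

#' @export
print.mito_profile <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Mitogenome profile: %s bp; %d CDS / %d tRNA / %d rRNA / %d control region(s)\n",
    format(s$genome_length, big.mark = ","),
    s$n_cds, s$n_trna, s$n_rrna, s$n_control_region
  ))
  if ("at_percent" %in% names(s)) {
    cat(sprintf("  AT %.1f%% / GC %.1f%%\n", s$at_percent, s$gc_percent))
  }
  cat(sprintf(
    "  protein-coding span %s bp (%.2f%% of the genome)\n",
    format(s$pcg_total_bp, big.mark = ","), s$pcg_fraction
  ))
  nw <- sum(x$findings$severity == "warning")
  cat(sprintf(
    "  %d validation finding(s), %d warning(s)\n", nrow(x$findings), nw
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy mito_profile
#' @export
tidy.mito_profile <- function(x, ...) x$per_feature

#' @method glance mito_profile
#' @export
glance.mito_profile <- function(x, ...) x$summary
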