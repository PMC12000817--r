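# Readers and writers for every external format the pipeline touches.
# Everything downstream consumes the tibbles produced here.

NA_MARKERS <- c("", "-", "–", "−")
MINUS_GLYPHS <- c("-", "–", "−", "‑", "—")

is_na_marker <- function(x) is.na(x) | x %in% NA_MARKERS

#' Read nucleotide sequences from a FASTA file
#'
#' Sequences are uppercased, `U` is mapped to `T`, and IUPAC ambiguity codes
#' (R, Y, S, W, K, M, B, D, H, V) are collapsed to `N`, so every returned
#' sequence is over the alphabet A/C/G/T/N. Any other character is a format
#' error that names the offending record and position.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical flag stored on every record (mitogenomes are
#'   circular; the default leaves them linear because scanning is linear
#'   throughout the package).
#' @return A tibble with columns `identifier`, `sequence`, `length`,
#'   `circular`, one row per FASTA record in file order.
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) format_error("file does not exist", path = path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("^﻿", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) format_error("empty FASTA file", path = path)
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    format_error("FASTA must start with a '>' header", path = path, line = 1)
  }
  rec <- cumsum(is_header)
  ids <- trimws(sub("^>", "", lines[is_header]))
  seqs <- vapply(
    split(lines[!is_header], rec[!is_header]),
    paste, character(1), collapse = ""
  )
  # records with a header but no sequence lines
  seqs <- seqs[match(seq_along(ids), as.integer(names(seqs)))]
  seqs[is.na(seqs)] <- ""
  seqs <- vapply(
    seq_along(seqs),
    function(i) normalize_nucleotides(seqs[[i]], ids[[i]], path),
    character(1)
  )
  tibble(
    identifier = ids, sequence = unname(seqs),
    length = nchar(seqs), circular = circular
  )
}

normalize_nucleotides <- function(x, id, path = NULL) {
  x <- toupper(x)
  if (nchar(x) == 0L) {
    format_error(sprintf("record '%s' has an empty sequence", id), path = path)
  }
  x <- chartr("U", "T", x)
  x <- chartr("RYSWKMBDHV", strrep("N", 10), x)
  bad <- regexpr("[^ACGTN]", x)
  if (bad > 0L) {
    format_error(
      sprintf(
        "record '%s' has non-IUPAC character '%s' at position %d",
        id, substr(x, bad, bad), bad
      ),
      path = path
    )
  }
  x
}

#' Write sequences to a FASTA file
#'
#' @param x A data frame with columns `identifier` and `sequence` (as
#'   returned by [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrapping width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  stopifnot(is.data.frame(x), all(c("identifier", "sequence") %in% names(x)))
  out <- unlist(purrr::map2(x$identifier, x$sequence, function(id, s) {
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  writeLines(out, path)
  invisible(path)
}

FTYPE_LEVELS <- c("CDS", "tRNA", "rRNA", "control_region")

parse_ftype <- function(x, path = NULL, line = NULL) {
  key <- gsub("[ _-]", "", tolower(x))
  out <- c(
    cds = "CDS", trna = "tRNA", rrna = "rRNA",
    controlregion = "control_region", dloop = "control_region"
  )[key]
  if (any(is.na(out))) {
    format_error(
      sprintf("unknown feature type '%s'", x[is.na(out)][1L]),
      path = path, line = line
    )
  }
  unname(out)
}

parse_strand <- function(x, path = NULL, line = NULL) {
  out <- ifelse(x == "+", "+", ifelse(x %in% MINUS_GLYPHS, "-", NA))
  if (any(is.na(out))) {
    format_error(
      sprintf("unknown direction token '%s'", x[is.na(out)][1L]),
      path = path, line = line
    )
  }
  out
}

parse_coord <- function(x, path = NULL, line = NULL) {
  ok <- grepl("^[0-9]+$", trimws(x))
  if (!all(ok)) {
    format_error(
      sprintf("non-integer coordinate '%s'", x[!ok][1L]),
      path = path, line = line
    )
  }
  as.integer(trimws(x))
}

#' Read a mitogenome feature table
#'
#' Parses the ten-column tab-separated gene-table dialect used for annotated
#' mitogenomes: start, end, declared length, direction, type, gene name,
#' product, anticodon, start codon, stop codon. The header row is optional.
#' Minus-strand rows may list their coordinates high-to-low (as annotation
#' tables commonly print them); they are normalized to `start <= end` with
#' strand `"-"`. Any dash glyph (ASCII hyphen, en dash, minus sign) in the
#' direction column is read as minus. Declared length and declared
#' start/stop codons are retained verbatim for [validate_feature_table()];
#' the pipeline never overwrites an annotation with its own arithmetic.
#'
#' Unnamed control regions are assigned the conventional names `CR1`, `CR2`,
#' ... in table order.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `name`, `ftype` (one of CDS, tRNA, rRNA,
#'   control_region), `start`, `end`, `strand`, `length` (computed,
#'   `end - start + 1`), `product`, `anticodon`, `declared_length`,
#'   `declared_start_codon`, `declared_stop_codon`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) format_error("file does not exist", path = path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("^﻿", "", lines)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) format_error("empty feature table", path = path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  cells <- lapply(cells, function(x) {
    x <- trimws(x)
    length(x) <- 10L
    # dash glyphs are NA markers everywhere except the direction column,
    # where a dash means minus strand
    na <- is_na_marker(x)
    na[4L] <- FALSE
    x[na] <- NA_character_
    x
  })
  first <- cells[[1L]]
  if (!grepl("^[0-9]+$", first[[1L]] %||% "")) {
    cells <- cells[-1L]
    lineno <- lineno[-1L]
  }
  if (length(cells) == 0L) format_error("feature table has no rows", path = path)
  m <- do.call(rbind, cells)
  raw <- tibble(
    raw_start = parse_coord(m[, 1L], path),
    raw_end = parse_coord(m[, 2L], path),
    declared_length = suppressWarnings(as.integer(m[, 3L])),
    strand = parse_strand(m[, 4L], path),
    ftype = parse_ftype(m[, 5L], path),
    name = m[, 6L],
    product = m[, 7L],
    anticodon = m[, 8L],
    declared_start_codon = m[, 9L],
    declared_stop_codon = m[, 10L]
  )
  tab <- raw |>
    mutate(
      start = pmin(.data$raw_start, .data$raw_end),
      end = pmax(.data$raw_start, .data$raw_end),
      length = .data$end - .data$start + 1L
    )
  if (any(tab$start < 1L)) {
    format_error("coordinates must be >= 1", path = path)
  }
  cr <- tab$ftype == "control_region" & is.na(tab$name)
  tab$name[cr] <- paste0("CR", seq_len(sum(cr)))
  other <- is.na(tab$name)
  tab$name[other] <- paste0(tolower(tab$ftype[other]), "_", which(other))
  key <- paste(tab$name, tab$ftype, tab$anticodon, sep = "\r")
  if (anyDuplicated(key)) {
    format_error(
      sprintf(
        "duplicate feature '%s' (same name, type and anticodon)",
        tab$name[duplicated(key)][1L]
      ),
      path = path
    )
  }
  tab |>
    select(
      "name", "ftype", "start", "end", "strand", "length", "product",
      "anticodon", "declared_length", "declared_start_codon",
      "declared_stop_codon"
    )
}

#' Write a feature table in the ten-column TSV dialect
#'
#' Inverse of [read_feature_table()]: re-reading the written file reproduces
#' the input tibble.
#'
#' @param features A feature tibble from [read_feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  out <- tibble(
    start = features$start,
    end = features$end,
    length = features$length,
    direction = features$strand,
    type = sub("_", " ", features$ftype),
    gene = features$name,
    product = features$product,
    anticodon = features$anticodon,
    start_codon = features$declared_start_codon,
    stop_codon = features$declared_stop_codon
  )
  readr::write_tsv(out, path, na = "-")
  invisible(path)
}

#' Read one per-gene amino-acid alignment (aligned FASTA)
#'
#' Rows are uppercased; all rows must have equal length and carry distinct
#' taxon labels. The gap character is `-` (`.` is accepted and mapped to
#' `-`). Residues outside the 20 standard one-letter codes are retained
#' verbatim (e.g. `X`); downstream site detection treats them as
#' disqualifying ambiguities.
#'
#' @param path Path to an aligned FASTA file.
#' @param gene Gene symbol for the block; defaults to the file name without
#'   extension.
#' @return A tibble with columns `gene`, `taxon`, `sequence`.
#' @export
read_alignment <- function(path, gene = NULL) {
  gene <- gene %||% tools::file_path_sans_ext(basename(path))
  if (!file.exists(path)) format_error("file does not exist", path = path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("^﻿", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) format_error("empty alignment file", path = path)
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    format_error("FASTA must start with a '>' header", path = path, line = 1)
  }
  rec <- cumsum(is_header)
  ids <- trimws(sub("^>", "", lines[is_header]))
  if (anyDuplicated(ids)) {
    format_error(
      sprintf("duplicate taxon label '%s'", ids[duplicated(ids)][1L]),
      path = path
    )
  }
  seqs <- vapply(
    split(lines[!is_header], rec[!is_header]),
    paste, character(1), collapse = ""
  )
  seqs <- unname(seqs[match(seq_along(ids), as.integer(names(seqs)))])
  seqs[is.na(seqs)] <- ""
  seqs <- chartr(".", "-", toupper(seqs))
  if (length(ids) < 2L) {
    format_error("alignment needs at least 2 rows", path = path)
  }
  if (length(unique(nchar(seqs))) != 1L) {
    format_error("ragged alignment: rows differ in length", path = path)
  }
  bad <- regexpr("[^A-Z*-]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    format_error(
      sprintf(
        "row '%s' has invalid character at position %d", ids[i], bad[i]
      ),
      path = path
    )
  }
  tibble(gene = gene, taxon = ids, sequence = seqs)
}

#' Read a directory of per-gene alignments
#'
#' @param dir Directory containing aligned FASTA files
#'   (`*.fa`, `*.fasta`, `*.faa`), one per gene, named by gene symbol.
#' @return A tibble with columns `gene`, `taxon`, `sequence` covering all
#'   blocks.
#' @export
read_alignments <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.(fa|fasta|faa)$", full.names = TRUE))
  if (length(paths) == 0L) {
    format_error("no alignment files found", path = dir)
  }
  purrr::map_dfr(paths, read_alignment)
}

#' Write an alignment block to aligned FASTA
#'
#' @param block A tibble with columns `taxon` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(block, path) {
  write_fasta(
    tibble(identifier = block$taxon, sequence = block$sequence), path
  )
}

#' Read a taxon-to-group assignment file
#'
#' Two-column TSV mapping taxon label to group label, with an optional line
#' `focal:<TAB>taxon` (or `focal: taxon`) naming the focal taxon for
#' focal-versus-group comparisons.
#'
#' @param path Path to the group file.
#' @return A tibble with columns `taxon` and `group`; the focal taxon (or
#'   `NULL`) is stored in the `focal` attribute and is also returned by
#'   [focal_taxon()].
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) format_error("file does not exist", path = path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("^﻿", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) format_error("empty group file", path = path)
  focal_line <- grepl("^focal:", lines)
  focal <- NULL
  if (any(focal_line)) {
    focal <- trimws(sub("^focal:", "", lines[focal_line][1L]))
  }
  rows <- strsplit(lines[!focal_line], "\t", fixed = TRUE)
  if (length(rows) == 0L) format_error("group file assigns no taxa", path = path)
  bad <- vapply(rows, length, integer(1)) < 2L
  if (any(bad)) {
    format_error("group file rows must be 'taxon<TAB>group'", path = path)
  }
  tab <- tibble(
    taxon = trimws(vapply(rows, `[`, character(1), 1L)),
    group = trimws(vapply(rows, `[`, character(1), 2L))
  )
  if (anyDuplicated(tab$taxon)) {
    format_error(
      sprintf("duplicate taxon label '%s'", tab$taxon[duplicated(tab$taxon)][1L]),
      path = path
    )
  }
  if (!is.null(focal) && !focal %in% tab$taxon) {
    format_error(
      sprintf("focal taxon '%s' is not assigned to a group", focal),
      path = path
    )
  }
  attr(tab, "focal") <- focal
  tab
}

#' Focal taxon of a group partition
#'
#' @param partition A partition tibble from [read_groups()] or
#'   [generate_clade_alignments()].
#' @return The focal taxon label, or `NULL` if none is set.
#' @export
focal_taxon <- function(partition) attr(partition, "focal", exact = TRUE)

#' Write a plain TSV report
#'
#' All pipeline reports are plain tab-separated text with a header row;
#' missing values are written as empty cells.
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(table, path) {
  readr::write_tsv(as_tibble(table), path, na = "")
  invisible(path)
}
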