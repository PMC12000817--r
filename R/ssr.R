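# Perfect-microsatellite (SSR) scanning, motif lengths 1-6, and the
# per-region census in the shape mitogenome papers tabulate it.

#' Minimum repeat counts for the SSR scanner
#'
#' One minimum repeat count per motif length 1-6. The defaults (4 for
#' mononucleotide motifs, 3 for all longer motifs) follow common
#' microsatellite-search practice for organellar genomes; all minima must
#' be at least 2 (a single copy is not a repeat). All values are fully
#' configurable — published SSR totals are extremely sensitive to these
#' settings.
#'
#' @param mono,di,tri,tetra,penta,hexa Minimum repeat count for motif
#'   lengths 1-6.
#' @return A named integer vector of length 6.
#' @export
ssr_thresholds <- function(mono = 4, di = 3, tri = 3, tetra = 3,
                           penta = 3, hexa = 3) {
  out <- as.integer(c(mono, di, tri, tetra, penta, hexa))
  if (any(is.na(out)) || any(out < 2L)) {
    abort("all SSR thresholds must be integers >= 2")
  }
  names(out) <- as.character(1:6)
  out
}

# "1:4,2:3,..." CLI syntax -> thresholds vector
parse_ssr_thresholds <- function(spec) {
  thr <- ssr_thresholds()
  parts <- strsplit(spec, ",", fixed = TRUE)[[1L]]
  for (p in parts) {
    kv <- strsplit(trimws(p), ":", fixed = TRUE)[[1L]]
    if (length(kv) != 2L || !kv[1L] %in% names(thr)) {
      abort(sprintf("bad SSR threshold token '%s' (expected e.g. '1:4')", p))
    }
    thr[kv[1L]] <- as.integer(kv[2L])
  }
  ssr_thresholds(
    thr[["1"]], thr[["2"]], thr[["3"]], thr[["4"]], thr[["5"]], thr[["6"]]
  )
}

is_primitive_motif <- function(motif) {
  m <- nchar(motif)
  if (m == 1L) return(TRUE)
  for (d in seq_len(m - 1L)) {
    if (m %% d == 0L &&
        strrep(substr(motif, 1L, d), m %/% d) == motif) {
      return(FALSE)
    }
  }
  TRUE
}

#' Find perfect microsatellites
#'
#' Scans a sequence for maximal, non-extendable perfect tandem repeats of
#' primitive motifs of length 1-6. A repeat is reported when its full-copy
#' count reaches the threshold for its motif length; its span is exactly
#' `motif length x repeats` (a trailing partial copy is not part of the
#' hit). Runs containing `N` are never part of a hit. A longer-motif hit
#' whose span coincides with a reported shorter-motif hit is suppressed
#' (this follows from motif primitivity but is enforced explicitly).
#' Scanning is linear even for circular genomes; origin-spanning repeats
#' are not reported.
#'
#' @param genome A genome record ([read_fasta()] tibble or sequence string).
#' @param thresholds Minimum repeat counts from [ssr_thresholds()].
#' @return A tibble with columns `motif`, `motif_length`, `repeats`,
#'   `start`, `end`, sorted by `start` then `motif_length`.
#' @examples
#' find_ssrs("GGACACACACGG")
#' @export
find_ssrs <- function(genome, thresholds = ssr_thresholds()) {
  s <- as_sequence(genome)
  ch <- seq_chars(s)
  n <- length(ch)
  hits <- list()
  for (m in 1:6) {
    thr <- thresholds[[as.character(m)]]
    if (n < m * thr) next
    # match[i]: position i agrees with position i+m and neither is N
    match <- ch[seq_len(n - m)] == ch[seq_len(n - m) + m] &
      ch[seq_len(n - m)] != "N" & ch[seq_len(n - m) + m] != "N"
    r <- rle(match)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    for (j in which(r$values)) {
      k <- r$lengths[j]
      region_len <- k + m
      repeats <- region_len %/% m
      if (repeats < thr) next
      i <- run_start[j]
      motif <- substr(s, i, i + m - 1L)
      if (!is_primitive_motif(motif)) next
      hits[[length(hits) + 1L]] <- tibble(
        motif = motif, motif_length = m, repeats = repeats,
        start = i, end = i + repeats * m - 1L
      )
    }
  }
  if (length(hits) == 0L) {
    return(tibble(
      motif = character(), motif_length = integer(), repeats = integer(),
      start = integer(), end = integer()
    ))
  }
  out <- bind_rows(hits) |> arrange(.data$start, .data$motif_length)
  # drop longer-motif hits that merely restate a shorter-motif span
  out |>
    group_by(.data$start, .data$end) |>
    slice_min(.data$motif_length, n = 1, with_ties = FALSE) |>
    ungroup() |>
    arrange(.data$start, .data$motif_length)
}

#' Assign SSR hits to annotated regions
#'
#' Each hit is assigned to the feature containing its start position; when
#' several features cover the start (mitochondrial annotations overlap),
#' the first feature in table order wins. Hits starting outside every
#' feature go to `"(unidentified region)"`.
#'
#' @param hits A hit tibble from [find_ssrs()].
#' @param features A feature tibble sharing the genome's coordinates.
#' @return `hits` with a `region` column appended.
#' @export
assign_regions <- function(hits, features) {
  region <- vapply(hits$start, function(p) {
    inside <- which(features$start <= p & p <= features$end)
    if (length(inside) == 0L) "(unidentified region)"
    else features$name[inside[1L]]
  }, character(1))
  hits |> mutate(region = region)
}

#' Per-region SSR census
#'
#' Cross-tabulates hits by region and motif-length class in the layout the
#' comparative-mitogenomics literature prints: mono- (MRS), di- (DRS),
#' tri- (TriRS) and tetranucleotide (TetRS) repeat columns, a pooled
#' penta+hexa "microsatellite" column, and row/column totals.
#'
#' @param hits A hit tibble with a `region` column ([assign_regions()]).
#' @return A tibble with one row per region plus a `Total` row; columns
#'   `region`, `MRS`, `DRS`, `TriRS`, `TetRS`, `microsatellite`, `Total`.
#' @export
ssr_census <- function(hits) {
  if (!"region" %in% names(hits)) {
    abort("hits must carry a `region` column; run assign_regions() first")
  }
  classes <- c("MRS", "DRS", "TriRS", "TetRS",
               "microsatellite", "microsatellite")
  body <- hits |>
    mutate(class = factor(classes[.data$motif_length],
                          levels = unique(classes))) |>
    count(.data$region, .data$class) |>
    tidyr::pivot_wider(
      names_from = "class", values_from = "n", values_fill = 0L,
      names_expand = TRUE
    ) |>
    mutate(Total = rowSums(across(-"region"))) |>
    arrange(.data$region != "(unidentified region)", .data$region)
  totals <- body |>
    summarise(region = "Total", across(-"region", sum))
  bind_rows(body, totals)
}
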