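# Independent brute-force oracles used by the property-style tests.
# These re-derive the definitions positionally, without the vectorized
# run-length machinery the package uses.

oracle_primitive <- function(motif) {
  m <- nchar(motif)
  if (m == 1L) return(TRUE)
  divisors <- which(m %% seq_len(m - 1L) == 0L)
  !any(vapply(divisors, function(d) {
    paste(rep(substr(motif, 1L, d), m / d), collapse = "") == motif
  }, logical(1)))
}

# test every (start, motif length) pair directly
oracle_find_ssrs <- function(seq, thresholds) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(ch)
  rows <- list()
  for (m in 1:6) {
    thr <- thresholds[[as.character(m)]]
    for (i in seq_len(max(0L, n - m * thr + 1L))) {
      motif <- paste(ch[i:(i + m - 1L)], collapse = "")
      if (grepl("N", motif, fixed = TRUE)) next
      if (!oracle_primitive(motif)) next
      # left-maximal: the periodic run cannot start before i
      if (i > 1L && ch[i - 1L] == ch[i + m - 1L]) next
      len <- m
      j <- i + m
      while (j <= n && ch[j] != "N" && ch[j] == ch[j - m]) {
        len <- len + 1L
        j <- j + 1L
      }
      repeats <- len %/% m
      if (repeats < thr) next
      rows[[length(rows) + 1L]] <- data.frame(
        motif = motif, motif_length = m, repeats = repeats,
        start = i, end = i + repeats * m - 1L
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      motif = character(), motif_length = integer(), repeats = integer(),
      start = integer(), end = integer()
    ))
  }
  out <- do.call(rbind, rows)
  # identical spans: keep the shortest motif
  out <- out[order(out$start, out$end, out$motif_length), ]
  out <- out[!duplicated(out[c("start", "end")]), ]
  out[order(out$start, out$motif_length), , drop = FALSE]
}

random_dna <- function(n, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

# column-by-column re-derivation of the group-conserved site definition
oracle_group_sites <- function(alignments, partition, group_a, group_b) {
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  taxa_a <- partition$taxon[partition$group == group_a]
  taxa_b <- partition$taxon[partition$group == group_b]
  rows <- list()
  for (g in unique(alignments$gene)) {
    block <- alignments[alignments$gene == g, ]
    seqs <- lapply(block$sequence, function(s) strsplit(s, "")[[1L]])
    names(seqs) <- block$taxon
    len <- length(seqs[[1L]])
    for (col in seq_len(len)) {
      a <- vapply(seqs[taxa_a], `[`, character(1), col)
      b <- vapply(seqs[taxa_b], `[`, character(1), col)
      if (length(unique(a)) != 1L || length(unique(b)) != 1L) next
      if (a[[1L]] == b[[1L]]) next
      if (!a[[1L]] %in% aa20 || !b[[1L]] %in% aa20) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, column = col, residue_a = a[[1L]], residue_b = b[[1L]]
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      gene = character(), column = integer(),
      residue_a = character(), residue_b = character()
    ))
  }
  do.call(rbind, rows)
}

random_protein_alignment <- function(n_taxa, len, gene = "g",
                                     alphabet = c("A", "N", "P", "S", "-")) {
  tibble::tibble(
    gene = gene,
    taxon = paste0("t", seq_len(n_taxa)),
    sequence = vapply(seq_len(n_taxa), function(i) {
      paste(sample(alphabet, len, replace = TRUE), collapse = "")
    }, character(1))
  )
}
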