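# Seeded generators for every input class the pipeline consumes, with the
# planted ground truth exposed so each analysis stage can be tested for
# exact recovery without any downloads.

new_truth <- function(...) {
  out <- list(...)
  class(out) <- "mito_truth"
  out
}

#' @export
print.mito_truth <- function(x, ...) {
  cat("Synthetic ground truth (seed ", x$seed, "):\n", sep = "")
  for (nm in setdiff(names(x), "seed")) {
    v <- x[[nm]]
    if (is.data.frame(v)) {
      cat(sprintf("  %s: %d row(s)\n", nm, nrow(v)))
    } else if (is.atomic(v) && length(v) == 1L) {
      cat(sprintf("  %s: %s\n", nm, format(v)))
    } else {
      cat(sprintf("  %s: <%s>\n", nm, paste(class(v), collapse = "/")))
    }
  }
  invisible(x)
}

count_codon_string <- function(s) {
  n_codons <- nchar(s) %/% 3L
  substring(s, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
}

#' Generate a synthetic annotated mitogenome
#'
#' Builds a genome sequence realizing a feature layout: CDS regions are
#' filled codon by codon (declared start codon, body codons drawn from a
#' codon-weight map excluding stop codons, then the declared stop codon —
#' truncated when the CDS length is not a multiple of 3, mimicking
#' incomplete stops), minus-strand features are written as reverse
#' complements, and everything else is drawn from a nucleotide
#' distribution hitting the target AT percentage in expectation. The
#' default layout is the packaged vulture gene table, so the generated
#' genome is 17,750 bp with a 11,407-bp protein-coding span.
#'
#' Where two same-strand CDS overlap (real mitogenomes do this), the later
#' feature in table order takes precedence and the earlier gene's codons
#' are re-read from the final sequence for the truth tallies. Overlapping
#' CDS on opposite strands would need contradictory bases and raise an
#' error.
#'
#' @param layout A feature tibble ([read_feature_table()] /
#'   [vulture_features()]); features must not wrap the origin.
#' @param at_percent Target AT percentage for non-coding sequence.
#' @param codon_bias Optional named weight vector over codons for CDS body
#'   sampling; default uniform over the code's non-stop codons.
#' @param code Genetic code supplying the stop-codon set.
#' @param seed Integer seed; identical seeds give identical genomes.
#' @return A list with `genome` (one-record sequence tibble,
#'   `circular = TRUE`), `features` (the layout), and `truth` containing
#'   `codon_tallies` (per-gene codon counts as placed), `codon_counts`
#'   (the pooled 64-row table), `at_percent` and `seed`.
#' @export
generate_mitogenome <- function(layout = vulture_features(),
                                at_percent = 54.1, codon_bias = NULL,
                                code = genetic_code(), seed = 1) {
  set.seed(seed)
  n <- genome_length_of(layout)
  cds <- layout |> filter(.data$ftype == "CDS")
  if (nrow(cds) > 1L) {
    for (i in seq_len(nrow(cds) - 1L)) {
      for (j in seq(i + 1L, nrow(cds))) {
        overlaps <- cds$start[i] <= cds$end[j] && cds$end[i] >= cds$start[j]
        if (overlaps && cds$strand[i] != cds$strand[j]) {
          format_error(sprintf(
            "infeasible layout: CDS '%s' and '%s' overlap on opposite strands",
            cds$name[i], cds$name[j]
          ))
        }
      }
    }
  }
  at <- at_percent / 100
  ch <- sample(
    c("A", "T", "G", "C"), n, replace = TRUE,
    prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)
  )
  stops <- attr(code, "stop_codons")
  if (is.null(codon_bias)) {
    codon_bias <- setNames(
      rep(1, length(setdiff(ALL_CODONS, stops))), setdiff(ALL_CODONS, stops)
    )
  }
  codon_bias <- codon_bias[!names(codon_bias) %in% stops]
  placed <- vector("list", nrow(cds))
  names(placed) <- cds$name
  for (i in seq_len(nrow(cds))) {
    len <- cds$length[i]
    start_codon <- cds$declared_start_codon[i]
    if (is.na(start_codon)) start_codon <- "ATG"
    stop_codon <- cds$declared_stop_codon[i]
    if (is.na(stop_codon)) stop_codon <- "TAA"
    r <- len %% 3L
    tail_nt <- if (r == 0L) stop_codon else substr(stop_codon, 1L, r)
    n_body <- (len - 3L - nchar(tail_nt)) %/% 3L
    if (n_body < 0L) {
      format_error(sprintf("CDS '%s' too short for start and stop", cds$name[i]))
    }
    body <- sample(
      names(codon_bias), n_body, replace = TRUE,
      prob = codon_bias / sum(codon_bias)
    )
    oriented <- paste0(start_codon, paste(body, collapse = ""), tail_nt)
    written <- if (cds$strand[i] == "-") revcomp(oriented) else oriented
    ch[seq(cds$start[i], cds$end[i])] <- seq_chars(written)
    placed[[i]] <- oriented
  }
  s <- paste(ch, collapse = "")
  # truth tallies: sampled codons, except where a later CDS overwrote them
  tallies <- purrr::map_dfr(seq_len(nrow(cds)), function(i) {
    region <- substr(s, cds$start[i], cds$end[i])
    oriented <- if (cds$strand[i] == "-") revcomp(region) else region
    src <- if (oriented == placed[[i]]) placed[[i]] else oriented
    tibble(gene = cds$name[i], codon = count_codon_string(src))
  }) |>
    count(.data$gene, .data$codon, name = "count")
  pooled <- tallies |>
    group_by(.data$codon) |>
    summarise(count = sum(.data$count)) |>
    (\(x) {
      full_join(tibble(codon = ALL_CODONS), x, by = "codon") |>
        mutate(count = ifelse(is.na(.data$count), 0L, as.integer(.data$count)))
    })()
  list(
    genome = tibble(
      identifier = paste0("synthetic_mitogenome_seed", seed),
      sequence = s, length = n, circular = TRUE
    ),
    features = layout,
    truth = new_truth(
      seed = seed, at_percent = at_percent,
      codon_tallies = tallies, codon_counts = pooled
    )
  )
}

#' Plant perfect microsatellites into a genome
#'
#' Overwrites the requested spans with exact tandem repeats and adjusts the
#' single base on each side so that no plant extends beyond its declared
#' repeat count (the left flank is forced to differ from the motif's last
#' base, the right flank from its first). Plants must be primitive-motif,
#' in bounds, and non-overlapping including their flanking bases.
#'
#' @param genome A genome record ([read_fasta()] tibble or a generated one).
#' @param plants A tibble with columns `motif`, `repeats`, `position`
#'   (1-based start).
#' @return A list with `genome` (modified record tibble) and `truth` whose
#'   `ssrs` tibble gives motif, repeats, start and end of every plant.
#' @export
plant_ssrs <- function(genome, plants) {
  s <- as_sequence(genome)
  n <- nchar(s)
  plants <- as_tibble(plants)
  stopifnot(all(c("motif", "repeats", "position") %in% names(plants)))
  plants <- plants |>
    mutate(
      motif = toupper(.data$motif),
      motif_length = nchar(.data$motif),
      start = as.integer(.data$position),
      end = .data$start + .data$motif_length * as.integer(.data$repeats) - 1L
    )
  if (any(!grepl("^[ACGT]+$", plants$motif)) ||
      any(plants$motif_length > 6L) ||
      !all(vapply(plants$motif, is_primitive_motif, logical(1)))) {
    abort("plant motifs must be primitive, 1-6 bp, over A/C/G/T")
  }
  if (any(plants$repeats < 2L)) abort("plants need at least 2 repeats")
  if (any(plants$start < 1L | plants$end > n)) {
    abort("plant out of genome bounds")
  }
  guard <- plants |> arrange(.data$start)
  if (nrow(guard) > 1L &&
      any(guard$start[-1L] - 1L <= guard$end[-nrow(guard)] + 1L)) {
    abort("overlapping plants (flanking bases included)")
  }
  ch <- seq_chars(s)
  for (i in seq_len(nrow(plants))) {
    p <- plants[i, ]
    ch[seq(p$start, p$end)] <- seq_chars(strrep(p$motif, p$repeats))
    last_base <- substr(p$motif, p$motif_length, p$motif_length)
    first_base <- substr(p$motif, 1L, 1L)
    if (p$start > 1L && ch[p$start - 1L] == last_base) {
      ch[p$start - 1L] <- setdiff(DNA_BASES, last_base)[1L]
    }
    if (p$end < n && ch[p$end + 1L] == first_base) {
      ch[p$end + 1L] <- setdiff(DNA_BASES, first_base)[1L]
    }
  }
  out <- if (is.data.frame(genome)) genome[1L, ] else tibble(
    identifier = "planted", circular = FALSE
  )
  out$sequence <- paste(ch, collapse = "")
  out$length <- n
  list(
    genome = out,
    truth = new_truth(
      seed = NA_integer_,
      ssrs = plants |> select("motif", "motif_length", "repeats", "start", "end")
    )
  )
}

default_gene_lengths <- function() {
  cds <- vulture_features() |> filter(.data$ftype == "CDS")
  setNames(cds$length %/% 3L - 1L, cds$name)
}

#' Generate two clades of aligned protein sequences with planted sites
#'
#' Emulates per-gene amino-acid alignments of two monophyletic groups (by
#' default 5 Old World and 6 New World vultures): a random base protein per
#' gene, planted group-conserved substitution sites (group A monomorphic
#' for one residue, group B for another), optional substitutions private
#' to a focal taxon, optional between-group divergence (a fraction of
#' additional columns where the groups differ uniformly), and within-group
#' noise at the remaining columns. Replacement residues are drawn
#' uniformly from the 19 alternatives; no gaps are generated.
#'
#' In constraint mode (the default), noise is post-processed so that it
#' can never create a spurious group-conserved column or a spurious
#' focal-private column: the site detectors then recover exactly the
#' planted truth. With `constrain = FALSE` noise may, with small
#' probability, create additional qualifying columns (useful for power
#' exploration).
#'
#' @param gene_lengths Named integer vector of per-gene alignment lengths
#'   (amino acids); default: the 13 vulture protein lengths derived from
#'   the packaged gene table.
#' @param n_group_a,n_group_b Taxa per group.
#' @param group_labels Labels for the two groups.
#' @param planted_sites Tibble with columns `gene`, `column`, `residue_a`,
#'   `residue_b` (`residue_a != residue_b`).
#' @param focal_sites Tibble with columns `gene`, `column`,
#'   `residue_focal`; the focal taxon is the first group-A taxon.
#' @param noise_rate Per-residue within-group substitution probability at
#'   non-planted columns.
#' @param divergence Fraction of additional between-group divergent
#'   columns per gene (scalar or named per-gene vector).
#' @param constrain Forbid noise from creating spurious qualifying columns.
#' @param seed Integer seed.
#' @return A list with `alignments` (tibble `gene`/`taxon`/`sequence`),
#'   `partition` (tibble `taxon`/`group`, focal attribute set when
#'   `focal_sites` is given) and `truth` (planted and divergence columns,
#'   expected cross-group distance per gene, seed).
#' @export
generate_clade_alignments <- function(gene_lengths = default_gene_lengths(),
                                      n_group_a = 5, n_group_b = 6,
                                      group_labels = c("OWV", "NWV"),
                                      planted_sites = NULL,
                                      focal_sites = NULL,
                                      noise_rate = 0, divergence = 0,
                                      constrain = TRUE, seed = 1) {
  set.seed(seed)
  stopifnot(length(gene_lengths) >= 1L, !is.null(names(gene_lengths)))
  genes <- names(gene_lengths)
  taxa_a <- paste0(group_labels[1L], "_", seq_len(n_group_a))
  taxa_b <- paste0(group_labels[2L], "_", seq_len(n_group_b))
  focal <- if (!is.null(focal_sites)) taxa_a[1L] else NULL
  partition <- tibble(
    taxon = c(taxa_a, taxa_b),
    group = rep(group_labels, c(n_group_a, n_group_b))
  )
  attr(partition, "focal") <- focal
  planted_sites <- if (is.null(planted_sites)) {
    tibble(gene = character(), column = integer(),
           residue_a = character(), residue_b = character())
  } else {
    as_tibble(planted_sites)
  }
  if (any(planted_sites$residue_a == planted_sites$residue_b)) {
    abort("planted residue pairs must differ")
  }
  if (anyDuplicated(planted_sites[c("gene", "column")])) {
    abort("planted columns must be distinct")
  }
  focal_sites <- if (is.null(focal_sites)) {
    tibble(gene = character(), column = integer(), residue_focal = character())
  } else {
    as_tibble(focal_sites)
  }
  div_rate <- if (length(divergence) == 1L) {
    setNames(rep(divergence, length(genes)), genes)
  } else {
    divergence[genes]
  }
  div_cols_all <- list()
  rows <- list()
  for (g in genes) {
    len <- gene_lengths[[g]]
    base <- sample(AA_STANDARD, len, replace = TRUE)
    m <- matrix(
      rep(base, each = n_group_a + n_group_b),
      nrow = n_group_a + n_group_b,
      dimnames = list(c(taxa_a, taxa_b), NULL)
    )
    pg <- planted_sites |> filter(.data$gene == g)
    fg <- focal_sites |> filter(.data$gene == g)
    if (any(pg$column > len) || any(fg$column > len)) {
      abort(sprintf("planted column beyond gene '%s' length %d", g, len))
    }
    taken <- union(pg$column, fg$column)
    n_div <- round(div_rate[[g]] * len)
    div_cols <- integer()
    if (n_div > 0L) {
      free <- setdiff(seq_len(len), taken)
      if (length(free) < n_div) abort("divergence exceeds free columns")
      div_cols <- sort(sample(free, n_div))
      for (col in div_cols) {
        m[taxa_b, col] <- sample(setdiff(AA_STANDARD, base[col]), 1L)
      }
    }
    for (k in seq_len(nrow(pg))) {
      m[taxa_a, pg$column[k]] <- pg$residue_a[k]
      m[taxa_b, pg$column[k]] <- pg$residue_b[k]
    }
    for (k in seq_len(nrow(fg))) {
      col <- fg$column[k]
      if (fg$residue_focal[k] == m[taxa_a[2L], col]) {
        abort("focal residue must differ from the rest of its group")
      }
      m[taxa_a[1L], col] <- fg$residue_focal[k]
    }
    protected <- union(taken, div_cols)
    if (noise_rate > 0) {
      open <- setdiff(seq_len(len), protected)
      for (t in rownames(m)) {
        hit <- open[stats::runif(length(open)) < noise_rate]
        for (col in hit) {
          m[t, col] <- sample(setdiff(AA_STANDARD, m[t, col]), 1L)
        }
      }
      if (constrain) {
        open_cols <- setdiff(seq_len(len), protected)
        for (col in open_cols) {
          a_col <- m[taxa_a, col]
          b_col <- m[taxa_b, col]
          if (!is.null(focal)) {
            rest <- m[taxa_a[-1L], col]
            if (length(unique(rest)) == 1L && rest[1L] != m[focal, col]) {
              m[focal, col] <- rest[1L]
              a_col <- m[taxa_a, col]
            }
          }
          if (length(unique(a_col)) == 1L && length(unique(b_col)) == 1L &&
              a_col[1L] != b_col[1L]) {
            fix_taxon <- taxa_a[length(taxa_a)]
            m[fix_taxon, col] <-
              setdiff(AA_STANDARD, c(a_col[1L], b_col[1L]))[1L]
          }
        }
      }
    }
    div_cols_all[[g]] <- div_cols
    rows[[g]] <- tibble(
      gene = g, taxon = rownames(m),
      sequence = apply(m, 1L, paste, collapse = "")
    )
  }
  expected <- tibble(
    gene = genes,
    length = as.integer(gene_lengths[genes]),
    n_divergent = vapply(div_cols_all[genes], length, integer(1)),
    n_planted = vapply(genes, function(g) {
      sum(planted_sites$gene == g)
    }, integer(1))
  ) |>
    mutate(
      expected_cross_distance =
        100 * (.data$n_divergent + .data$n_planted) / .data$length
    )
  list(
    alignments = bind_rows(rows),
    partition = partition,
    truth = new_truth(
      seed = seed,
      planted_sites = planted_sites,
      focal_sites = focal_sites,
      divergence_columns = tibble(
        gene = rep(genes, vapply(div_cols_all[genes], length, integer(1))),
        column = unlist(div_cols_all[genes], use.names = FALSE)
      ),
      expected_distances = expected,
      noise_rate = noise_rate,
      constrained = constrain
    )
  )
}
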