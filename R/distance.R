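# Pairwise uncorrected distances over gapped alignments, with pairwise or
# complete deletion, per gene or over the concatenation.

#' Uncorrected p-distance between two aligned sequences
#'
#' Pairwise deletion: columns where either row carries a gap (`-`) or a
#' non-standard residue are excluded; the distance is
#' `100 * mismatches / used sites`.
#'
#' @param row_a,row_b Equal-length gapped strings.
#' @return A one-row tibble with `distance` (percent, unrounded) and
#'   `used_sites`.
#' @examples
#' p_distance("A-CG", "AACG") # 0 over 3 sites
#' @export
p_distance <- function(row_a, row_b) {
  a <- seq_chars(toupper(row_a))
  b <- seq_chars(toupper(row_b))
  if (length(a) != length(b)) abort("rows differ in length")
  usable <- a %in% AA_STANDARD & b %in% AA_STANDARD
  used <- sum(usable)
  if (used == 0L) abort("no usable sites after pairwise deletion")
  tibble(
    distance = 100 * sum(a[usable] != b[usable]) / used,
    used_sites = used
  )
}

#' Pairwise distance matrix over per-gene alignments
#'
#' Computes all pairwise distances, per gene or over the concatenated
#' alignment, as percentages rounded half-up to two decimals. The default
#' is the uncorrected p-distance with pairwise deletion; a
#' Poisson-corrected variant (`-ln(1 - p)`, in percent) and complete
#' deletion (columns with a gap or ambiguity in ANY taxon dropped before
#' any pair is compared) are available because published distance tables
#' rarely state which settings produced them.
#'
#' @param alignments A tibble with columns `gene`, `taxon`, `sequence`;
#'   when `concatenate = TRUE` all genes must share the same taxon set.
#' @param concatenate One matrix over the concatenation (default) or one
#'   per gene.
#' @param method `"p"` (default) or `"poisson"`.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return A tibble of class `mito_dist` in long format: `gene` (or
#'   `"concatenated"`), `taxon_a`, `taxon_b`, `distance`, `used_sites`,
#'   one row per unordered taxon pair. [dist_to_matrix()] reshapes one
#'   gene's rows to a symmetric labeled matrix.
#' @export
distance_matrix <- function(alignments, concatenate = TRUE,
                            method = c("p", "poisson"),
                            deletion = c("pairwise", "complete")) {
  method <- match.arg(method)
  deletion <- match.arg(deletion)
  blocks <- split(alignments, alignments$gene)
  if (concatenate) {
    taxon_sets <- lapply(blocks, function(b) sort(b$taxon))
    if (length(unique(taxon_sets)) != 1L) {
      abort("concatenation requires the same taxon set in every gene")
    }
    taxa <- sort(blocks[[1L]]$taxon)
    concat <- vapply(taxa, function(t) {
      paste(vapply(blocks, function(b) {
        b$sequence[b$taxon == t]
      }, character(1)), collapse = "")
    }, character(1))
    blocks <- list(concatenated = tibble(
      gene = "concatenated", taxon = taxa, sequence = unname(concat)
    ))
  }
  out <- purrr::map_dfr(blocks, function(block) {
    taxa <- block$taxon
    seqs <- setNames(block$sequence, taxa)
    if (deletion == "complete") {
      m <- alignment_matrix(block)
      keep <- apply(m, 2, function(col) all(col %in% AA_STANDARD))
      seqs <- setNames(
        apply(m[, keep, drop = FALSE], 1, paste, collapse = ""), taxa
      )
    }
    pairs <- utils::combn(taxa, 2L)
    purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      d <- p_distance(seqs[[pairs[1L, k]]], seqs[[pairs[2L, k]]])
      tibble(
        gene = block$gene[[1L]],
        taxon_a = pairs[1L, k], taxon_b = pairs[2L, k],
        distance = d$distance, used_sites = d$used_sites
      )
    })
  })
  if (method == "poisson") {
    p <- out$distance / 100
    if (any(p >= 1)) abort("Poisson correction undefined at p = 1")
    out$distance <- -log(1 - p) * 100
  }
  out$distance <- round_half_up(out$distance, 2)
  class(out) <- c("mito_dist", class(out))
  out
}

#' Reshape long-format distances to a symmetric matrix
#'
#' @param distances A `mito_dist` tibble from [distance_matrix()].
#' @param gene Which gene's rows to reshape (default the first present).
#' @return A symmetric numeric matrix with zero diagonal and taxon labels.
#' @export
dist_to_matrix <- function(distances, gene = NULL) {
  gene <- gene %||% distances$gene[[1L]]
  d <- distances[distances$gene == gene, ]
  taxa <- sort(unique(c(d$taxon_a, d$taxon_b)))
  m <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  m[cbind(d$taxon_a, d$taxon_b)] <- d$distance
  m[cbind(d$taxon_b, d$taxon_a)] <- d$distance
  m
}

#' Group-wise distance summaries
#'
#' Summaries of pairwise distances between (and within) groups, or between
#' a focal taxon and each group — the form in which comparative mitogenome
#' studies quote their distance results ("focal vs group X ranged from
#' a% to b%").
#'
#' @param distances A `mito_dist` tibble from [distance_matrix()].
#' @param partition A group tibble from [read_groups()].
#' @param focal Optional focal taxon; when set, summaries are focal versus
#'   each group (the focal taxon's own pairings excluded from its group).
#' @return A tibble with columns `gene`, `group_a`, `group_b` (or `group`
#'   when focal), `min`, `mean`, `max`, `n_pairs`.
#' @export
dist_group_summary <- function(distances, partition, focal = NULL) {
  focal <- focal %||% focal_taxon(partition)
  grp <- setNames(partition$group, partition$taxon)
  if (!is.null(focal)) {
    d <- distances |>
      filter(.data$taxon_a == focal | .data$taxon_b == focal) |>
      mutate(
        other = ifelse(.data$taxon_a == focal, .data$taxon_b, .data$taxon_a),
        group = unname(grp[.data$other])
      )
    return(
      d |>
        group_by(.data$gene, .data$group) |>
        summarise(
          min = min(.data$distance), mean = mean(.data$distance),
          max = max(.data$distance), n_pairs = n(), .groups = "drop"
        )
    )
  }
  distances |>
    mutate(
      ga = pmin(unname(grp[.data$taxon_a]), unname(grp[.data$taxon_b])),
      gb = pmax(unname(grp[.data$taxon_a]), unname(grp[.data$taxon_b]))
    ) |>
    group_by(.data$gene, group_a = .data$ga, group_b = .data$gb) |>
    summarise(
      min = min(.data$distance), mean = mean(.data$distance),
      max = max(.data$distance), n_pairs = n(), .groups = "drop"
    )
}
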