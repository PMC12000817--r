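# Detection of group-conserved amino-acid substitution sites between two
# taxon groups, their side-chain chemical classification, and summaries.

#' Side-chain property scheme
#'
#' Maps each of the 20 standard residues to a chemical class:
#' Hydrophobic (A, V, L, I, M, F, W, Y), Polar uncharged (S, T, N, Q),
#' Positive (K, R, H), Negative (D, E) and Special case (C, G, P). The
#' special-case residues — cysteine (disulfide bonds), glycine
#' (conformational freedom) and proline (backbone rigidity) — are each
#' treated as their own singleton class wherever the package asks whether
#' two residues fall in *different* classes: a C-to-G exchange is a
#' chemical-class change even though both are "special".
#'
#' @return A tibble with columns `residue` and `class` (20 rows).
#' @export
property_scheme <- function() {
  tibble(
    residue = c(
      "A", "V", "L", "I", "M", "F", "W", "Y",
      "S", "T", "N", "Q",
      "K", "R", "H",
      "D", "E",
      "C", "G", "P"
    ),
    class = c(
      rep("Hydrophobic", 8),
      rep("Polar uncharged", 4),
      rep("Positive", 3),
      rep("Negative", 2),
      rep("Special case", 3)
    )
  )
}

#' Classify residues by side-chain chemistry
#'
#' @param residue Character vector of one-letter residue codes.
#' @param scheme A scheme tibble from [property_scheme()].
#' @return Character vector of class labels.
#' @examples
#' classify_residue(c("H", "Y", "Q")) # Positive, Hydrophobic, Polar uncharged
#' @export
classify_residue <- function(residue, scheme = property_scheme()) {
  lookup <- setNames(scheme$class, scheme$residue)
  out <- unname(lookup[toupper(residue)])
  if (any(is.na(out))) {
    abort(sprintf(
      "unknown residue '%s'", residue[is.na(out)][1L]
    ))
  }
  out
}

# class used when deciding whether two residues differ chemically:
# C, G, P are singletons, everything else uses its scheme class
effective_class <- function(residue, scheme = property_scheme()) {
  cls <- classify_residue(residue, scheme)
  ifelse(cls == "Special case", toupper(residue), cls)
}

#' Are two residues in different chemical classes?
#'
#' Uses the singleton rule for the special-case residues C, G and P (see
#' [property_scheme()]).
#'
#' @param residue_a,residue_b One-letter residue codes (vectorized).
#' @param scheme A scheme tibble.
#' @return Logical vector.
#' @export
cross_class <- function(residue_a, residue_b, scheme = property_scheme()) {
  effective_class(residue_a, scheme) != effective_class(residue_b, scheme)
}

alignment_matrix <- function(block) {
  m <- do.call(rbind, strsplit(block$sequence, "", fixed = TRUE))
  rownames(m) <- block$taxon
  m
}

classify_site_pair <- function(gene, position, residue_a, residue_b,
                               scheme) {
  tibble(
    gene = gene, position = position,
    residue_a = residue_a, residue_b = residue_b,
    class_a = classify_residue(residue_a, scheme),
    class_b = classify_residue(residue_b, scheme),
    cross_class = cross_class(residue_a, residue_b, scheme),
    special_involved = residue_a %in% c("C", "G", "P") |
      residue_b %in% c("C", "G", "P")
  )
}

#' Find group-conserved substitution sites
#'
#' Scans every alignment column of every gene for sites where two taxon
#' groups are each monomorphic yet differ from one another: all group-A
#' rows share one residue, all group-B rows share a different residue, and
#' no qualifying row carries a gap or a non-standard residue at that
#' column. Such sites are candidate lineage-diagnostic substitutions.
#' Positions are reported in ungapped numbering relative to the first
#' group-A taxon (the reference), alongside the raw alignment column.
#'
#' @param alignments A tibble with columns `gene`, `taxon`, `sequence`
#'   ([read_alignment()] / [read_alignments()]).
#' @param partition A group tibble from [read_groups()].
#' @param group_a,group_b Group labels to compare; default the first two
#'   labels in partition order.
#' @param scheme A scheme tibble from [property_scheme()].
#' @return A tibble with columns `gene`, `position`, `column`, `residue_a`,
#'   `residue_b`, `class_a`, `class_b`, `cross_class`, `special_involved`.
#' @export
find_group_conserved_sites <- function(alignments, partition,
                                       group_a = NULL, group_b = NULL,
                                       scheme = property_scheme()) {
  groups <- unique(partition$group)
  group_a <- group_a %||% groups[1L]
  group_b <- group_b %||% groups[2L]
  taxa_a <- partition$taxon[partition$group == group_a]
  taxa_b <- partition$taxon[partition$group == group_b]
  if (length(taxa_a) == 0L || length(taxa_b) == 0L) {
    abort("both groups must contain at least one taxon")
  }
  purrr::map_dfr(split(alignments, alignments$gene), function(block) {
    missing <- setdiff(c(taxa_a, taxa_b), block$taxon)
    if (length(missing) > 0L) {
      abort(sprintf(
        "gene '%s': taxa missing from alignment: %s",
        block$gene[[1L]], paste(missing, collapse = ", ")
      ))
    }
    m <- alignment_matrix(block)
    a <- m[taxa_a, , drop = FALSE]
    b <- m[taxa_b, , drop = FALSE]
    ref <- m[taxa_a[1L], ]
    ref_pos <- cumsum(ref != "-")
    ok <- apply(a, 2, function(col) length(unique(col)) == 1L) &
      apply(b, 2, function(col) length(unique(col)) == 1L)
    res_a <- a[1L, ]
    res_b <- b[1L, ]
    qual <- ok & res_a != res_b &
      res_a %in% AA_STANDARD & res_b %in% AA_STANDARD
    cols <- which(qual)
    if (length(cols) == 0L) return(NULL)
    classify_site_pair(
      block$gene[[1L]], ref_pos[cols], res_a[cols], res_b[cols], scheme
    ) |>
      mutate(column = cols, .after = "position")
  })
}

#' Find substitutions private to a focal taxon
#'
#' Within one group, finds alignment columns where the focal taxon differs
#' from a residue shared by ALL other members of its group (gaps and
#' non-standard residues disqualify a column). The `unique_class` flag
#' marks sites where the focal residue additionally falls in a different
#' chemical class than the rest of the group (singleton rule for C/G/P).
#'
#' @param alignments A tibble with columns `gene`, `taxon`, `sequence`.
#' @param partition A group tibble; the focal taxon defaults to
#'   [focal_taxon()] of the partition.
#' @param focal Focal taxon label (overrides the partition attribute).
#' @param group Group to compare within; defaults to the focal taxon's own
#'   group, which must have at least 2 other members.
#' @param scheme A scheme tibble.
#' @return A tibble with columns `gene`, `position`, `column`,
#'   `residue_group`, `residue_focal`, `class_group`, `class_focal`,
#'   `unique_class`, `special_involved`.
#' @export
focal_vs_group_sites <- function(alignments, partition, focal = NULL,
                                 group = NULL, scheme = property_scheme()) {
  focal <- focal %||% focal_taxon(partition)
  if (is.null(focal)) abort("no focal taxon set")
  if (!focal %in% partition$taxon) {
    abort(sprintf("focal taxon '%s' is not in the partition", focal))
  }
  group <- group %||% partition$group[partition$taxon == focal]
  others <- setdiff(partition$taxon[partition$group == group], focal)
  if (length(others) < 2L) {
    abort("the focal taxon's group must have at least 2 other members")
  }
  purrr::map_dfr(split(alignments, alignments$gene), function(block) {
    missing <- setdiff(c(focal, others), block$taxon)
    if (length(missing) > 0L) {
      abort(sprintf(
        "gene '%s': taxa missing from alignment: %s",
        block$gene[[1L]], paste(missing, collapse = ", ")
      ))
    }
    m <- alignment_matrix(block)
    rest <- m[others, , drop = FALSE]
    foc <- m[focal, ]
    ref_pos <- cumsum(foc != "-")
    ok <- apply(rest, 2, function(col) length(unique(col)) == 1L)
    res_rest <- rest[1L, ]
    qual <- ok & res_rest != foc &
      res_rest %in% AA_STANDARD & foc %in% AA_STANDARD
    cols <- which(qual)
    if (length(cols) == 0L) return(NULL)
    tibble(
      gene = block$gene[[1L]],
      position = ref_pos[cols],
      column = cols,
      residue_group = res_rest[cols],
      residue_focal = foc[cols],
      class_group = classify_residue(res_rest[cols], scheme),
      class_focal = classify_residue(foc[cols], scheme),
      unique_class = cross_class(res_rest[cols], foc[cols], scheme),
      special_involved = res_rest[cols] %in% c("C", "G", "P") |
        foc[cols] %in% c("C", "G", "P")
    )
  })
}

#' Summarize substitution sites
#'
#' Per-gene site counts, the cross-class subtotal, the gene(s) carrying the
#' most sites, and per-residue tallies for the special-case residues
#' (C, G, P), each site counted once per special residue it involves.
#' Works on detector output ([find_group_conserved_sites()],
#' [focal_vs_group_sites()]) and on transcribed site tables such as
#' [vulture_group_sites()]; when the input lacks class columns they are
#' recomputed from the residue pair under `scheme`.
#'
#' @param sites A site tibble with columns `gene` and a residue pair
#'   (`residue_a`/`residue_b` or `residue_group`/`residue_focal`).
#' @param scheme A scheme tibble.
#' @return An object of class `subst_summary`: list with `by_gene`
#'   (`gene`, `n_sites`, `n_cross_class`), `special_residues` (`residue`,
#'   `n_sites`), `total`, `total_cross_class`, `max_genes` (character
#'   vector, ties reported together). [generics::tidy()] returns
#'   `by_gene`; [generics::glance()] a one-row overview.
#' @export
summarize_sites <- function(sites, scheme = property_scheme()) {
  if (nrow(sites) == 0L) {
    out <- list(
      by_gene = tibble(gene = character(), n_sites = integer(),
                       n_cross_class = integer()),
      special_residues = tibble(residue = c("C", "G", "P"), n_sites = 0L),
      total = 0L, total_cross_class = 0L, max_genes = character()
    )
    class(out) <- "subst_summary"
    return(out)
  }
  ra <- sites$residue_a %||% sites$residue_group
  rb <- sites$residue_b %||% sites$residue_focal
  xc <- cross_class(ra, rb, scheme)
  by_gene <- tibble(gene = sites$gene, xc = xc) |>
    group_by(.data$gene) |>
    summarise(n_sites = n(), n_cross_class = sum(.data$xc)) |>
    arrange(.data$gene)
  special <- purrr::map_int(
    c(C = "C", G = "G", P = "P"),
    function(r) sum(ra == r | rb == r)
  )
  out <- list(
    by_gene = by_gene,
    special_residues = tibble(
      residue = names(special), n_sites = as.integer(special)
    ),
    total = nrow(sites),
    total_cross_class = sum(xc),
    max_genes = by_gene$gene[by_gene$n_sites == max(by_gene$n_sites)]
  )
  class(out) <- "subst_summary"
  out
}

#' @export
print.subst_summary <- function(x, ...) {
  cat(sprintf(
    "%d substitution site(s); %d between different chemical classes\n",
    x$total, x$total_cross_class
  ))
  if (length(x$max_genes) > 0L) {
    top <- x$by_gene$n_sites[x$by_gene$gene %in% x$max_genes][1L]
    cat(sprintf(
      "  most sites: %s (%d)\n", paste(x$max_genes, collapse = ", "), top
    ))
  }
  sp <- x$special_residues
  cat(sprintf(
    "  special-case involvement: C %d, G %d, P %d\n",
    sp$n_sites[sp$residue == "C"], sp$n_sites[sp$residue == "G"],
    sp$n_sites[sp$residue == "P"]
  ))
  invisible(x)
}

#' @method tidy subst_summary
#' @export
tidy.subst_summary <- function(x, ...) x$by_gene

#' @method glance subst_summary
#' @export
glance.subst_summary <- function(x, ...) {
  tibble(
    total = x$total,
    total_cross_class = x$total_cross_class,
    n_genes = nrow(x$by_gene),
    max_gene = paste(x$max_genes, collapse = ","),
    max_gene_sites = if (nrow(x$by_gene) == 0L) 0L else max(x$by_gene$n_sites)
  )
}
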