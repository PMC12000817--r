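make_partition <- function(n_a = 5, n_b = 6, labels = c("OWV", "NWV"),
                           focal = NULL) {
  part <- tibble::tibble(
    taxon = c(paste0("owv", seq_len(n_a)), paste0("nwv", seq_len(n_b))),
    group = rep(labels, c(n_a, n_b))
  )
  attr(part, "focal") <- focal
  part
}

column_alignment <- function(cols, gene = "g1") {
  # cols: list of per-column character vectors, one residue per taxon
  m <- do.call(cbind, cols)
  tibble::tibble(
    gene = gene,
    taxon = c(paste0("owv", 1:5), paste0("nwv", 1:6)),
    sequence = apply(m, 1, paste, collapse = "")
  )
}

test_that("residues classify into the five side-chain classes", {
  expect_equal(classify_residue("H"), "Positive")
  expect_equal(classify_residue("Y"), "Hydrophobic")
  expect_equal(classify_residue("Q"), "Polar uncharged")
  expect_equal(classify_residue(c("D", "E")), rep("Negative", 2))
  expect_equal(classify_residue(c("C", "G", "P")), rep("Special case", 3))
  expect_error(classify_residue("B"))
  scheme <- property_scheme()
  expect_equal(nrow(scheme), 20L)
  expect_equal(sort(unique(scheme$class)), c(
    "Hydrophobic", "Negative", "Polar uncharged", "Positive", "Special case"
  ))
})

test_that("special-case residues are singleton classes for cross-class calls", {
  expect_true(cross_class("C", "G")) # both 'Special case', still a change
  expect_true(cross_class("A", "N"))
  expect_false(cross_class("S", "T"))
  expect_false(cross_class("A", "V"))
  expect_true(cross_class("P", "S"))
})

test_that("group-conserved columns are detected and classified", {
  cols <- list(
    c(rep("A", 5), rep("N", 6)), # site: A vs N
    c("A", "A", "V", "A", "A", rep("N", 6)), # group A polymorphic: no site
    c(rep("M", 5), rep("M", 6)), # identical: no site
    c(rep("-", 5), rep("T", 6)), # gaps disqualify
    c(rep("C", 5), rep("G", 6)) # special vs special
  )
  sites <- find_group_conserved_sites(
    column_alignment(cols), make_partition()
  )
  expect_equal(nrow(sites), 2L)
  expect_equal(sites$residue_a, c("A", "C"))
  expect_equal(sites$residue_b, c("N", "G"))
  expect_equal(sites$class_a, c("Hydrophobic", "Special case"))
  expect_equal(sites$class_b, c("Polar uncharged", "Special case"))
  expect_true(all(sites$cross_class))
  expect_equal(sites$column, c(1L, 5L))
})

test_that("site positions use ungapped numbering on the first group-A taxon", {
  aln <- tibble::tibble(
    gene = "g1",
    taxon = c("owv1", "owv2", "nwv1", "nwv2"),
    sequence = c("-MAKV", "-MAKV", "-MANV", "-MANV")
  )
  part <- tibble::tibble(
    taxon = c("owv1", "owv2", "nwv1", "nwv2"),
    group = c("OWV", "OWV", "NWV", "NWV")
  )
  sites <- find_group_conserved_sites(aln, part)
  expect_equal(sites$column, 4L)
  expect_equal(sites$position, 3L) # leading gap shifts numbering
})

test_that("swapping the groups mirrors residues but preserves the site set", {
  set.seed(19)
  part <- make_partition(n_a = 2, n_b = 2)
  found_any <- FALSE
  for (rep in 1:5) {
    aln <- random_protein_alignment(4, 60, alphabet = c("A", "N", "P", "-"))
    aln$taxon <- part$taxon
    ab <- find_group_conserved_sites(aln, part, "OWV", "NWV")
    ba <- find_group_conserved_sites(aln, part, "NWV", "OWV")
    expect_equal(nrow(ab), nrow(ba))
    if (nrow(ab) == 0) next
    found_any <- TRUE
    expect_equal(ab$column, ba$column)
    expect_equal(ab$residue_a, ba$residue_b)
    expect_equal(ab$residue_b, ba$residue_a)
    expect_equal(ab$class_a, ba$class_b)
    expect_equal(ab$cross_class, ba$cross_class)
  }
  expect_true(found_any)
})

test_that("the detector equals a per-column oracle on random alignments", {
  set.seed(67)
  part <- make_partition(n_a = 2, n_b = 3)
  n_sites <- 0L
  for (i in 1:20) {
    aln <- random_protein_alignment(
      5, 40, alphabet = c("A", "N", "P", "-", "X")
    )
    aln$taxon <- part$taxon
    got <- find_group_conserved_sites(aln, part)
    want <- oracle_group_sites(aln, part, "OWV", "NWV")
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      n_sites <- n_sites + nrow(got)
      expect_equal(got$column, want$column)
      expect_equal(got$residue_a, want$residue_a)
      expect_equal(got$residue_b, want$residue_b)
    }
  }
  expect_gt(n_sites, 0L) # the comparison must not be vacuous
})

test_that("focal-private substitutions are detected with the unique-class flag", {
  cols <- list(
    c("P", rep("S", 4), rep("S", 6)), # focal P vs others S
    c("A", rep("A", 4), rep("A", 6)), # identical: no site
    c("T", "S", "S", "S", "N", rep("S", 6)) # rest polymorphic: no site
  )
  aln <- column_alignment(cols)
  part <- make_partition(focal = "owv1")
  sites <- focal_vs_group_sites(aln, part)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$residue_group, "S")
  expect_equal(sites$residue_focal, "P")
  expect_true(sites$unique_class)
  expect_error(
    focal_vs_group_sites(aln, make_partition(focal = NULL)),
    "focal"
  )
})

test_that("the published Gypini/Cathartidae site list summarizes correctly", {
  sites <- vulture_group_sites()
  summ <- summarize_sites(sites)
  expect_equal(summ$total, 67L)
  expect_equal(summ$max_genes, "ND1")
  expect_equal(summ$by_gene$n_sites[summ$by_gene$gene == "ND1"], 11L)
  sp <- setNames(summ$special_residues$n_sites, summ$special_residues$residue)
  expect_equal(sp[["P"]], 7L)
  expect_equal(sp[["C"]], 5L)
})

test_that("an empty site list gives an all-zero summary", {
  summ <- summarize_sites(vulture_group_sites()[0, ])
  expect_equal(summ$total, 0L)
  expect_equal(summ$total_cross_class, 0L)
  expect_equal(summ$max_genes, character())
  expect_equal(sum(summ$special_residues$n_sites), 0L)
})
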