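test_that("the generated mitogenome realizes the packaged layout", {
  sim <- generate_mitogenome(seed = 101)
  expect_equal(sim$genome$length, 17750L)
  g <- glance(genome_profile(sim$features, sim$genome))
  expect_equal(c(g$n_cds, g$n_trna), c(13L, 22L))
  expect_equal(g$pcg_total_bp, 11407L)
})

test_that("the same seed reproduces the genome byte for byte", {
  a <- generate_mitogenome(seed = 55)
  b <- generate_mitogenome(seed = 55)
  expect_identical(a$genome$sequence, b$genome$sequence)
  c <- generate_mitogenome(seed = 56)
  expect_false(identical(a$genome$sequence, c$genome$sequence))

  fa <- withr::local_tempfile()
  fb <- withr::local_tempfile()
  write_fasta(a$genome, fa)
  write_fasta(b$genome, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("non-coding composition tracks the AT target", {
  sim <- generate_mitogenome(at_percent = 50, seed = 9)
  at <- composition(sim$genome)$at_percent
  expect_lt(abs(at - 50), 2)
})

test_that("codon tallies in the truth match the counting pipeline", {
  sim <- generate_mitogenome(seed = 77)
  counted <- count_codons(extract_cds(sim$genome, sim$features))
  expect_equal(counted$count, sim$truth$codon_counts$count)
  expect_equal(counted$codon, sim$truth$codon_counts$codon)
})

test_that("generated CDS translate back to clean proteins", {
  sim <- generate_mitogenome(seed = 31)
  cds <- extract_cds(sim$genome, sim$features)
  # ND6 is the only plus-strand CDS and overlaps nothing downstream
  nd6 <- translate_cds(cds[cds$name == "ND6", ])
  expect_equal(length(nd6$internal_stops[[1]]), 0L)
  expect_true(nd6$starts_with_start_codon)
  expect_equal(nd6$terminal_stop, "TAG") # declared in the layout
})

test_that("opposite-strand CDS overlaps are rejected as infeasible", {
  layout <- dplyr::bind_rows(
    normalize_feature(1, 300, "+", "CDS"),
    normalize_feature(250, 549, "-", "CDS")
  )
  layout$name <- c("f1", "f2")
  layout$declared_start_codon <- "ATG"
  layout$declared_stop_codon <- "TAA"
  expect_error(
    generate_mitogenome(layout, seed = 1),
    class = "mitovult_format_error"
  )
})

test_that("planted microsatellites are recovered exactly once each", {
  set.seed(202)
  for (seed in 1:10) {
    base <- generate_mitogenome(seed = seed)
    plants <- tibble::tibble(
      motif = c("AC", "AGC", "A", "ACGT"),
      repeats = c(6L, 4L, 7L, 3L),
      position = c(2000L, 5000L, 9000L, 14000L)
    )
    planted <- plant_ssrs(base$genome, plants)
    hits <- find_ssrs(planted$genome)
    for (k in seq_len(nrow(planted$truth$ssrs))) {
      p <- planted$truth$ssrs[k, ]
      covering <- hits[hits$start <= p$start & hits$end >= p$end &
                         hits$motif_length == p$motif_length, ]
      expect_equal(nrow(covering), 1L)
      expect_gte(covering$repeats, p$repeats)
    }
  }
})

test_that("plants below threshold stay invisible and overlaps are rejected", {
  genome <- tibble::tibble(
    identifier = "flat", sequence = strrep("ACGTGTCAGT", 50), length = 500L
  )
  low <- plant_ssrs(genome, tibble::tibble(
    motif = "ACGTA", repeats = 2L, position = 100L
  ))
  hits <- find_ssrs(low$genome, ssr_thresholds()) # penta threshold 3
  expect_false(any(hits$motif_length == 5 & hits$start == 100))
  expect_error(
    plant_ssrs(genome, tibble::tibble(
      motif = c("AC", "CA"), repeats = c(5L, 5L), position = c(100L, 105L)
    )),
    "overlap"
  )
})

test_that("constraint-mode clades return exactly the planted sites", {
  planted <- tibble::tibble(
    gene = "g1", column = c(4L, 10L, 17L, 23L, 30L, 38L, 44L, 51L, 60L, 70L),
    residue_a = c("A", "P", "C", "T", "H", "M", "S", "G", "Q", "W"),
    residue_b = c("N", "S", "Y", "K", "Y", "T", "F", "A", "E", "R")
  )
  for (seed in 1:5) {
    sim <- generate_clade_alignments(
      gene_lengths = c(g1 = 80L), planted_sites = planted,
      noise_rate = 0.08, constrain = TRUE, seed = seed
    )
    sites <- find_group_conserved_sites(sim$alignments, sim$partition)
    expect_equal(sites$column, planted$column)
    expect_equal(sites$residue_a, planted$residue_a)
    expect_equal(sites$residue_b, planted$residue_b)
  }
})

test_that("zero planting and zero noise give zero sites", {
  sim <- generate_clade_alignments(gene_lengths = c(g1 = 50L), seed = 4)
  expect_equal(
    nrow(find_group_conserved_sites(sim$alignments, sim$partition)), 0L
  )
})

test_that("focal-private plants are recovered exactly", {
  focal_sites <- tibble::tibble(
    gene = c("g1", "g1", "g2"), column = c(5L, 20L, 9L),
    residue_focal = c("P", "G", "W")
  )
  sim <- generate_clade_alignments(
    gene_lengths = c(g1 = 40L, g2 = 30L), focal_sites = focal_sites,
    noise_rate = 0.05, constrain = TRUE, seed = 12
  )
  expect_equal(focal_taxon(sim$partition), "OWV_1")
  got <- focal_vs_group_sites(sim$alignments, sim$partition)
  expect_equal(got$gene, focal_sites$gene)
  expect_equal(got$column, focal_sites$column)
  expect_equal(got$residue_focal, focal_sites$residue_focal)
})

test_that("planted divergence yields the exact expected cross-group distance", {
  sim <- generate_clade_alignments(
    gene_lengths = c(a = 100L, b = 200L), divergence = 0.05, seed = 8
  )
  d <- distance_matrix(sim$alignments)
  grp <- setNames(sim$partition$group, sim$partition$taxon)
  cross <- d[grp[d$taxon_a] != grp[d$taxon_b], ]
  within <- d[grp[d$taxon_a] == grp[d$taxon_b], ]
  expect_true(all(cross$distance == 5))
  expect_true(all(within$distance == 0))
})
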