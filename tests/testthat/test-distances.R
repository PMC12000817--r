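test_that("p-distance applies pairwise deletion", {
  expect_equal(p_distance("AAAA", "AAAA")$distance, 0)
  d <- p_distance("AAAA", "AAAT")
  expect_equal(d$distance, 25)
  expect_equal(d$used_sites, 4L)
  d2 <- p_distance("A-CG", "AACG")
  expect_equal(d2$distance, 0)
  expect_equal(d2$used_sites, 3L)
  expect_error(p_distance("--", "AA"))
  expect_error(p_distance("AAA", "AA"), "length")
})

test_that("p-distance agrees with ape's raw pairwise-deletion distance", {
  skip_if_not_installed("ape")
  set.seed(13)
  alphabet <- c("a", "c", "g", "t", "-")
  seqs <- replicate(4, paste(sample(alphabet, 120, replace = TRUE,
                                    prob = c(rep(0.22, 4), 0.12)),
                             collapse = ""))
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- paste0("t", 1:4)
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(mat), model = "raw",
                                 pairwise.deletion = TRUE)) * 100
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(
        p_distance(seqs[i], seqs[j])$distance, ref[i, j],
        tolerance = 1e-9
      )
    }
  }
})

test_that("distance matrices are symmetric with zero diagonal and bounded", {
  set.seed(29)
  aln <- random_protein_alignment(5, 80, alphabet = c("A", "N", "S", "-"))
  d <- distance_matrix(aln)
  m <- dist_to_matrix(d)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 5))
  expect_true(all(d$distance >= 0 & d$distance <= 100))
})

test_that("identical taxa are at distance zero everywhere", {
  aln <- tibble::tibble(
    gene = rep(c("g1", "g2"), each = 3),
    taxon = rep(c("a", "b", "twin_of_a"), 2),
    sequence = c("MKVA", "MRVA", "MKVA", "PPST", "PPSA", "PPST")
  )
  d <- distance_matrix(aln)
  pair <- d[d$taxon_a == "a" & d$taxon_b == "twin_of_a", ]
  expect_equal(pair$distance, 0)
})

test_that("concatenated distance is the used-site-weighted mean of per-gene ones", {
  set.seed(41)
  aln <- dplyr::bind_rows(
    random_protein_alignment(4, 60, gene = "g1",
                             alphabet = c("A", "N", "S", "T", "-")),
    random_protein_alignment(4, 90, gene = "g2",
                             alphabet = c("A", "N", "S", "T", "-"))
  )
  per_gene <- distance_matrix(aln, concatenate = FALSE)
  concat <- distance_matrix(aln, concatenate = TRUE)
  for (k in seq_len(nrow(concat))) {
    rows <- per_gene[
      per_gene$taxon_a == concat$taxon_a[k] &
        per_gene$taxon_b == concat$taxon_b[k],
    ]
    weighted <- sum(rows$distance * rows$used_sites) / sum(rows$used_sites)
    expect_lt(abs(concat$distance[k] - weighted), 0.011)
    expect_equal(concat$used_sites[k], sum(rows$used_sites))
  }
})

test_that("concatenation requires a shared taxon set", {
  aln <- tibble::tibble(
    gene = c("g1", "g1", "g2", "g2"),
    taxon = c("a", "b", "a", "c"),
    sequence = c("MK", "MR", "PP", "PS")
  )
  expect_error(distance_matrix(aln), "taxon set")
})

test_that("poisson correction and complete deletion behave as documented", {
  aln <- tibble::tibble(
    gene = "g1",
    taxon = c("a", "b"),
    sequence = c("AAAA-AAAAA", "AAAT-TAAAA")
  )
  p <- distance_matrix(aln)
  expect_equal(p$distance, round(100 * 2 / 9, 2))
  pois <- distance_matrix(aln, method = "poisson")
  expect_equal(pois$distance, round(-log(1 - 2 / 9) * 100, 2))
  comp <- distance_matrix(aln, deletion = "complete")
  expect_equal(comp$used_sites, 9L)
})

test_that("group summaries report focal-versus-group ranges", {
  aln <- tibble::tibble(
    gene = "g1",
    taxon = c("focal", "g1a", "g1b", "h1a", "h1b"),
    sequence = c("AAAAAAAAAA", "AAAAAAAAAT", "AAAAAAAATT",
                 "AAAAATTTTT", "AAAATTTTTT")
  )
  part <- tibble::tibble(
    taxon = aln$taxon,
    group = c("G", "G", "G", "H", "H")
  )
  summ <- dist_group_summary(distance_matrix(aln), part, focal = "focal")
  g <- summ[summ$group == "G", ]
  h <- summ[summ$group == "H", ]
  expect_equal(c(g$min, g$max), c(10, 20))
  expect_equal(c(h$min, h$max), c(50, 60))
  expect_equal(g$n_pairs, 2L)
})
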