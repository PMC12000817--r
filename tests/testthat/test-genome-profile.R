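test_that("normalize_feature orients coordinates and computes lengths", {
  cases <- list(
    list(4076, 2934, "-", 2934L, 4076L, 1143L),
    list(5903, 4089, "-", 4089L, 5903L, 1815L),
    list(7, 7, "+", 7L, 7L, 1L)
  )
  for (k in cases) {
    f <- normalize_feature(k[[1]], k[[2]], k[[3]])
    expect_equal(f$start, k[[4]])
    expect_equal(f$end, k[[5]])
    expect_equal(f$length, k[[6]])
  }
  expect_error(normalize_feature(0, 10, "+"))
})

test_that("the packaged gene table validates cleanly except the COX3 triplet flag", {
  tab <- vulture_features()
  findings <- validate_feature_table(tab)
  expect_equal(sum(findings$kind == "length_mismatch"), 0L)
  not3 <- findings[findings$kind == "cds_length_not_triplet", ]
  expect_equal(not3$feature, "COX3")
  expect_match(not3$message, "784")
  # every declared length equals end - start + 1 across all 39 rows
  expect_true(all(tab$declared_length == tab$end - tab$start + 1L))
})

test_that("validate_feature_table reports declared/computed disagreements", {
  f <- withr::local_tempfile(
    lines = "1\t99\t100\t+\tCDS\tg\t-\t-\tATG\tTAA"
  )
  findings <- validate_feature_table(read_feature_table(f))
  expect_equal(sum(findings$kind == "length_mismatch"), 1L)
})

test_that("genome length comes from the sequence when present, else the table", {
  tab <- vulture_features()
  expect_equal(genome_length_of(tab), 17750L)
  one <- normalize_feature(1, 10, "+")
  expect_equal(genome_length_of(one), 10L)
  genome <- tibble::tibble(identifier = "g", sequence = strrep("A", 100))
  short <- normalize_feature(1, 60, "+")
  expect_equal(genome_length_of(short, genome), 100L)
})

test_that("composition reports AT/GC over non-N positions, half-up to 1 dp", {
  expect_equal(composition("ATAT")$at_percent, 100)
  expect_equal(composition("ATAT")$gc_percent, 0)
  expect_equal(composition("ACGT")$at_percent, 50)
  # N excluded from the denominator: 2 AT / 3 used
  cN <- composition("ATGN")
  expect_equal(cN$at_percent, 66.7)
  expect_equal(cN$n_excluded, 1L)
  expect_error(composition("NNNN"))
})

test_that("AT fraction is strand-invariant", {
  set.seed(7)
  for (i in 1:10) {
    s <- random_dna(101)
    expect_equal(
      composition(s)$at_percent,
      composition(mitovult:::revcomp(s))$at_percent
    )
  }
})

test_that("protein-coding span is the plain sum of CDS lengths", {
  tab <- vulture_features()
  span <- pcg_span_stats(tab, 17750)
  expect_equal(span$pcg_total_bp, 11407L)
  expect_equal(span$pcg_fraction, 64.26)

  two <- dplyr::bind_rows(
    normalize_feature(1, 150, "+", "CDS"),
    normalize_feature(201, 350, "+", "CDS")
  )
  two$name <- c("a", "b")
  span2 <- pcg_span_stats(two, 600)
  expect_equal(span2$pcg_total_bp, 300L)
  expect_equal(span2$pcg_fraction, 50)
  expect_error(pcg_span_stats(two[0, ], 600))
})

test_that("extract_cds orients strands and flags incomplete stops", {
  feats <- dplyr::bind_rows(
    normalize_feature(1, 9, "+", "CDS"),
    normalize_feature(11, 19, "-", "CDS"),
    normalize_feature(21, 24, "+", "CDS")
  )
  feats$name <- c("plus", "minus", "partial")
  # pos 1-9 plus CDS, 11-19 minus CDS, 21-24 partial CDS
  genome <- "ATGAAATAACCTAGGGCACGATGT"
  out <- extract_cds(genome, feats)
  expect_equal(out$observed_start_codon[[1]], "ATG")
  expect_equal(out$observed_stop_codon[[1]], "TAA")
  expect_true(out$stop_complete[[1]])
  # minus strand: revcomp of CTAGGGCAC = GTGCCCTAG
  expect_equal(out$cds[[2]], "GTGCCCTAG")
  expect_equal(out$observed_start_codon[[2]], "GTG")
  # 4 nt: one trailing nt, incomplete stop
  expect_false(out$stop_complete[[3]])
  expect_equal(nchar(out$observed_stop_codon[[3]]), 1L)

  oob <- normalize_feature(20, 30, "+", "CDS")
  oob$name <- "oob"
  expect_error(extract_cds(genome, oob), "bounds")
})

test_that("translation follows the vertebrate mitochondrial code", {
  tr <- translate_cds("ATGTGAAGA")
  expect_equal(tr$protein, "MW") # TGA = Trp
  expect_equal(tr$terminal_stop, "AGA") # AGA = stop in the mito code
  expect_equal(translate_cds("ATAGCC")$protein, "MA") # ATA = Met
  # the standard code reads TGA as an internal stop and AGA as Arg
  std <- translate_cds("ATGTGAAGA", code = genetic_code("standard"))
  expect_equal(std$protein, "M*R")
  expect_true(is.na(std$terminal_stop))
  expect_equal(std$internal_stops[[1]], 2L)
  expect_error(translate_cds("AT"))
})

test_that("translation flags internal stops and partial tails", {
  tr <- translate_cds("ATGTAAATGC")
  expect_equal(tr$protein, "M*M")
  expect_equal(tr$internal_stops[[1]], 2L)
  expect_true(tr$incomplete_tail)
})

test_that("genome_profile summarizes the packaged table end to end", {
  prof <- genome_profile(vulture_features())
  g <- glance(prof)
  expect_equal(g$genome_length, 17750L)
  expect_equal(
    c(g$n_cds, g$n_trna, g$n_rrna, g$n_control_region),
    c(13L, 22L, 2L, 2L)
  )
  expect_equal(g$pcg_fraction, 64.26)
  expect_equal(nrow(tidy(prof)), 39L)
})
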