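test_that("longest perfect match equals the brute-force oracle", {
  x <- random_acgt(40)
  expect_identical(longest_perfect_match(x, x), list(len = 40L, a_off = 0L, b_off = 0L))
  got <- longest_perfect_match("ABAB", "BABA")
  expect_identical(got, oracle_lcs("ABAB", "BABA"))
  expect_identical(got, list(len = 3L, a_off = 0L, b_off = 1L))
  set.seed(31)
  for (i in 1:10) {
    a <- random_acgt(200); b <- random_acgt(200)
    expect_identical(longest_perfect_match(a, b)$len, oracle_lcs(a, b)$len,
                     info = paste("rep", i))
  }
})

test_that("extra-sequence self-homology recovers planted copies exactly", {
  # default: 170-nt 5'-extra copied from the (-) strand with 3-nt overlap
  sim <- generate_genome(genome_blueprint(seed = 12L))
  h5 <- map_extra_to_canonical(sim$genome, "FIVE_EXTRA")
  expect_gte(nrow(h5), 1L)
  top <- h5[1, ]
  expect_identical(top$target_strand, "minus")
  expect_identical(c(top$target_start, top$target_end), c(31L, 203L))
  expect_identical(top$length, 173L)
  expect_equal(top$identity, 100)
  expect_identical(top$query_start, format_signed(signed_position("FIVE_EXTRA", 170L), sim$genome))
  expect_identical(top$query_end, format_signed(signed_position("CANONICAL", 3L), sim$genome))
  h3 <- map_extra_to_canonical(sim$genome, "THREE_EXTRA")
  expect_identical(c(h3$target_start[1], h3$target_end[1]), c(4466L, 4493L))
  expect_identical(h3$target_strand[1], "plus")
  expect_identical(h3$length[1], 28L)
})

test_that("plus-strand 5' copies and unrelated extras behave as specified", {
  bp <- genome_blueprint(five_extra = extra_spec(143L, "plus", interval = c(65L, 159L)),
                         seed = 21L)
  sim <- generate_genome(bp)
  h5 <- map_extra_to_canonical(sim$genome, "FIVE_EXTRA")
  expect_identical(h5$target_strand[1], "plus")
  expect_identical(c(h5$target_start[1], h5$target_end[1]), c(65L, 159L))
  expect_identical(h5$length[1], 95L)
  # random extra: no hits at high identity / length
  bp2 <- genome_blueprint(five_extra = extra_spec(120L, "random"), seed = 22L)
  sim2 <- generate_genome(bp2)
  expect_identical(nrow(map_extra_to_canonical(sim2$genome, "FIVE_EXTRA")), 0L)
  # empty extra region signals the "None" rows
  bp3 <- genome_blueprint(five_extra = extra_spec(0L, "none"), seed = 23L)
  sim3 <- generate_genome(bp3)
  expect_error(map_extra_to_canonical(sim3$genome, "FIVE_EXTRA"),
               class = "totiscan_empty_region")
})

test_that("strand duality: a (-)hit mirrors the reverse-complemented query on (+)", {
  set.seed(41)
  canon <- random_acgt(800)
  q <- revcomp(substr(canon, 301, 420))
  h_minus <- find_local_matches(q, revcomp(canon), min_len = 50L)
  h_plus <- find_local_matches(revcomp(q), canon, min_len = 50L)
  expect_identical(nrow(h_minus), 1L)
  expect_identical(nrow(h_plus), 1L)
  n <- nchar(canon)
  expect_identical(n - h_minus$s_end[1] + 1L, h_plus$s_start[1])
  expect_identical(n - h_minus$s_start[1] + 1L, h_plus$s_end[1])
  expect_identical(h_plus$s_start[1], 301L)
})

test_that("rRNA-like decoys in the 3'-extra map to the reference, both strands", {
  bp <- genome_blueprint(three_extra = extra_spec(213L, "rrna_decoy", offset = 12L,
                                                  decoy_len = 201L, mutations = 1L),
                         seed = 31L)
  sim <- generate_genome(bp)
  reg <- extract_regions(sim$genome)
  hits <- map_to_reference(reg$three_extra, sim$decoy_reference[[1]],
                           min_len = 100L, min_identity = 99)
  expect_gte(nrow(hits), 1L)
  expect_identical(hits$ref_strand[1], "plus")
  expect_gte(hits$length[1], 199L)          # one substitution may split or shrink
  expect_gte(hits$identity[1], 99)
  # reverse-complemented decoy reports the (-) strand of the reference
  rc_hits <- map_to_reference(revcomp(reg$three_extra), sim$decoy_reference[[1]],
                              min_len = 100L, min_identity = 99)
  expect_identical(rc_hits$ref_strand[1], "minus")
  # genome without a decoy has no hit against the reference
  sim2 <- generate_genome(genome_blueprint(seed = 32L))
  none <- map_to_reference(extract_regions(sim2$genome)$three_extra,
                           sim$decoy_reference[[1]], min_len = 30L, min_identity = 95)
  expect_identical(nrow(none), 0L)
})

test_that("xenolog filtering applies inclusive thresholds with a strict mode", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_synthetic_blast_tab(path, seed = 5L)
  hits <- read_blast_tab(path)
  expect_identical(ncol(hits), 12L)
  kept <- filter_xenolog_hits(hits)
  # inclusive: the 93%/30-nt and 95%/37-nt rows stay; 79%/500 and 25-nt rows drop
  expect_true(all(kept$identity >= 80 & kept$length >= 30))
  expect_true("synthetic_mito_coxI" %in% kept$subject_id)
  expect_true("synthetic_contig_0228346" %in% kept$subject_id)
  expect_false("synthetic_low_id" %in% kept$subject_id)
  expect_false("synthetic_short" %in% kept$subject_id)
  strict <- filter_xenolog_hits(hits, strict = TRUE)
  expect_false("synthetic_mito_coxI" %in% strict$subject_id)  # 30 nt not above 30
  expect_true("synthetic_contig_0228346" %in% strict$subject_id)
  # subset of input and idempotent
  expect_true(all(kept$sseqid %in% hits$sseqid))
  expect_identical(filter_xenolog_hits(kept)[names(hits)], kept[names(hits)])
})

test_that("malformed tabular rows are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q\ts\t90\t50\t5\t0\t1\t50\t1\t50\t1e-10\t90",
               "q\ts\t90\t50"), path)
  expect_error(read_blast_tab(path), "line 2", class = "totiscan_malformed_row")
})
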