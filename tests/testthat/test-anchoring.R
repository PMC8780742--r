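td_motifs <- terminal_motif_set("GAAATT", "CCATAAGC", canonical_length_hint = 4565L)

test_that("5' anchor finds the conserved hexamer, with errors on absence", {
  m <- terminal_motif_set("GAATTT", "CTACGCG")
  expect_identical(find_five_prime_anchor("CCGAATTTAAA", m), 2L)
  expect_identical(find_five_prime_anchor("GAATTTCCCC", m), 0L)
  expect_error(find_five_prime_anchor("CCCCCCCCCC", m),
               class = "totiscan_motif_not_found")
  # ambiguity codes never match
  expect_error(find_five_prime_anchor("GANTTTCCCC", m),
               class = "totiscan_motif_not_found")
})

test_that("3' terminus resolves duplicates by proximity to the length hint", {
  set.seed(42)
  # terminus planted at canonical lengths hint-40 and hint+400 past a 5' motif
  hint <- 600L
  body <- random_seq(1200L, 0.5)
  body <- gsub("CTACGCG", "CTACGCA", body, fixed = TRUE)
  cv <- strsplit(body, "")[[1]]
  cv[1:6] <- strsplit("GAATTT", "")[[1]]
  plant <- function(cv, endpos) { cv[(endpos - 6):endpos] <- strsplit("CTACGCG", "")[[1]]; cv }
  cv <- plant(cv, hint - 40L)
  cv <- plant(cv, hint + 400L)
  seq <- paste(cv, collapse = "")
  m <- terminal_motif_set("GAATTT", "CTACGCG", canonical_length_hint = hint)
  got <- find_three_prime_terminus(seq, m, 0L, hint)
  # exhaustive check: chosen end is the argmin of |implied length - hint|
  ends <- c(hint - 40L, hint + 400L)
  expect_identical(got, ends[which.min(abs(ends - hint))])
  # equidistant occurrences are ambiguous
  cv2 <- strsplit(gsub("CTACGCG", "CTACGCA", body, fixed = TRUE), "")[[1]]
  cv2[1:6] <- strsplit("GAATTT", "")[[1]]
  cv2 <- plant(cv2, hint - 50L); cv2 <- plant(cv2, hint + 50L)
  expect_error(find_three_prime_terminus(paste(cv2, collapse = ""), m, 0L, hint),
               class = "totiscan_ambiguous_terminus")
  expect_error(find_three_prime_terminus("GAATTTAAAA", m, 0L, hint),
               class = "totiscan_motif_not_found")
})

test_that("region extraction partitions the contig and matches planted extras", {
  g0 <- viral_genome("t", "GAAATTACGTACGT", 0L, 14L)
  reg <- extract_regions(g0)
  expect_identical(reg, list(five_extra = "", canonical = "GAAATTACGTACGT",
                             three_extra = ""))
  bp <- genome_blueprint(five_extra = extra_spec(57L, "random"),
                         three_extra = extra_spec(91L, "random"), seed = 11L)
  sim <- generate_genome(bp)
  g <- anchor_genome(sim$genome$seq, td_motifs, id = "s")
  reg <- extract_regions(g)
  expect_identical(nchar(reg$five_extra), 57L)
  expect_identical(nchar(reg$three_extra), 91L)
  expect_identical(paste0(reg$five_extra, reg$canonical, reg$three_extra), g$seq)
})

test_that("partition conservation and anchoring idempotence hold across seeds", {
  for (s in 1:5) {
    sim <- generate_genome(genome_blueprint(seed = s))
    g <- anchor_genome(sim$genome$seq, td_motifs, id = "s")
    reg <- extract_regions(g)
    expect_identical(nchar(reg$five_extra) + nchar(reg$canonical) + nchar(reg$three_extra),
                     nchar(g$seq))
    expect_identical(nchar(reg$five_extra), sim$truth$five_extra_len)
    expect_identical(nchar(reg$three_extra), sim$truth$three_extra_len)
    g2 <- anchor_genome(reg$canonical, td_motifs, id = "re")
    expect_identical(g2$canonical_start, 0L)
    expect_identical(g2$canonical_end, nchar(reg$canonical))
  }
})

test_that("signed coordinates round-trip and hit the documented boundaries", {
  sim <- generate_genome(genome_blueprint(seed = 3L))
  g <- sim$genome
  expect_identical(signed_to_offset(signed_position("CANONICAL", 1L), g),
                   g$canonical_start)
  expect_identical(signed_to_offset(signed_position("FIVE_EXTRA", 1L), g),
                   g$canonical_start - 1L)
  expect_identical(signed_to_offset(signed_position("THREE_EXTRA", 1L), g),
                   g$canonical_end)
  set.seed(99)
  offs <- sample(0:(nchar(g$seq) - 1L), 10000L, replace = TRUE)
  rt <- vapply(offs, function(o) signed_to_offset(offset_to_signed(o, g), g), integer(1))
  expect_identical(rt, offs)
  expect_error(signed_position("CANONICAL", 0L), class = "totiscan_out_of_range")
  expect_error(signed_to_offset(signed_position("FIVE_EXTRA", g$canonical_start + 1L), g),
               class = "totiscan_out_of_range")
  # literature notation: canonical 5' G is position 1
  expect_match(format_signed(signed_position("CANONICAL", 1L), g), "^G1$")
  expect_match(format_signed(signed_position("FIVE_EXTRA", 170L), g), "\\(-\\)170$")
})

test_that("the GenBank flat-file reader recovers id and sequence", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       SYN00001                 24 bp ss-RNA     linear   VRL",
    "DEFINITION  synthetic record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..24",
    "ORIGIN",
    "        1 gaauttacgt acgtacgtac gtaa",
    "//"), path)
  got <- read_genbank(path)
  expect_identical(names(got), "SYN00001")
  expect_identical(got[["SYN00001"]], "GAATTTACGTACGTACGTACGTAA")
  expect_error(read_genbank(withr::local_tempfile(lines = "no records")),
               class = "totiscan_malformed_row")
})

test_that("region report mirrors the organization-table length columns", {
  sims <- lapply(1:2, function(s) generate_genome(genome_blueprint(seed = s)))
  gs <- lapply(sims, `[[`, "genome")
  rep <- region_report(gs)
  expect_identical(rep$sequenced_len, vapply(gs, function(g) nchar(g$seq), integer(1)))
  expect_identical(rep$canonical_len, rep(4565L, 2))
  expect_identical(rep$five_extra_len, rep(170L, 2))
  expect_identical(rep$three_extra_len, rep(28L, 2))
})
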