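test_that("generation is deterministic and blueprint conflicts are rejected", {
  a <- generate_genome(genome_blueprint(seed = 14L))
  b <- generate_genome(genome_blueprint(seed = 14L))
  expect_identical(a$genome$seq, b$genome$seq)
  c <- generate_genome(genome_blueprint(seed = 15L))
  expect_false(identical(a$genome$seq, c$genome$seq))
  expect_error(genome_blueprint(slippery_pos = 1999L),
               class = "totiscan_blueprint_conflict")   # not codon-aligned
  expect_error(genome_blueprint(reinit_pos = 2154L),
               class = "totiscan_blueprint_conflict")   # ATG out of Pol frame
  expect_error(genome_blueprint(gag_span = c(204L, 2128L)),
               class = "totiscan_blueprint_conflict")   # not a codon multiple
})

test_that("every planted feature is recovered end-to-end on a default blueprint", {
  sim <- generate_genome(genome_blueprint(seed = 16L))
  td <- terminal_motif_set("GAAATT", "CCATAAGC", canonical_length_hint = 4565L)
  g <- anchor_genome(sim$genome$seq, td, id = "e2e")
  expect_identical(g$canonical_start, sim$truth$five_extra_len)
  canon <- extract_regions(g)$canonical
  expect_identical(nchar(canon), sim$truth$canonical_len)
  orfs <- find_orfs(canon, min_aa = 500L)
  expect_true(any(orfs$start == sim$truth$gag$start & orfs$end == sim$truth$gag$end))
  slp <- find_slippery_sites(canon)
  expect_true(sim$truth$slippery_pos %in% slp$site_start)
  re <- find_reinitiation_sites(canon, sim$truth$gag$start + 1L,
                                sim$truth$pol_frame_anchor)
  hit <- re[re$site_start == sim$truth$reinit$site_start, ]
  expect_identical(hit$reinit_atg_start, sim$truth$reinit$atg_start)
  expect_true(hit$in_frame_with_pol)
  h5 <- map_extra_to_canonical(g, "FIVE_EXTRA")
  expect_identical(c(h5$target_start[1], h5$target_end[1]),
                   c(sim$truth$five_hit$target_start, sim$truth$five_hit$target_end))
})

test_that("an indel pair restores the frame and perturbs only its window", {
  s <- paste(sample(.totiscan_nonstop <- c("GCT", "CAT", "GAA", "TGG", "AAA"),
                    120, TRUE), collapse = "")
  out <- evolve_with_compensatory_indels(s, sub_rate = 0, n_indel_pairs = 1L,
                                         max_pair_distance = 60L, seed = 19L)
  tr <- out$trace
  expect_identical(replay_trace(s, tr), out$derived)
  sizes <- vapply(tr$events, function(e)
    switch(e$type, ins = nchar(e$payload), del = -e$payload, 0L), numeric(1))
  expect_identical(sum(sizes) %% 3, 0)
  expect_identical(nchar(out$derived) - nchar(s), as.integer(sum(sizes)))
  w <- tr$windows[[1]]
  # outside the compensated window the sequence (and frame) is untouched
  expect_identical(substr(out$derived, 1, w[1] - 1), substr(s, 1, w[1] - 1))
  expect_identical(substr(out$derived, w[2] + 1, nchar(out$derived)),
                   substr(s, w[2] + 1, nchar(s)))
  expect_identical(translate_cdna(substr(out$derived, w[2] + 1, nchar(out$derived))),
                   translate_cdna(substr(s, w[2] + 1, nchar(s))))
  # trivial parameters are the identity
  none <- evolve_with_compensatory_indels(s, 0, 0L, seed = 20L)
  expect_identical(none$derived, s)
  expect_error(evolve_with_compensatory_indels("ACGTA", seed = 1L),
               class = "totiscan_parameter_error")
})

test_that("compensated windows lower amino-acid identity more than nucleotide identity", {
  set.seed(77)
  anc <- paste(sample(setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                                c("A","C","G","T")), 1, paste, collapse = ""),
                              c("TAA", "TAG", "TGA")), 700, TRUE), collapse = "")
  wins <- 0L
  for (s in 1:20) {
    out <- evolve_with_compensatory_indels(anc, sub_rate = 0.02, n_indel_pairs = 2L,
                                           max_pair_distance = 100L, seed = s)
    cmp <- compare_compensated_windows(anc, out$derived, out$trace)
    if (mean(cmp$aa_identity) < mean(cmp$nt_identity)) wins <- wins + 1L
  }
  expect_gte(wins, 17L)
})

test_that("rRNA decoys are reproducible and sized as requested", {
  d1 <- make_rrna_decoy(201L, seed = 4L)
  d2 <- make_rrna_decoy(201L, seed = 4L)
  expect_identical(d1$seq, d2$seq)
  expect_identical(nchar(d1$seq), 201L)
  expect_identical(d1$record$id, "synthetic_18S_rRNA_decoy")
  expect_error(make_rrna_decoy(10L, seed = 1L))
})

test_that("LIS comparator scrambles only the requested blocks", {
  set.seed(88)
  a <- random_acgt(600)
  b <- make_lis_comparator(a, list(c(101L, 200L)), seed = 6L)
  expect_identical(substr(a, 1, 100), substr(b, 1, 100))
  expect_identical(substr(a, 201, 600), substr(b, 201, 600))
  inside_match <- mean(strsplit(substr(a, 101, 200), "")[[1]] ==
                         strsplit(substr(b, 101, 200), "")[[1]])
  expect_lt(inside_match, 0.5)
})
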