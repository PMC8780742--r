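test_that("pair-maximal folding matches enumeration on small sequences", {
  expect_identical(nrow(fold("AAAAAA")$pairs), 0L)
  expect_identical(fold("AAAAAA")$score, 0)
  st <- fold("GGGGAAAACCCC")
  expect_identical(nrow(st$pairs), 4L)
  expect_identical(oracle_max_pairs("GGGGAAAACCCC"), 4L)
  # the unique maximum is the planted 4-pair stem with a 4-nt loop
  expect_identical(st$pairs[order(st$pairs[, 1]), ],
                   cbind(i = 1:4, j = 12:9))
  for (s in all_strings(c("A", "C", "G", "T"), 5)) {
    if (nchar(s) < 5) next
    expect_identical(nrow(fold(s)$pairs), oracle_max_pairs(s), info = s)
  }
  set.seed(61)
  for (i in 1:150) {
    s <- random_acgt(sample(5:12, 1))
    expect_identical(nrow(fold(s)$pairs), oracle_max_pairs(s), info = s)
  }
})

test_that("folds are nested, deterministic and U/T-spelling invariant", {
  set.seed(62)
  for (i in 1:20) {
    s <- random_acgt(sample(20:60, 1))
    st <- fold(s)
    p <- st$pairs
    if (nrow(p) > 1) for (r1 in 1:(nrow(p) - 1)) for (r2 in (r1 + 1):nrow(p)) {
      i1 <- p[r1, 1]; j1 <- p[r1, 2]; i2 <- p[r2, 1]; j2 <- p[r2, 2]
      expect_false(i1 < i2 && i2 < j1 && j1 < j2)  # no pseudoknots
    }
    # paired bases complementary under the RNA view (GU allowed)
    bases <- strsplit(st$seq, "")[[1]]
    combs <- paste0(bases[p[, 1]], bases[p[, 2]])
    expect_true(all(combs %in% c("AT", "TA", "GC", "CG", "GT", "TG")))
    expect_true(all(p[, 2] - p[, 1] >= 4))         # min_loop 3
    expect_identical(fold(chartr("T", "U", s))$pairs, st$pairs)
  }
})

test_that("hairpin extraction reports stems and contiguous loops", {
  expect_identical(find_hairpins(fold("AAAAAAAA")), list())
  # perfect inverted repeat: 10-pair stem, single 5-nt loop
  st <- fold(paste0(strrep("G", 10), strrep("A", 5), strrep("C", 10)))
  hp <- find_hairpins(st)
  expect_identical(length(hp), 1L)
  expect_identical(hp[[1]]$outer, c(1L, 25L))
  expect_identical(nrow(hp[[1]]$stem_pairs), 10L)
  expect_identical(length(hp[[1]]$loops), 1L)
  expect_identical(hp[[1]]$loops[[1]], 11:15)
  # bulged stem: two contiguous loops
  stb <- fold(paste0(strrep("G", 8), strrep("A", 4), strrep("C", 4),
                     strrep("A", 2), strrep("C", 4)))
  hpb <- find_hairpins(stb)
  expect_identical(length(hpb), 1L)
  expect_identical(nrow(hpb[[1]]$stem_pairs), 8L)
  expect_identical(length(hpb[[1]]$loops), 2L)
  expect_lt(hpb[[1]]$score, 0)
  # min_stem filters short stems out
  expect_identical(find_hairpins(fold("GGAAAACC"), min_stem = 3L), list())
})

test_that("planted generator hairpins are recovered exactly from their interval", {
  sim <- generate_genome(genome_blueprint(seed = 8L))
  canon <- extract_regions(sim$genome)$canonical
  for (h in sim$truth$hairpins) {
    st <- fold(substr(canon, h$at, h$at + h$span - 1L))
    expect_identical(nrow(st$pairs), h$stem)
    expect_identical(st$pairs[order(st$pairs[, 1]), , drop = FALSE],
                     h$local_pairs[order(h$local_pairs[, 1]), , drop = FALSE])
    hp <- find_hairpins(st)
    expect_identical(length(hp), 1L)
    expect_identical(length(hp[[1]]$loops), h$n_loops)
  }
})

test_that("palindrome finder equals the quadratic oracle", {
  expect_identical(find_palindromes("GAATTC"), data.frame(start = 1L, end = 6L))
  expect_identical(nrow(find_palindromes("AAAAAA")), 0L)
  set.seed(63)
  for (i in 1:20) {
    s <- random_acgt(300)
    got <- find_palindromes(s)
    exp <- oracle_palindromes(s)
    rownames(got) <- rownames(exp) <- NULL
    expect_identical(got, exp, info = paste("seq", i))
  }
})

test_that("kissing-loop search finds forced complementarity and nothing else", {
  seq <- paste0("AAAA", "GGGGG", "AAAAAA", "CCCCC", "AAAA")
  hairA <- list(outer = c(3L, 11L), stem_pairs = cbind(i = 3L, j = 11L),
                loops = list(5:9), score = 0)
  hairB <- list(outer = c(14L, 22L), stem_pairs = cbind(i = 14L, j = 22L),
                loops = list(16:20), score = 0)
  kp <- find_kissing_pairs(list(hairA, hairB), seq, min_run = 5L)
  expect_identical(nrow(kp), 1L)
  expect_identical(kp$run, 5L)
  # re-validate the run base by base
  a <- strsplit(seq, "")[[1]]
  run_a <- a[kp$a_start + 0:(kp$run - 1)]
  run_b <- a[kp$b_start + 0:(kp$run - 1)]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  expect_identical(unname(comp[run_a]), rev(run_b))
  # non-complementary loops: empty
  hairB2 <- hairB
  seq2 <- paste0("AAAA", "GGGGG", "AAAAAA", "AAAAA", "AAAA")
  expect_identical(nrow(find_kissing_pairs(list(hairA, hairB2), seq2, 5L)), 0L)
  expect_identical(nrow(find_kissing_pairs(list(hairA), seq, 5L)), 0L)
})

test_that("the planted LBC-like stem-loop pair shows no kissing-loop interaction", {
  # negative control built from the planted 3'-end stem-loop geometry
  sim <- generate_genome(genome_blueprint(seed = 9L))
  canon <- extract_regions(sim$genome)$canonical
  hs <- sim$truth$hairpins
  lo <- min(vapply(hs, `[[`, integer(1), "at"))
  hi <- max(vapply(hs, function(h) h$at + h$span - 1L, integer(1)))
  w <- substr(canon, lo, hi)
  st <- fold(w)
  hp <- find_hairpins(st, min_stem = 3L)
  expect_gte(length(hp), 2L)
  expect_identical(nrow(find_kissing_pairs(hp, w, min_run = 5L)), 0L)
})
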