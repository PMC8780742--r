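nt_scheme <- scoring_scheme("nucleotide")

test_that("global alignment matches exhaustive path enumeration on short pairs", {
  sf <- nt_score_fun(2, -2)
  set.seed(1)
  pairs <- expand.grid(a = all_strings(c("A", "C"), 3), b = all_strings(c("A", "C"), 3),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    got <- global_align(pairs$a[i], pairs$b[i], nt_scheme)$score
    expect_equal(got, oracle_align_enum(pairs$a[i], pairs$b[i], sf, 4, 1),
                 info = paste(pairs$a[i], pairs$b[i]))
  }
})

test_that("alignment of identical sequences is gapless and 100% identical", {
  s <- random_acgt(80)
  aln <- global_align(s, s, nt_scheme)
  expect_identical(aln$aligned_a, s)
  expect_false(any(aln$columns == "gap"))
  expect_equal(percent_identity(aln), 100)
})

test_that("alignment score is symmetric under the symmetric nucleotide scheme", {
  set.seed(7)
  for (i in 1:20) {
    a <- random_acgt(sample(10:60, 1)); b <- random_acgt(sample(10:60, 1))
    expect_equal(global_align(a, b, nt_scheme)$score,
                 global_align(b, a, nt_scheme)$score)
  }
})

test_that("percent identity follows the documented denominator rules", {
  expect_equal(percent_identity(global_align("ACGTACGTAC", "ACGTACGTAC", nt_scheme)), 100)
  expect_equal(percent_identity(global_align("ACGT", "ACGA", nt_scheme)), 75)
  # hand-counted 12-column alignment: 8 matches, 2 mismatches, 2 internal gaps
  aln <- structure(list(
    aligned_a = "ACGTAC--GTAC", aligned_b = "ACGAACTTGTTC",
    score = 0,
    columns = c("match", "match", "match", "mismatch", "match", "match",
                "gap", "gap", "match", "match", "mismatch", "match")),
    class = "alignment_result")
  expect_equal(percent_identity(aln, "aligned_columns"), 100 * 8 / 12)
  expect_equal(percent_identity(aln, "shorter"), 100 * 8 / 10)
})

random_aa <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                      n, TRUE), collapse = "")
scramble_aa <- function(s, blocks) {
  cv <- strsplit(s, "")[[1]]
  for (b in blocks)
    cv[b[1]:b[2]] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                            b[2] - b[1] + 1L, TRUE)
  paste(cv, collapse = "")
}

test_that("windowed identity profiles track a planted scrambled protein block", {
  set.seed(21)
  aa_scheme <- scoring_scheme("protein")
  a <- random_aa(500)
  b <- scramble_aa(a, list(c(201L, 300L)))
  aln <- global_align(a, b, aa_scheme)
  prof <- windowed_identity(aln, 20L)
  expect_true(all(prof$values[prof$starts < 170 | prof$starts > 310] > 0.5))
  inside <- prof$starts >= 205 & prof$starts <= 275
  expect_true(all(prof$values[inside] < 0.5))
  perfect <- windowed_identity(global_align(a, a, aa_scheme), 20L)
  expect_true(all(perfect$values == 1))
  # step-1 profile mean approximates the global identity (edge effects only)
  expect_lt(abs(mean(prof$values) - percent_identity(aln) / 100), 0.05)
  expect_error(windowed_identity(aln, 600L), class = "totiscan_window_too_large")
})

test_that("LIS calling recovers planted low-identity blocks, none on clean pairs", {
  set.seed(33)
  aa_scheme <- scoring_scheme("protein")
  a <- random_aa(700)
  blocks <- list(c(151L, 250L), c(451L, 550L))
  b <- scramble_aa(a, blocks)
  aln <- global_align(a, b, aa_scheme)
  prof <- windowed_identity(aln, 20L)
  lis <- detect_lis(prof)
  expect_identical(nrow(lis), 2L)
  for (k in 1:2) {
    expect_lt(abs(lis$start_a[k] - blocks[[k]][1]), 20)
    expect_lt(abs(lis$end_a[k] - blocks[[k]][2]), 20)
    expect_lt(lis$mean_identity[k], 0.5)
    expect_lt(span_identity(aln, lis$start_a[k], lis$end_a[k]), 0.5)
  }
  clean <- windowed_identity(global_align(a, a, aa_scheme), 20L)
  expect_identical(nrow(detect_lis(clean)), 0L)
})

test_that("injected substitutions do not increase percent identity", {
  set.seed(55)
  a <- random_acgt(300)
  ident_at <- function(k) {
    cv <- strsplit(a, "")[[1]]
    pos <- sample(300, k)
    for (p in pos) cv[p] <- sample(setdiff(c("A", "C", "G", "T"), cv[p]), 1)
    percent_identity(global_align(a, paste(cv, collapse = ""), nt_scheme))
  }
  prev <- 100
  for (k in c(5, 20, 60, 120)) {
    cur <- ident_at(k)
    expect_lt(cur, prev + 1)  # tolerance for alignment re-arrangement
    prev <- cur
  }
})

test_that("nt-vs-aa contrast flips under a compensated frameshift", {
  s <- paste(rep("ATGGCTCATGAA", 25), collapse = "")  # 300 nt, codon clean
  expect_equal(unname(nt_vs_aa_identity(s, s)), c(100, 100))
  # +1 insertion then -1 deletion 60 nt apart, no substitutions
  cv <- strsplit(s, "")[[1]]
  derived <- paste(c(cv[1:90], "G", cv[91:150], cv[152:300]), collapse = "")
  v <- nt_vs_aa_identity(s, derived)
  expect_gt(v[["nt_identity"]], 95)
  expect_gt(v[["nt_identity"]], v[["aa_identity"]])
})

test_that("protein alignment under BLOSUM62 matches the independent affine DP", {
  sf <- blosum62_score_fun()
  scheme <- scoring_scheme("protein")
  set.seed(13)
  aa <- c("A", "R", "N", "D", "W")
  for (i in 1:40) {
    a <- paste(sample(aa, sample(2:8, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(2:8, 1), TRUE), collapse = "")
    expect_equal(global_align(a, b, scheme)$score,
                 oracle_align_dp(a, b, sf, 11, 1), info = paste(a, b))
  }
})
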