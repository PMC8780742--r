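# RNA secondary structure: Nussinov base-pair maximization (nested pairing
# DP, GU wobble allowed), hairpin/stem-loop extraction with unpaired-loop
# reporting, biological (reverse-complement) palindromes, and kissing-loop
# complementarity between hairpin loops. The published delta-G values of
# thermodynamic folders are NOT reproduced: the pairmax score (and an
# optional stacking pseudo-energy used only for ranking) orders structures
# by stability without claiming free energies.

#' Predict a nested secondary structure by base-pair maximization
#'
#' Nussinov dynamic program over AU/GC (and GU when `wobble`) pairs with a
#' minimum hairpin loop of `min_loop` unpaired bases. Traceback is
#' deterministic: the leftmost pairable base pairs first, with its smallest
#' admissible partner. U and T spellings are equivalent.
#'
#' @param seq sequence, 5 to 5000 nt (the DP is cubic; windows of a few
#'   hundred nt are the intended use).
#' @param min_loop minimum unpaired loop span (default 3).
#' @param wobble allow GU pairs (default TRUE).
#' @return object of class `rna_structure`: `seq` (cDNA spelling), `pairs`
#'   (2-column 1-based matrix, i < j), `score` (= -number of pairs; more
#'   negative = more stable).
#' @export
fold <- function(seq, min_loop = 3L, wobble = TRUE) {
  seq <- normalize_seq(seq)
  if (nchar(seq) < 5L || nchar(seq) > 5000L)
    totiscan_error("fold() accepts sequences of 5 to 5000 nt", "totiscan_alphabet_error")
  if (grepl("[^ACGT]", seq))
    totiscan_error("fold() requires an unambiguous ACGT/U sequence",
                   "totiscan_alphabet_error")
  p <- cpp_nussinov(seq, as.integer(min_loop), wobble)
  pairs <- matrix(as.integer(p + 1L), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  structure(list(seq = seq, pairs = pairs, score = -as.numeric(nrow(pairs)),
                 min_loop = as.integer(min_loop)),
            class = "rna_structure")
}

#' Dot-bracket string of a structure
#' @param structure [fold()] result.
#' @return character scalar.
#' @export
dot_bracket <- function(structure) {
  v <- rep(".", nchar(structure$seq))
  v[structure$pairs[, 1]] <- "("
  v[structure$pairs[, 2]] <- ")"
  paste(v, collapse = "")
}

# stacking pseudo-energy: sum over directly stacked pairs of a simple
# strength table (GC 3, AU 2, GU 1; a stack scores the mean of its two
# pairs). Ranking-only; not a free energy.
.pair_strength <- function(seq, i, j) {
  b <- paste0(substr(seq, i, i), substr(seq, j, j))
  switch(b, GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1, 0)
}

#' Stacking pseudo-energy of a structure (ranking only)
#' @param structure [fold()] result.
#' @return nonpositive numeric; more negative = more stably stacked.
#' @export
structure_energy <- function(structure) {
  p <- structure$pairs
  if (nrow(p) < 2L) return(0)
  p <- p[order(p[, 1]), , drop = FALSE]
  e <- 0
  for (r in seq_len(nrow(p) - 1L)) {
    if (p[r + 1L, 1] == p[r, 1] + 1L && p[r + 1L, 2] == p[r, 2] - 1L) {
      e <- e - (.pair_strength(structure$seq, p[r, 1], p[r, 2]) +
                .pair_strength(structure$seq, p[r + 1L, 1], p[r + 1L, 2])) / 2
    }
  }
  e
}

#' Extract hairpin (stem-loop) elements from a structure
#'
#' A hairpin is a maximal chain of pairs each directly enclosing a single
#' child pair (stacked runs crossing bulges/internal loops), ending at a
#' hairpin loop. Unpaired runs inside the outer pair are reported as loops
#' ("two contiguous loops" = hairpin loop + one bulge).
#'
#' @param structure [fold()] result.
#' @param min_stem minimum number of stem pairs (default 3).
#' @return list of hairpins, each: `outer` (i, j), `stem_pairs` (matrix),
#'   `loops` (list of integer vectors of unpaired positions), `score`
#'   (stacking pseudo-energy of the element).
#' @export
find_hairpins <- function(structure, min_stem = 3L) {
  p <- structure$pairs
  if (!nrow(p)) return(list())
  p <- p[order(p[, 1]), , drop = FALSE]
  n <- nrow(p)
  # children: pairs q directly nested in pair r with no intermediate pair
  encloses <- function(r, q) p[r, 1] < p[q, 1] && p[q, 2] < p[r, 2]
  parent <- rep(NA_integer_, n)
  for (q in seq_len(n)) {
    best <- NA_integer_
    for (r in seq_len(n)) {
      if (r == q || !encloses(r, q)) next
      if (is.na(best) || encloses(best, r)) best <- r
    }
    parent[q] <- best
  }
  n_children <- tabulate(parent[!is.na(parent)], nbins = n)
  innermost <- which(n_children == 0L)
  paired_pos <- c(p[, 1], p[, 2])
  hairpins <- list()
  used <- logical(n)
  for (h in innermost) {
    if (used[h]) next
    chain <- h
    cur <- h
    repeat {
      pa <- parent[cur]
      if (is.na(pa) || n_children[pa] != 1L) break
      chain <- c(chain, pa)
      cur <- pa
    }
    used[chain] <- TRUE
    stem <- p[rev(chain), , drop = FALSE]
    outer <- stem[1, ]
    inside <- seq.int(outer[1], outer[2])
    unpaired <- setdiff(inside, paired_pos)
    loops <- if (length(unpaired)) {
      split(unpaired, cumsum(c(1L, diff(unpaired) != 1L)))
    } else list()
    if (nrow(stem) < min_stem) next
    sub <- structure
    sub$pairs <- stem
    hairpins[[length(hairpins) + 1L]] <-
      list(outer = as.integer(outer), stem_pairs = stem,
           loops = unname(loops), score = structure_energy(sub))
  }
  hairpins[order(vapply(hairpins, function(x) x$outer[1], numeric(1)))]
}

#' Find biological (reverse-complement) palindromes
#'
#' Maximal even-length intervals equal to their own reverse complement
#' (strict Watson-Crick), at least `min_len` long; intervals contained in a
#' longer reported palindrome are dropped.
#'
#' @param seq nucleotide sequence.
#' @param min_len minimum palindrome length (even; default 6).
#' @return data.frame `start`, `end` (1-based inclusive).
#' @export
find_palindromes <- function(seq, min_len = 6L) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  cands <- list()
  for (c0 in seq_len(n - 1L)) {          # even center between c0 and c0+1
    l <- c0; r <- c0 + 1L
    while (l >= 1L && r <= n && !is.na(comp[ch[l]]) && comp[ch[l]] == ch[r]) {
      l <- l - 1L; r <- r + 1L
    }
    len <- r - l - 1L
    if (len >= min_len)
      cands[[length(cands) + 1L]] <- c(l + 1L, r - 1L)
  }
  if (!length(cands)) return(data.frame(start = integer(0), end = integer(0)))
  m <- unique(do.call(rbind, cands))
  keep <- vapply(seq_len(nrow(m)), function(i) {
    !any(m[, 1] <= m[i, 1] & m[, 2] >= m[i, 2] &
           (m[, 1] < m[i, 1] | m[, 2] > m[i, 2]))
  }, logical(1))
  out <- data.frame(start = m[keep, 1], end = m[keep, 2])
  out[order(out$start), , drop = FALSE]
}

#' Search for kissing-loop complementarity between hairpin loops
#'
#' For every pair of hairpins, looks for an antiparallel Watson-Crick
#' complementary run of at least `min_run` nt formed entirely from
#' contiguous unpaired loop positions of each hairpin.
#'
#' @param hairpins list from [find_hairpins()].
#' @param seq the folded sequence.
#' @param min_run minimum complementary run (nt, default 5).
#' @return data.frame: `hairpin_a`, `hairpin_b` (indices into `hairpins`),
#'   `run` (nt), `a_start`, `b_start` (1-based positions of the runs).
#' @export
find_kissing_pairs <- function(hairpins, seq, min_run = 5L) {
  seq <- normalize_seq(seq)
  empty <- data.frame(hairpin_a = integer(0), hairpin_b = integer(0),
                      run = integer(0), a_start = integer(0), b_start = integer(0))
  if (length(hairpins) < 2L) return(empty)
  rows <- list()
  for (a in seq_len(length(hairpins) - 1L)) for (b in (a + 1L):length(hairpins)) {
    for (la in hairpins[[a]]$loops) for (lb in hairpins[[b]]$loops) {
      sa <- paste(substring(seq, la, la), collapse = "")
      sb <- paste(substring(seq, lb, lb), collapse = "")
      m <- longest_perfect_match(sa, revcomp(sb))
      if (m$len >= min_run) {
        rows[[length(rows) + 1L]] <- data.frame(
          hairpin_a = a, hairpin_b = b, run = m$len,
          a_start = la[1] + m$a_off,
          b_start = lb[length(lb)] - m$b_off - m$len + 1L)
      }
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
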