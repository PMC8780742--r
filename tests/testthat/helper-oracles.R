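# Independent oracles used to validate the package implementations.
# Deliberately naive: enumeration / quadratic scans, no shared code with R/.

# -- global alignment -------------------------------------------------------

# exhaustive enumeration of every global alignment path; affine gap run
# costs open + ext * len. Exponential: only for very short sequences.
oracle_align_enum <- function(a, b, score_fun, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, sc, run) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, sc); return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      rec(i + 1L, j + 1L, sc + score_fun(av[i], bv[j]), "")
    if (i <= length(av))
      rec(i + 1L, j, sc - ext - if (run == "X") 0 else open, "X")
    if (j <= length(bv))
      rec(i, j + 1L, sc - ext - if (run == "Y") 0 else open, "Y")
  }
  rec(1L, 1L, 0, "")
  best
}

# independently written three-state affine Needleman-Wunsch in plain R
oracle_align_dp <- function(a, b, score_fun, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -open - ext * i
  for (j in seq_len(m)) Y[1, j + 1] <- -open - ext * j
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- score_fun(av[i], bv[j])
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

nt_score_fun <- function(match = 2, mismatch = -2)
  function(x, y) if (x == y) match else mismatch

blosum62_score_fun <- function() {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  mat <- get("BLOSUM62", envir = e)
  function(x, y) mat[x, y]
}

# -- Nussinov ---------------------------------------------------------------

# memoised max-pairs recursion written independently of the C++ kernel
oracle_max_pairs <- function(seq, min_loop = 3L, wobble = TRUE) {
  ch <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  n <- length(ch)
  if (n < 2L) return(0L)
  ok <- function(x, y) {
    p <- paste0(x, y)
    p %in% c("AT", "TA", "CG", "GC") || (wobble && p %in% c("GT", "TG"))
  }
  memo <- new.env()
  f <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- f(i + 1L, j)
    for (k in (i + min_loop + 1L):j)
      if (ok(ch[i], ch[k]))
        best <- max(best, 1L + f(i + 1L, k - 1L) + (if (k < j) f(k + 1L, j) else 0L))
    memo[[key]] <- best
    best
  }
  f(1L, n)
}

# -- palindromes ------------------------------------------------------------

oracle_revcomp <- function(s) {
  v <- rev(strsplit(s, "")[[1]])
  paste(c(A = "T", T = "A", C = "G", G = "C")[v], collapse = "")
}

# every even-length interval checked literally, then containment-filtered
oracle_palindromes <- function(seq, min_len = 6L) {
  n <- nchar(seq)
  found <- list()
  min_even <- min_len + min_len %% 2L
  for (s in seq_len(n)) {
    len <- min_even
    while (s + len - 1L <= n) {
      sub <- substr(seq, s, s + len - 1L)
      if (sub == oracle_revcomp(sub)) found[[length(found) + 1L]] <- c(s, s + len - 1L)
      len <- len + 2L
    }
  }
  if (!length(found)) return(data.frame(start = integer(0), end = integer(0)))
  m <- unique(do.call(rbind, found))
  keep <- vapply(seq_len(nrow(m)), function(i)
    !any(m[, 1] <= m[i, 1] & m[, 2] >= m[i, 2] & (m[, 1] < m[i, 1] | m[, 2] > m[i, 2])),
    logical(1))
  out <- data.frame(start = m[keep, 1], end = m[keep, 2])
  out[order(out$start), , drop = FALSE]
}

# -- ORFs -------------------------------------------------------------------

# six-line-style naive scanner: walk codons from every ATG
naive_orf_scan <- function(seq, min_aa) {
  n <- nchar(seq)
  res <- list()
  for (i in seq_len(n - 2L)) {
    if (substr(seq, i, i + 2L) != "ATG") next
    j <- i
    repeat {
      if (j + 2L > n) break
      cod <- substr(seq, j, j + 2L)
      if (j > i && cod %in% c("TAA", "TAG", "TGA")) {
        if ((j - i) / 3L >= min_aa)
          res[[length(res) + 1L]] <- c(start = i - 1L, end = j + 2L)
        break
      }
      j <- j + 3L
    }
  }
  if (!length(res)) return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, res)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  rownames(out) <- NULL
  out
}

# -- longest common substring ----------------------------------------------

# cubic scan over substrings of a, longest first, leftmost tie-break
oracle_lcs <- function(a, b) {
  na <- nchar(a)
  for (len in seq.int(min(na, nchar(b)), 1L)) {
    for (off in 0:(na - len)) {
      sub <- substr(a, off + 1L, off + len)
      hit <- regexpr(sub, b, fixed = TRUE)
      if (hit != -1L) return(list(len = len, a_off = off, b_off = as.integer(hit) - 1L))
    }
  }
  list(len = 0L, a_off = -1L, b_off = -1L)
}

random_acgt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

all_strings <- function(alphabet, max_len) {
  unlist(lapply(seq_len(max_len), function(L) {
    g <- do.call(expand.grid, rep(list(alphabet), L))
    apply(g, 1, paste, collapse = "")
  }))
}
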