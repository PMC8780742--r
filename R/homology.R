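# Self-homology of extra sequences against the canonical (+)/(-) strands,
# generic local matching against user references (e.g. rRNA), the
# longest-common-substring kernel, and xenolog filtering of 12-column
# tabular hit files.

#' Longest perfect (exact) match between two strings
#'
#' Ties resolve to maximal length, then smallest offset in `a`, then
#' smallest offset in `b`.
#'
#' @param a,b nonempty character scalars.
#' @return list `len`, `a_off`, `b_off` (0-based offsets; -1 when `len` 0).
#' @export
longest_perfect_match <- function(a, b) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  r <- cpp_lcs_substring(a, b)
  list(len = r[1], a_off = r[2], b_off = r[3])
}

#' All near-exact local matches between two sequences
#'
#' Exact-match seeding (k-mers) with same-diagonal chaining across mismatch
#' columns: adjacent exact runs on one diagonal are merged while the merged
#' identity stays at or above `min_identity`. No indels are modelled — the
#' kernel targets the 99-100%-identity matches that self-homology and
#' rRNA-carryover analyses report.
#'
#' @param query,subject character scalars.
#' @param min_len minimum merged match length (nt).
#' @param min_identity minimum percent identity of a merged match.
#' @param seed_k exact seed length (default 15).
#' @return data.frame: `q_start`, `q_end`, `s_start`, `s_end` (1-based
#'   inclusive), `length`, `identity` (percent), sorted by length
#'   descending.
#' @export
find_local_matches <- function(query, subject, min_len = 20L,
                               min_identity = 95, seed_k = 15L) {
  em <- cpp_exact_matches(query, subject, as.integer(seed_k))
  if (!nrow(em))
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      length = integer(0), identity = numeric(0)))
  d <- data.frame(q0 = em[, 1], t0 = em[, 2], len = em[, 3])
  d$diag <- d$t0 - d$q0
  d <- d[order(d$diag, d$q0), ]
  # chain same-diagonal runs across pure-mismatch gaps
  chains <- list()
  cur <- d[1, ]
  cur$match <- cur$len
  for (i in seq_len(nrow(d))[-1]) {
    r <- d[i, ]
    gap <- r$q0 - (cur$q0 + cur$len)
    merged_span <- r$q0 + r$len - cur$q0
    merged_match <- cur$match + r$len
    if (r$diag == cur$diag && gap >= 0 &&
        100 * merged_match / merged_span >= min_identity) {
      cur$len <- merged_span
      cur$match <- merged_match
    } else {
      chains[[length(chains) + 1L]] <- cur
      cur <- r; cur$match <- r$len
    }
  }
  chains[[length(chains) + 1L]] <- cur
  ch <- do.call(rbind, chains)
  ch$identity <- 100 * ch$match / ch$len
  ch <- ch[ch$len >= min_len & ch$identity >= min_identity, , drop = FALSE]
  if (!nrow(ch))
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      length = integer(0), identity = numeric(0)))
  out <- data.frame(q_start = ch$q0 + 1L, q_end = ch$q0 + ch$len,
                    s_start = ch$t0 + 1L, s_end = ch$t0 + ch$len,
                    length = ch$len, identity = ch$identity)
  out <- out[order(-out$length, out$q_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# map subject coordinates of a minus-strand match (found on the
# reverse-complemented target of length n) back onto the (+) frame
.minus_to_plus <- function(s_start, s_end, n) {
  c(start = n - s_end + 1L, end = n - s_start + 1L)
}

#' Map an extra sequence against the canonical (+)/(-) strands
#'
#' The query is the extra sequence extended by `extension` nt of adjoining
#' canonical sequence (published self-homology stretches run a few nt into
#' the canonical region). Matches against the (-) strand are reported in
#' (+)-strand coordinates. Query coordinates are signed positions.
#'
#' @param genome anchored [viral_genome()].
#' @param query `"FIVE_EXTRA"` or `"THREE_EXTRA"`.
#' @param min_len,min_identity,seed_k see [find_local_matches()].
#' @param extension nt of proximal canonical sequence appended to the query
#'   (default 10).
#' @return data.frame: `query_region`, `query_start`, `query_end` (signed
#'   notation), `target_strand`, `target_start`, `target_end` (1-based on
#'   the canonical (+) frame), `length`, `identity`; sorted by length
#'   descending. Error of class `totiscan_empty_region` if the extra region
#'   is empty (the "None" rows of organization tables).
#' @export
map_extra_to_canonical <- function(genome, query = c("FIVE_EXTRA", "THREE_EXTRA"),
                                   min_len = 20L, min_identity = 95,
                                   seed_k = 15L, extension = 10L) {
  query <- match.arg(query)
  reg <- extract_regions(genome)
  canon <- reg$canonical
  extra <- if (query == "FIVE_EXTRA") reg$five_extra else reg$three_extra
  if (!nchar(extra))
    totiscan_error(sprintf("%s region is empty", query), "totiscan_empty_region")
  n5 <- nchar(reg$five_extra)
  nc <- nchar(canon)
  if (query == "FIVE_EXTRA") {
    qseq <- paste0(extra, substr(canon, 1L, extension))
    # query position -> signed position
    q2signed <- function(q) if (q <= n5) signed_position("FIVE_EXTRA", n5 - q + 1L)
                            else signed_position("CANONICAL", q - n5)
  } else {
    ext <- min(extension, nc)
    qseq <- paste0(substr(canon, nc - ext + 1L, nc), extra)
    q2signed <- function(q) if (q <= ext) signed_position("CANONICAL", nc - ext + q)
                            else signed_position("THREE_EXTRA", q - ext)
  }
  hit_rows <- list()
  for (strand in c("plus", "minus")) {
    target <- if (strand == "plus") canon else revcomp(canon)
    h <- find_local_matches(qseq, target, min_len, min_identity, seed_k)
    if (!nrow(h)) next
    for (i in seq_len(nrow(h))) {
      if (strand == "minus") {
        pm <- .minus_to_plus(h$s_start[i], h$s_end[i], nc)
        ts <- pm["start"]; te <- pm["end"]
      } else { ts <- h$s_start[i]; te <- h$s_end[i] }
      # drop trivial self-matches: a plus-strand hit of the canonical
      # extension onto its own position
      if (strand == "plus" && query == "FIVE_EXTRA" &&
          h$q_start[i] > n5 && (h$q_start[i] - n5) == ts) next
      if (strand == "plus" && query == "THREE_EXTRA" &&
          h$q_start[i] <= min(extension, nc) &&
          ts == nc - min(extension, nc) + h$q_start[i]) next
      qs <- q2signed(h$q_start[i]); qe <- q2signed(h$q_end[i])
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        query_region = query,
        query_start = format_signed(qs, genome),
        query_end = format_signed(qe, genome),
        target_strand = strand,
        target_start = as.integer(ts), target_end = as.integer(te),
        length = h$length[i], identity = h$identity[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hit_rows))
    return(data.frame(query_region = character(0), query_start = character(0),
                      query_end = character(0), target_strand = character(0),
                      target_start = integer(0), target_end = integer(0),
                      length = integer(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hit_rows)
  out <- out[order(-out$length, out$target_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a genome region against a user-supplied reference (e.g. rRNA)
#'
#' Both reference strands are searched; minus-strand matches are reported
#' in the reference's (+) coordinates.
#'
#' @param seq query sequence (e.g. an extra region).
#' @param reference reference sequence (single character scalar).
#' @param min_len,min_identity,seed_k see [find_local_matches()].
#' @return data.frame like [find_local_matches()] plus `ref_strand`.
#' @export
map_to_reference <- function(seq, reference, min_len = 30L,
                             min_identity = 95, seed_k = 15L) {
  rows <- list()
  n <- nchar(reference)
  for (strand in c("plus", "minus")) {
    target <- if (strand == "plus") reference else revcomp(reference)
    h <- find_local_matches(seq, target, min_len, min_identity, seed_k)
    if (!nrow(h)) next
    if (strand == "minus" && nrow(h)) {
      pm <- t(vapply(seq_len(nrow(h)),
                     function(i) .minus_to_plus(h$s_start[i], h$s_end[i], n),
                     numeric(2)))
      h$s_start <- as.integer(pm[, 1]); h$s_end <- as.integer(pm[, 2])
    }
    h$ref_strand <- strand
    rows[[length(rows) + 1L]] <- h
  }
  if (!length(rows))
    return(cbind(find_local_matches("A", "C"), ref_strand = character(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.blast12_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Read a 12-column tabular hit file
#'
#' The classic 12-column tab-separated dialect (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore).
#'
#' @param path input file.
#' @return data.frame with the 12 standard columns. Error of class
#'   `totiscan_malformed_row` naming the offending line.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 12)), .blast12_cols))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad))
    totiscan_error(sprintf("malformed hit row at line %d (expected 12 columns, got %d)",
                           bad[1], lengths(parts)[bad[1]]),
                   "totiscan_malformed_row")
  m <- do.call(rbind, parts)
  df <- data.frame(m, stringsAsFactors = FALSE)
  names(df) <- .blast12_cols
  num_cols <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send", "evalue", "bitscore")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v))
      totiscan_error(sprintf("malformed hit row at line %d (non-numeric %s)",
                             which(is.na(v))[1], cc), "totiscan_malformed_row")
    df[[cc]] <- v
  }
  df
}

#' Filter tabular hits with the xenolog thresholds
#'
#' Keeps hits at or above the identity and length thresholds (inclusive by
#' default; `strict = TRUE` applies strictly-greater-than semantics).
#' Idempotent; output rows are a subset of the input.
#'
#' @param hits data.frame from [read_blast_tab()].
#' @param min_identity percent identity threshold (default 80).
#' @param min_len alignment length threshold in nt (default 30).
#' @param strict use strict `>` comparisons instead of `>=`.
#' @return data.frame of xenolog candidates: `subject_id`, `identity`,
#'   `length`, `query_start`, `query_end` plus the original columns.
#' @export
filter_xenolog_hits <- function(hits, min_identity = 80, min_len = 30,
                                strict = FALSE) {
  keep <- if (strict) hits$pident > min_identity & hits$length > min_len
          else hits$pident >= min_identity & hits$length >= min_len
  out <- hits[keep, , drop = FALSE]
  out$subject_id <- out$sseqid
  out$identity <- out$pident
  out$query_start <- out$qstart
  out$query_end <- out$qend
  rownames(out) <- NULL
  out
}
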