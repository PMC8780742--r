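# Pairwise identity analysis: global alignment (affine gaps), percent
# identity under explicit denominator rules, sliding-window identity
# profiles anchored to sequence A, low-identity-stretch (LIS) calling, and
# the nucleotide-vs-amino-acid identity contrast that motivates the
# compensatory-frameshift model.

#' Alignment scoring scheme
#'
#' Nucleotide default mirrors the linear scheme used by common desktop
#' aligners (mismatch 2, gap open 4, gap extend 1); the match bonus is +2.
#' Protein default is BLOSUM62 with gap open 11 / extend 1. Gap costs are
#' stored as positive magnitudes; a length-L gap costs `open + L * extend`.
#'
#' @param kind `"nucleotide"` or `"protein"`.
#' @param match,mismatch nucleotide scores (ignored for protein).
#' @param gap_open,gap_extend nonnegative penalties.
#' @param matrix_name protein substitution matrix (shipped with Biostrings).
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(kind = c("nucleotide", "protein"),
                           match = 2, mismatch = -2,
                           gap_open = if (kind == "protein") 11 else 4,
                           gap_extend = 1,
                           matrix_name = "BLOSUM62") {
  kind <- match.arg(kind)
  stopifnot(gap_open >= 0, gap_extend >= 0, gap_extend <= gap_open)
  structure(list(kind = kind, match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 matrix_name = if (kind == "protein") matrix_name else NULL),
            class = "scoring_scheme")
}

.subst_matrix <- function(scheme) {
  if (scheme$kind == "nucleotide") {
    letters <- c("A", "C", "G", "T", "N")
    m <- matrix(scheme$mismatch, 5, 5, dimnames = list(letters, letters))
    diag(m) <- scheme$match
    m["N", ] <- scheme$mismatch   # ambiguity codes never match
    m[, "N"] <- scheme$mismatch
    m
  } else {
    e <- new.env()
    utils::data(list = scheme$matrix_name, package = "Biostrings", envir = e)
    get(scheme$matrix_name, envir = e)
  }
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch-style global alignment with affine gap costs, delegated
#' to `Biostrings::pairwiseAlignment` (whose scoring convention — a length-L
#' gap costing open + L*extend — matches [scoring_scheme()]). Protein
#' sequences may contain `*` (stop), aligned as an ordinary symbol via an
#' extended substitution matrix.
#'
#' @param a,b sequences (character scalars).
#' @param scheme [scoring_scheme()].
#' @return object of class `alignment_result` with `aligned_a`, `aligned_b`,
#'   `score` and per-column flags in `match`/`mismatch`/`gap`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme("nucleotide")) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  if (scheme$kind == "nucleotide") {
    a <- normalize_seq(a); b <- normalize_seq(b)
    if (grepl("[^ACGTN]", a) || grepl("[^ACGTN]", b))
      totiscan_error("unsupported nucleotide alphabet for alignment",
                     "totiscan_alphabet_error")
    mat <- .subst_matrix(scheme)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      substitutionMatrix = mat, gapOpening = scheme$gap_open,
      gapExtension = scheme$gap_extend, type = "global")
  } else {
    if (grepl("[^A-Z*]", a) || grepl("[^A-Z*]", b))
      totiscan_error("unsupported protein alphabet", "totiscan_alphabet_error")
    mat <- .subst_matrix(scheme)
    if (!"*" %in% rownames(mat)) {
      mat <- rbind(cbind(mat, `*` = min(mat)), `*` = c(rep(min(mat), ncol(mat)), max(mat)))
    }
    pa <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                        gapOpening = scheme$gap_open,
                                        gapExtension = scheme$gap_extend,
                                        type = "global")
  }
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(ga, "")[[1]]; cb <- strsplit(gb, "")[[1]]
  flags <- ifelse(ca == "-" | cb == "-", "gap",
                  ifelse(ca == cb, "match", "mismatch"))
  structure(list(aligned_a = ga, aligned_b = gb,
                 score = Biostrings::score(pa), columns = flags),
            class = "alignment_result")
}

#' Vectorized global alignment scores
#'
#' Optimal global alignment scores for paired vectors of sequences under the
#' same scoring configuration as [global_align()], computed in one call
#' (useful for large property sweeps).
#'
#' @param a,b character vectors of equal length.
#' @param scheme [scoring_scheme()].
#' @return numeric vector of scores.
#' @export
global_align_scores <- function(a, b, scheme = scoring_scheme("nucleotide")) {
  stopifnot(length(a) == length(b))
  mat <- .subst_matrix(scheme)
  if (scheme$kind == "nucleotide") {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(a), Biostrings::DNAStringSet(b),
      substitutionMatrix = mat, gapOpening = scheme$gap_open,
      gapExtension = scheme$gap_extend, type = "global", scoreOnly = TRUE)
  } else {
    if (!"*" %in% rownames(mat))
      mat <- rbind(cbind(mat, `*` = min(mat)), `*` = c(rep(min(mat), ncol(mat)), max(mat)))
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(a), Biostrings::AAStringSet(b),
      substitutionMatrix = mat, gapOpening = scheme$gap_open,
      gapExtension = scheme$gap_extend, type = "global", scoreOnly = TRUE)
  }
  as.numeric(pa)
}

#' Percent identity of a global alignment
#'
#' @param aln [global_align()] result.
#' @param denominator `"aligned_columns"` (default: all alignment columns
#'   excluding terminal gap overhangs; internal gaps count as mismatches) or
#'   `"shorter"` (length of the shorter input sequence).
#' @return percentage in (0, 100].
#' @export
percent_identity <- function(aln, denominator = c("aligned_columns", "shorter")) {
  denominator <- match.arg(denominator)
  flags <- aln$columns
  n_match <- sum(flags == "match")
  if (denominator == "shorter") {
    ca <- strsplit(aln$aligned_a, "")[[1]]; cb <- strsplit(aln$aligned_b, "")[[1]]
    den <- min(sum(ca != "-"), sum(cb != "-"))
  } else {
    non_gap <- which(flags != "gap")
    if (!length(non_gap)) return(0)
    den <- max(non_gap) - min(non_gap) + 1L  # trims terminal overhangs only
  }
  100 * n_match / den
}

#' Sliding-window identity profile anchored to sequence A
#'
#' Each window covers `window` consecutive residues of the ungapped A
#' sequence; its value is the number of match columns in the A-anchored
#' alignment span divided by `window` (so insertions in B count against
#' identity, as do gaps in A).
#'
#' @param aln [global_align()] result.
#' @param window window size on A (50 nt / 20 aa in the standard analysis).
#' @param step window start step (default 1).
#' @return object of class `identity_profile` with `starts` (1-based A
#'   coordinates) and `values` (fractions in `[0, 1]`).
#' @export
windowed_identity <- function(aln, window, step = 1L) {
  ca <- strsplit(aln$aligned_a, "")[[1]]
  apos <- cumsum(ca != "-")          # A coordinate of each column (0 before first)
  len_a <- max(apos)
  if (window < 2L || window > len_a)
    totiscan_error("window must be in [2, length(A)]", "totiscan_window_too_large")
  is_match <- aln$columns == "match"
  # matches attributed to each A position (match columns have ca != "-")
  match_at <- tabulate(apos[is_match], nbins = len_a)
  cm <- c(0, cumsum(match_at))
  starts <- seq.int(1L, len_a - window + 1L, by = step)
  vals <- (cm[starts + window] - cm[starts]) / window
  structure(list(window = as.integer(window), step = as.integer(step),
                 starts = starts, values = vals),
            class = "identity_profile")
}

#' Call low-identity stretches from an identity profile
#'
#' Maximal runs of windows below `threshold`; neighbouring runs separated by
#' fewer than `window / 2` above-threshold windows are merged; merged spans
#' shorter than `min_len` residues are dropped. Boundaries are 1-based
#' inclusive on sequence A, from the first sub-threshold window start to the
#' last sub-threshold window end.
#'
#' @param profile [windowed_identity()] result.
#' @param threshold identity fraction (default 0.5).
#' @param min_len minimum stretch length on A (default = window).
#' @return data.frame with `start_a`, `end_a`, `mean_identity` (mean profile
#'   value over the merged run) and `span_identity` (fraction of identical
#'   residues over the reported span).
#' @export
detect_lis <- function(profile, threshold = 0.5, min_len = profile$window) {
  low <- profile$values < threshold
  if (!any(low)) return(data.frame(start_a = integer(0), end_a = integer(0),
                                   mean_identity = numeric(0),
                                   span_identity = numeric(0)))
  r <- rle(low)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  runs <- data.frame(start = idx_start[r$values], end = idx_end[r$values])
  gap_max <- profile$window / 2
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) for (i in 2:nrow(runs)) {
    sep <- runs$start[i] - merged$end[nrow(merged)] - 1L
    if (sep * profile$step < gap_max)
      merged$end[nrow(merged)] <- runs$end[i]
    else merged <- rbind(merged, runs[i, ])
  }
  out <- lapply(seq_len(nrow(merged)), function(i) {
    ws <- profile$starts[merged$start[i]]
    we <- profile$starts[merged$end[i]] + profile$window - 1L
    vals <- profile$values[merged$start[i]:merged$end[i]]
    data.frame(start_a = ws, end_a = we, mean_identity = mean(vals),
               span_identity = NA_real_)
  })
  out <- do.call(rbind, out)
  out[out$end_a - out$start_a + 1L >= min_len, , drop = FALSE]
}

#' Identity over a fixed span of sequence A
#'
#' Fraction of positions of A in `[start_a, end_a]` whose alignment column
#' is a match (gap columns count against identity). Used to report the
#' identity of a called LIS over its own span.
#'
#' @param aln [global_align()] result.
#' @param start_a,end_a 1-based inclusive A coordinates.
#' @return fraction in `[0, 1]`.
#' @export
span_identity <- function(aln, start_a, end_a) {
  ca <- strsplit(aln$aligned_a, "")[[1]]
  apos <- cumsum(ca != "-")
  sel <- apos >= start_a & apos <= end_a & ca != "-"
  sum(aln$columns[sel] == "match") / (end_a - start_a + 1L)
}

#' Nucleotide-vs-amino-acid identity contrast for a coding region
#'
#' Aligns the nucleotide sequences of a region and, independently, their
#' conceptual translations, returning both percent identities. Under
#' compensatory frameshifting (paired indels restoring the net frame) the
#' nucleotide identity stays high while the translated identity collapses
#' inside the shifted window.
#'
#' @param nt_a,nt_b coding nucleotide sequences (frame 1).
#' @param region optional `c(start, end)` 1-based nt interval applied to
#'   both sequences (rounded out to codon boundaries for translation).
#' @param denominator passed to [percent_identity()].
#' @return named numeric `c(nt_identity =, aa_identity =)` in percent.
#' @export
nt_vs_aa_identity <- function(nt_a, nt_b, region = NULL,
                              denominator = "aligned_columns") {
  nt_a <- normalize_seq(nt_a); nt_b <- normalize_seq(nt_b)
  if (!is.null(region)) {
    s <- (region[1] - 1L) %/% 3L * 3L + 1L       # codon-aligned
    ea <- min(nchar(nt_a), region[2]); eb <- min(nchar(nt_b), region[2])
    nt_a <- substr(nt_a, s, ea); nt_b <- substr(nt_b, s, eb)
  }
  aln_nt <- global_align(nt_a, nt_b, scoring_scheme("nucleotide"))
  aa_a <- translate_cdna(nt_a); aa_b <- translate_cdna(nt_b)
  aln_aa <- global_align(aa_a, aa_b, scoring_scheme("protein"))
  c(nt_identity = percent_identity(aln_nt, denominator),
    aa_identity = percent_identity(aln_aa, denominator))
}

#' Write an identity profile as TSV
#' @param profile [windowed_identity()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(data.frame(position = profile$starts,
                         identity = sprintf("%.4f", profile$values)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
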