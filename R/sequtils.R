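# Shared sequence helpers. All internal sequences are cDNA-style character
# strings over A/C/G/T (+ IUPAC ambiguity codes on input); U is normalized to
# T at every public entry point.

totiscan_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "totiscan_error")))
}

#' Normalize a nucleotide sequence to cDNA spelling
#'
#' Uppercases, converts U to T and validates the alphabet (IUPAC nucleotide
#' codes are permitted; they never match any motif).
#'
#' @param seq character scalar.
#' @return normalized character scalar.
#' @export
normalize_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("u", "t", toupper(seq))
  s <- chartr("U", "T", s)
  if (nchar(s) && grepl("[^ACGTRYSWKMBDHVN]", s))
    totiscan_error("sequence contains non-nucleotide characters", "totiscan_alphabet_error")
  s
}

#' Reverse complement of a cDNA string
#' @param seq character scalar (cDNA alphabet).
#' @return reverse-complemented character scalar.
#' @export
revcomp <- function(seq) {
  seq <- normalize_seq(seq)
  if (!nchar(seq)) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a cDNA string (standard nuclear code)
#'
#' Trailing incomplete codons are dropped; stop codons are rendered `*` and
#' treated as ordinary symbols by downstream alignments.
#'
#' @param seq character scalar, cDNA.
#' @return amino-acid character scalar.
#' @export
translate_cdna <- function(seq) {
  seq <- normalize_seq(seq)
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1L, n)),
                                     if.fuzzy.codon = "X", no.init.codon = TRUE))
}

#' Random nucleotide sequence with AT bias
#'
#' Draws from the session RNG; callers seed via [set.seed()] or pass a seed
#' to the simulator entry points.
#'
#' @param n length in nt.
#' @param at_bias total probability mass on A+T (split evenly).
#' @return character scalar of length `n`.
#' @export
random_seq <- function(n, at_bias = 0.55) {
  if (n <= 0) return("")
  p <- c(A = at_bias / 2, T = at_bias / 2, C = (1 - at_bias) / 2, G = (1 - at_bias) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Read a (multi-)FASTA file as named character vector
#' @param path FASTA file.
#' @param normalize normalize U to T (default TRUE).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, normalize = TRUE) {
  x <- Biostrings::readBStringSet(path)
  out <- setNames(as.character(x), names(x))
  if (normalize) out <- vapply(out, normalize_seq, character(1))
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @param as_rna re-emit T as U.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, as_rna = FALSE) {
  if (as_rna) seqs <- vapply(seqs, function(s) chartr("T", "U", s), character(1))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read sequences from a GenBank flat file (id and sequence only)
#'
#' Minimal reader for locally stored GenBank records: extracts the LOCUS
#' name and the ORIGIN sequence of each record. Feature tables are ignored.
#'
#' @param path GenBank flat file (may contain several records).
#' @param normalize normalize U to T (default TRUE).
#' @return named character vector of sequences.
#' @export
read_genbank <- function(path, normalize = TRUE) {
  lines <- readLines(path, warn = FALSE)
  out <- character(0)
  id <- NULL; in_origin <- FALSE; buf <- character(0)
  for (ln in lines) {
    if (startsWith(ln, "LOCUS")) {
      id <- strsplit(trimws(ln), "\\s+")[[1]][2]
    } else if (startsWith(ln, "ORIGIN")) {
      in_origin <- TRUE
    } else if (startsWith(ln, "//")) {
      if (!is.null(id)) out[id] <- paste(buf, collapse = "")
      id <- NULL; in_origin <- FALSE; buf <- character(0)
    } else if (in_origin) {
      buf <- c(buf, toupper(gsub("[^A-Za-z]", "", ln)))
    }
  }
  if (!length(out))
    totiscan_error("no GenBank records found", "totiscan_malformed_row")
  if (normalize) out <- vapply(out, normalize_seq, character(1))
  out
}

# all start offsets (1-based, overlapping allowed) of a literal pattern;
# plain character matching, so ambiguity codes (N etc.) never match.
fixed_matches <- function(pattern, subject) {
  if (!nchar(pattern) || nchar(subject) < nchar(pattern)) return(integer(0))
  k <- nchar(pattern)
  starts <- seq_len(nchar(subject) - k + 1L)
  starts[substring(subject, starts, starts + k - 1L) == pattern]
}
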