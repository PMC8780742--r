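# Canonical-end anchoring and the signed coordinate scheme.
#
# A sequenced LBC contig is partitioned into a 5'-extra region, the canonical
# genome (delimited by the family's conserved 5' hexamer and short 3'
# terminal string) and a 3'-extra region. Internally everything is 0-based
# half-open; the 1-based signed convention used in the literature
# ((-)k upstream of the 5' G = 1, (+)k downstream of the 3' terminus) is a
# presentation layer implemented by `signed_position()`.

#' Terminal motif set for a virus family
#'
#' @param five_prime_motif conserved 5' hexamer on the (+)strand
#'   (`GAATTT` for Sc-LBC, `GAAATT` for Td-LBCbarr).
#' @param three_prime_terminus short string ending the canonical (+)strand
#'   (`CTACGCG` for Sc-LBC, `CCATAAGC` for TdV-LBCbarr1).
#' @param minus_strand_init_signal the (-)strand 3' transcription-initiation
#'   signal, stored as its (+)strand image (e.g. `GAATTT` for 3'CTTAAA).
#' @param canonical_length_hint expected canonical length in nt, used to
#'   disambiguate repeated 3' termini (4615 Sc-LBC, 4565 TdV-LBCbarr).
#' @return object of class `terminal_motif_set`.
#' @export
terminal_motif_set <- function(five_prime_motif, three_prime_terminus,
                               minus_strand_init_signal = five_prime_motif,
                               canonical_length_hint = NULL) {
  for (s in c(five_prime_motif, three_prime_terminus, minus_strand_init_signal)) {
    stopifnot(is.character(s), length(s) == 1L, nchar(s) > 0L)
    if (grepl("[^ACGT]", s))
      totiscan_error("motifs must be plain ACGT", "totiscan_alphabet_error")
  }
  structure(list(five_prime_motif = five_prime_motif,
                 three_prime_terminus = three_prime_terminus,
                 minus_strand_init_signal = minus_strand_init_signal,
                 canonical_length_hint = canonical_length_hint),
            class = "terminal_motif_set")
}

#' Built-in LBC family motif configurations
#'
#' Loads the per-family terminal motif sets and canonical length hints
#' shipped with the package (`lbc-sc`, `lbc-td`), or a user JSON config of
#' the same schema.
#'
#' @param path optional JSON config; default = packaged configuration.
#' @return named list of [terminal_motif_set()] objects.
#' @export
lbc_families <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lbc_families.json", package = "totiscan")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(cfg, function(f)
    terminal_motif_set(f$five_prime_motif, f$three_prime_terminus,
                       f$minus_strand_init_signal,
                       f$canonical_length_hint))
}

#' Construct a viral genome record
#'
#' @param id genome identifier.
#' @param seq full sequenced (+)strand (cDNA alphabet; U accepted).
#' @param canonical_start 0-based offset of the first canonical base.
#' @param canonical_end 0-based exclusive offset one past the last canonical
#'   base.
#' @param host free-text host description.
#' @return object of class `viral_genome`.
#' @export
viral_genome <- function(id, seq, canonical_start, canonical_end, host = "") {
  seq <- normalize_seq(seq)
  stopifnot(canonical_start >= 0, canonical_start < canonical_end,
            canonical_end <= nchar(seq))
  structure(list(id = id, host = host, seq = seq,
                 canonical_start = as.integer(canonical_start),
                 canonical_end = as.integer(canonical_end)),
            class = "viral_genome")
}

#' @export
print.viral_genome <- function(x, ...) {
  cat(sprintf("<viral_genome> %s: %d nt sequenced, canonical %d nt (5'-extra %d, 3'-extra %d)\n",
              x$id, nchar(x$seq), x$canonical_end - x$canonical_start,
              x$canonical_start, nchar(x$seq) - x$canonical_end))
  invisible(x)
}

# longest ATG-initiated open reading frame fully downstream of `from`
# (0-based offset); used only for the 5'-anchor tie rule.
.downstream_orf_coverage <- function(seq, from) {
  sub <- substr(seq, from + 1L, nchar(seq))
  orfs <- find_orfs(sub, min_aa = 1L)
  if (!nrow(orfs)) return(0L)
  max(orfs$end - orfs$start)
}

#' Locate the canonical 5' end
#'
#' Finds the occurrence of the family's conserved 5' hexamer that starts the
#' canonical genome. If the hexamer occurs more than once in the first 25%
#' of the contig, the occurrence maximizing downstream ORF coverage wins;
#' remaining ties go to the leftmost occurrence.
#'
#' @param seq full contig (+)strand.
#' @param motifs [terminal_motif_set()].
#' @return 0-based offset of the motif's first base.
#' @export
find_five_prime_anchor <- function(seq, motifs) {
  seq <- normalize_seq(seq)
  stopifnot(nchar(seq) > 0L, nchar(motifs$five_prime_motif) == 6L)
  occ <- fixed_matches(motifs$five_prime_motif, seq)  # 1-based
  if (!length(occ))
    totiscan_error("5' terminal motif not found", "totiscan_motif_not_found")
  early <- occ[occ <= ceiling(nchar(seq) * 0.25)]
  cand <- if (length(early)) early else occ
  if (length(cand) > 1L) {
    cov <- vapply(cand, function(p) .downstream_orf_coverage(seq, p - 1L), integer(1))
    cand <- cand[cov == max(cov)]
  }
  cand[1L] - 1L
}

#' Locate the canonical 3' end
#'
#' Finds the occurrence of the family's 3' terminal string that closes the
#' canonical genome. With a canonical length hint the occurrence whose
#' implied canonical length is closest to the hint wins (equidistant pairs
#' are an error); without a hint the last occurrence is used.
#'
#' @param seq full contig (+)strand.
#' @param motifs [terminal_motif_set()].
#' @param anchor 0-based 5' anchor offset from [find_five_prime_anchor()].
#' @param canonical_length_hint expected canonical length (nt); defaults to
#'   the motif set's hint.
#' @return 0-based exclusive end offset (one past the terminal base).
#' @export
find_three_prime_terminus <- function(seq, motifs, anchor,
                                      canonical_length_hint = motifs$canonical_length_hint) {
  seq <- normalize_seq(seq)
  ends <- fixed_matches(motifs$three_prime_terminus, seq) +
    nchar(motifs$three_prime_terminus) - 1L            # 1-based last base
  ends <- ends[ends > anchor + 1L]
  if (!length(ends))
    totiscan_error("3' terminal motif not found downstream of anchor",
                   "totiscan_motif_not_found")
  if (is.null(canonical_length_hint)) return(ends[length(ends)])
  d <- abs((ends - anchor) - canonical_length_hint)
  best <- which(d == min(d))
  if (length(best) > 1L)
    totiscan_error("two 3' termini equidistant from the canonical length hint",
                   "totiscan_ambiguous_terminus")
  ends[best]
}

#' Anchor a contig into a viral genome record
#'
#' @inheritParams find_five_prime_anchor
#' @param id,host genome metadata.
#' @param canonical_length_hint see [find_three_prime_terminus()].
#' @return [viral_genome()] with both anchors set.
#' @export
anchor_genome <- function(seq, motifs, id = "genome", host = "",
                          canonical_length_hint = motifs$canonical_length_hint) {
  seq <- normalize_seq(seq)
  a <- find_five_prime_anchor(seq, motifs)
  e <- find_three_prime_terminus(seq, motifs, a, canonical_length_hint)
  viral_genome(id, seq, a, e, host)
}

#' Partition a genome into 5'-extra / canonical / 3'-extra
#' @param genome [viral_genome()].
#' @return list with `five_extra`, `canonical`, `three_extra` strings whose
#'   concatenation is the full sequence.
#' @export
extract_regions <- function(genome) {
  stopifnot(inherits(genome, "viral_genome"))
  list(five_extra = substr(genome$seq, 1L, genome$canonical_start),
       canonical = substr(genome$seq, genome$canonical_start + 1L, genome$canonical_end),
       three_extra = substr(genome$seq, genome$canonical_end + 1L, nchar(genome$seq)))
}

#' Signed position in the three-region coordinate scheme
#'
#' Canonical positions run 1..N from the 5' G of the conserved motif;
#' 5'-extra positions count leftward from (-)1 at the base immediately
#' upstream of the motif; 3'-extra positions count rightward from (+)1 just
#' past the canonical terminus. There is no position 0.
#'
#' @param region one of `"FIVE_EXTRA"`, `"CANONICAL"`, `"THREE_EXTRA"`.
#' @param index positive integer, 1-based within the region.
#' @return object of class `signed_position`.
#' @export
signed_position <- function(region, index) {
  region <- match.arg(region, c("FIVE_EXTRA", "CANONICAL", "THREE_EXTRA"))
  index <- as.integer(index)
  if (is.na(index) || index < 1L)
    totiscan_error("signed positions are 1-based (there is no position 0)",
                   "totiscan_out_of_range")
  structure(list(region = region, index = index), class = "signed_position")
}

#' Convert a signed position to a 0-based offset on the full contig
#' @param pos [signed_position()].
#' @param genome [viral_genome()].
#' @return 0-based offset.
#' @export
signed_to_offset <- function(pos, genome) {
  stopifnot(inherits(pos, "signed_position"), inherits(genome, "viral_genome"))
  n5 <- genome$canonical_start
  nc <- genome$canonical_end - genome$canonical_start
  n3 <- nchar(genome$seq) - genome$canonical_end
  off <- switch(pos$region,
                FIVE_EXTRA = if (pos$index > n5) NA else n5 - pos$index,
                CANONICAL = if (pos$index > nc) NA else n5 + pos$index - 1L,
                THREE_EXTRA = if (pos$index > n3) NA else genome$canonical_end + pos$index - 1L)
  if (is.na(off))
    totiscan_error("signed position outside its region", "totiscan_out_of_range")
  as.integer(off)
}

#' Convert a 0-based contig offset to a signed position
#' @param offset 0-based offset on the full sequence.
#' @param genome [viral_genome()].
#' @return [signed_position()].
#' @export
offset_to_signed <- function(offset, genome) {
  stopifnot(inherits(genome, "viral_genome"))
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 0L || offset >= nchar(genome$seq))
    totiscan_error("offset outside the sequenced contig", "totiscan_out_of_range")
  if (offset < genome$canonical_start)
    signed_position("FIVE_EXTRA", genome$canonical_start - offset)
  else if (offset < genome$canonical_end)
    signed_position("CANONICAL", offset - genome$canonical_start + 1L)
  else
    signed_position("THREE_EXTRA", offset - genome$canonical_end + 1L)
}

#' Format a signed position in the literature's notation
#'
#' E.g. `G(-)170` for 5'-extra position 170, `T31` for canonical position
#' 31, `C(+)28` for 3'-extra position 28.
#'
#' @param pos [signed_position()].
#' @param genome [viral_genome()] (supplies the base letter).
#' @return character scalar.
#' @export
format_signed <- function(pos, genome) {
  off <- signed_to_offset(pos, genome)
  base <- substr(genome$seq, off + 1L, off + 1L)
  tag <- switch(pos$region, FIVE_EXTRA = "(-)", CANONICAL = "", THREE_EXTRA = "(+)")
  paste0(base, tag, pos$index)
}

#' Region length report for a set of genomes
#'
#' One row per genome with sequenced, canonical and extra-sequence lengths
#' (the layout of published genome-organization tables).
#'
#' @param genomes list of [viral_genome()] objects.
#' @return data.frame.
#' @export
region_report <- function(genomes) {
  if (!length(genomes))
    return(data.frame(genome_id = character(0), sequenced_len = integer(0),
                      canonical_len = integer(0), five_extra_len = integer(0),
                      three_extra_len = integer(0), stringsAsFactors = FALSE))
  rows <- lapply(genomes, function(g) {
    data.frame(genome_id = g$id,
               sequenced_len = nchar(g$seq),
               canonical_len = g$canonical_end - g$canonical_start,
               five_extra_len = g$canonical_start,
               three_extra_len = nchar(g$seq) - g$canonical_end,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
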