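# ORF discovery, -1 ribosomal frameshift slippery sites, GGGGAG-type
# translation re-initiation sites, Gag-Pol fusion translation and terminal
# motif checks. All reported positions are 1-based canonical coordinates
# (the signed scheme's CANONICAL region).

#' Find ATG-initiated ORFs in all three forward frames
#'
#' Every ATG with an in-frame downstream stop yields an ORF (nested starts
#' included). The ORF span includes the stop codon; the reported protein
#' excludes it.
#'
#' @param seq (+)strand nucleotide sequence.
#' @param min_aa minimum protein length (aa, stop excluded).
#' @return data.frame sorted by `start`: 0-based half-open `start`/`end`,
#'   `frame` (0/1/2) and `protein`.
#' @export
find_orfs <- function(seq, min_aa = 100L) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    starts0 <- seq.int(frame + 1L, n - 2L, by = 3L)
    if (!length(starts0)) next
    codons <- substring(seq, starts0, starts0 + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (!length(atg) || !length(stp)) next
    for (ai in atg) {
      nx <- stp[stp > ai]
      if (!length(nx)) next
      si <- nx[1]
      prot_len <- si - ai            # includes M, excludes stop
      if (prot_len < min_aa) next
      s0 <- starts0[ai] - 1L
      e0 <- starts0[si] + 2L
      out[[length(out) + 1L]] <- data.frame(
        start = s0, end = e0, frame = frame,
        protein = translate_cdna(substr(seq, s0 + 1L, e0 - 3L)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0), frame = integer(0),
                      protein = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan for -1 frameshift slippery heptamers
#'
#' Reports every (overlapping) occurrence of the given heptamers (cDNA
#' spelling: `GGATTTT` for LBC-type, `GGGTTTA` for LA-type viruses).
#'
#' @param seq canonical (+)strand.
#' @param motifs character vector of heptamers (cDNA).
#' @return data.frame: `kind` (`primary_minus1`), `site_seq`, `site_start`
#'   (1-based canonical).
#' @export
find_slippery_sites <- function(seq, motifs = c("GGATTTT", "GGGTTTA")) {
  seq <- normalize_seq(seq)
  rows <- lapply(motifs, function(m) {
    p <- fixed_matches(m, seq)
    if (!length(p)) return(NULL)
    data.frame(kind = "primary_minus1", site_seq = m, site_start = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(kind = character(0), site_seq = character(0),
                      site_start = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res[order(res$site_start), , drop = FALSE]
}

#' Scan for GGGGAG re-initiation sites in frame with the Pol domain
#'
#' Finds `GGGGAG` hexamers downstream of the Gag ORF start whose nearest
#' downstream ATG (within `atg_window` nt of the hexamer's end) exists, and
#' flags whether that ATG is in frame with the Pol domain anchor.
#'
#' @param seq canonical (+)strand.
#' @param gag_start 1-based canonical start of the Gag ORF.
#' @param pol_frame_anchor 1-based canonical position of any Pol-frame codon
#'   start (from configuration/ground truth; the Pol frame is not inferred).
#' @param atg_window how far downstream of the hexamer to look for the ATG
#'   (nt, default 30; published examples have the ATG directly adjacent).
#' @return data.frame: `kind` (`secondary_reinit`), `site_seq`,
#'   `site_start`, `reinit_atg_start` (1-based), `in_frame_with_pol`.
#' @export
find_reinitiation_sites <- function(seq, gag_start, pol_frame_anchor,
                                    atg_window = 30L) {
  seq <- normalize_seq(seq)
  occ <- fixed_matches("GGGGAG", seq)
  occ <- occ[occ > gag_start]
  rows <- lapply(occ, function(p) {
    from <- p + 6L
    win <- substr(seq, from, min(nchar(seq), from + atg_window - 1L))
    a <- fixed_matches("ATG", win)
    if (!length(a)) return(NULL)
    atg <- from + a[1] - 1L
    data.frame(kind = "secondary_reinit", site_seq = "GGGGAG", site_start = p,
               reinit_atg_start = atg,
               in_frame_with_pol = (atg - pol_frame_anchor) %% 3L == 0L,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(kind = character(0), site_seq = character(0),
                      site_start = integer(0), reinit_atg_start = integer(0),
                      in_frame_with_pol = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Translate the Gag-Pol fusion across a -1 frameshift
#'
#' Translates the Gag frame through the last complete codon ending at or
#' before the slippery heptamer's final nucleotide, then shifts back one
#' nucleotide (the ribosome re-reads the heptamer's final base) and
#' continues in the -1 frame to the next stop codon.
#'
#' @param seq canonical (+)strand.
#' @param gag one row of [find_orfs()] (the Gag ORF; 0-based half-open).
#' @param site_start 1-based canonical start of the slippery heptamer
#'   (must lie inside the Gag ORF, upstream of its stop).
#' @param site_len heptamer length (default 7).
#' @return list of class `fusion_protein`: `fusion_protein` (aa string),
#'   `shift_offset` (0-based nt offset where the first post-shift codon
#'   begins), `gag_protein`.
#' @export
fuse_gag_pol <- function(seq, gag, site_start, site_len = 7L) {
  seq <- normalize_seq(seq)
  slip_end <- site_start + site_len - 1L
  stopifnot(site_start > gag$start, slip_end <= gag$end - 3L)
  rel <- slip_end - gag$start              # nt of Gag frame covered at slip end
  n_codon <- rel %/% 3L
  prefix_end0 <- gag$start + n_codon * 3L  # 0-based exclusive
  prefix <- translate_cdna(substr(seq, gag$start + 1L, prefix_end0))
  shift0 <- prefix_end0 - 1L               # re-read last nt of the heptamer
  tail_seq <- substr(seq, shift0 + 1L, nchar(seq))
  tail_aa <- translate_cdna(tail_seq)
  stop_at <- regexpr("*", tail_aa, fixed = TRUE)
  if (stop_at == -1L)
    totiscan_error("no stop codon downstream of the -1 shift",
                   "totiscan_no_downstream_stop")
  suffix <- substr(tail_aa, 1L, stop_at - 1L)
  structure(list(fusion_protein = paste0(prefix, suffix),
                 shift_offset = shift0,
                 gag_protein = gag$protein),
            class = "fusion_protein")
}

#' Check terminal motifs and 5' AU-richness of an anchored genome
#'
#' @param genome [viral_genome()].
#' @param motifs [terminal_motif_set()].
#' @param k length of the 5' window for the A+T fraction (default 30).
#' @return list: `five_prime_motif_present`, `AU_rich_5prime_fraction`
#'   (A+T fraction of the first `k` canonical nt),
#'   `minus_strand_init_signal_present` (the (-)strand 3' signal, checked on
#'   its (+)strand image at the canonical 5' end).
#' @export
check_terminal_motifs <- function(genome, motifs, k = 30L) {
  canon <- extract_regions(genome)$canonical
  head_k <- substr(canon, 1L, k)
  at_frac <- mean(strsplit(head_k, "")[[1]] %in% c("A", "T"))
  list(five_prime_motif_present =
         startsWith(canon, motifs$five_prime_motif),
       AU_rich_5prime_fraction = at_frac,
       minus_strand_init_signal_present =
         startsWith(canon, motifs$minus_strand_init_signal))
}

#' Write ORF / slippery-site / re-initiation annotations as GFF3
#'
#' Coordinates are 1-based canonical positions (GFF3 convention).
#'
#' @param orfs [find_orfs()] result (0-based half-open; converted).
#' @param slippery [find_slippery_sites()] result.
#' @param reinit [find_reinitiation_sites()] result.
#' @param seqid sequence identifier for column 1.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(orfs, slippery, reinit, seqid, path) {
  gff_row <- function(type, start, end, attrs)
    sprintf("%s\ttotiscan\t%s\t%d\t%d\t.\t+\t.\t%s", seqid, type, start, end, attrs)
  lines <- "##gff-version 3"
  if (nrow(orfs))
    lines <- c(lines, mapply(function(s, e, f) gff_row("ORF", s + 1L, e, sprintf("frame=%d", f)),
                             orfs$start, orfs$end, orfs$frame))
  if (nrow(slippery))
    lines <- c(lines, mapply(function(p, m) gff_row("slippery_site", p, p + nchar(m) - 1L,
                                                    sprintf("motif=%s", m)),
                             slippery$site_start, slippery$site_seq))
  if (nrow(reinit))
    lines <- c(lines, mapply(function(p, a, fr)
      gff_row("reinitiation_site", p, a + 2L,
              sprintf("atg_start=%d;in_frame_with_pol=%s", a, tolower(fr))),
      reinit$site_start, reinit$reinit_atg_start, reinit$in_frame_with_pol))
  writeLines(unlist(lines), path)
  invisible(path)
}
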