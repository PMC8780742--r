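# Synthetic LBC-like genomes with planted, fully-recorded features, plus the
# compensatory-frameshift evolution simulator. Every analysis step in the
# package can be exercised offline against generator ground truth.
#
# Construction notes (see the methods vignette for rationale):
# * Planted hairpins are G-arm / A-loop / C-arm constructs: with
#   Watson-Crick(+GU) pairing and no T present, the pair-maximal nested
#   structure of the planted interval is exactly the intended stem, the
#   traceback is unambiguous, and no reading frame can gain a stop codon.
# * Extra-sequence copies are flanked by guard bases so that planted
#   self-homology matches cannot extend by chance, keeping ground-truth
#   coordinates exact.
# * Accidental occurrences of the 5' terminal hexamer in the first quarter
#   of the contig are removed by frame-safe point edits so anchoring is
#   unambiguous.

.STOPS <- c("TAA", "TAG", "TGA")
.NONSTOP_CODONS <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                             c("A","C","G","T")), 1, paste, collapse = ""),
                           .STOPS)

#' Extra-sequence specification for a genome blueprint
#'
#' Describes one extra region: total length, and an optional planted copy of
#' canonical sequence ((+) or (-) strand), random filler, or an rRNA-like
#' decoy. For (-)strand copies, `overlap` canonical nt are shared between
#' the copy and the canonical 5' end (the copy is right-aligned against the
#' canonical boundary); `offset` random nt precede a 3'-extra copy.
#'
#' @param len total extra length (nt); 0 = no extra region.
#' @param source `"none"`, `"random"`, `"plus"`, `"minus"`, `"rrna_decoy"`.
#' @param interval canonical 1-based `c(start, end)` copied (plus/minus).
#' @param overlap canonical nt included in the homologous stretch beyond the
#'   extra region (minus-source 5' copies; default 0).
#' @param offset random nt between the terminus and the copy (3' extras).
#' @param decoy_len decoy length (rrna_decoy source).
#' @param mutations substitutions planted in a decoy copy (identity < 100%).
#' @return list of class `extra_spec`.
#' @export
extra_spec <- function(len = 0L, source = c("none", "random", "plus", "minus", "rrna_decoy"),
                       interval = NULL, overlap = 0L, offset = 0L,
                       decoy_len = NULL, mutations = 0L) {
  source <- match.arg(source)
  structure(list(len = as.integer(len), source = source, interval = interval,
                 overlap = as.integer(overlap), offset = as.integer(offset),
                 decoy_len = decoy_len, mutations = as.integer(mutations)),
            class = "extra_spec")
}

#' Blueprint for a synthetic LBC-like genome
#'
#' Defaults emulate a TdV-LBCbarr-like organization: 4565-nt canonical
#' genome opening with the conserved `GAAATT` hexamer and an AU-rich 5'
#' region, a Gag ORF (nt 204-2129, downstream of the 5'-copy source region) carrying the `GGATTTT` slippery heptamer,
#' a Pol continuation in the -1 frame with a planted marker peptide and its
#' own stop, a `GGGGAG`+ATG re-initiation site in the Pol frame between the
#' Gag stop and the Pol domain, a 170-nt 5'-extra copied from the canonical
#' (-) strand (nt 31-203, 3-nt overlap: the published 173-nt geometry) and a
#' 28-nt 3'-extra copied from the (+) strand (nt 4466-4493), and two planted
#' stem-loops downstream of the Pol stop.
#'
#' @param id genome identifier.
#' @param canonical_len canonical genome length (nt).
#' @param motifs [terminal_motif_set()] (default Td-like).
#' @param gag_span 1-based inclusive nt span of the Gag ORF (stop included);
#'   length must be a multiple of 3.
#' @param slippery_pos 1-based start of the planted `GGATTTT` heptamer;
#'   must be codon-aligned with `gag_span` and inside the ORF.
#' @param reinit_pos 1-based start of the planted `GGGGAGATGA` block; the
#'   ATG (at `reinit_pos + 6`) must be in the Pol frame.
#' @param marker_pos,pol_marker Pol-frame position and nt sequence of a
#'   distinctive marker (its translation must appear in the fusion protein).
#' @param pol_stop 1-based Pol-frame position of the planted TAA.
#' @param lis_blocks list of canonical nt intervals reserved for divergence
#'   (comparator scrambling / indel placement).
#' @param five_extra,three_extra [extra_spec()] objects.
#' @param hairpins list of `list(at =, stem =, loop =, bulge = 0)` planted
#'   stem-loops (canonical 1-based `at`).
#' @param at_bias background A+T fraction (default 0.55; the first 30 nt use
#'   0.75 to emulate the AU-rich 5' region).
#' @param seed mandatory RNG seed.
#' @return list of class `genome_blueprint`.
#' @export
genome_blueprint <- function(id = "synthetic_lbc",
                             canonical_len = 4565L,
                             motifs = terminal_motif_set("GAAATT", "CCATAAGC",
                                                         canonical_length_hint = 4565L),
                             gag_span = c(204L, 2129L),
                             slippery_pos = 1998L,
                             reinit_pos = 2153L,
                             marker_pos = 3200L,
                             pol_marker = "TGGCATCACGAGCAGTGG",
                             pol_stop = 4340L,
                             lis_blocks = list(c(2400L, 2900L), c(3500L, 3800L)),
                             five_extra = extra_spec(170L, "minus",
                                                     interval = c(31L, 203L),
                                                     overlap = 3L),
                             three_extra = extra_spec(28L, "plus",
                                                      interval = c(4466L, 4493L)),
                             hairpins = list(list(at = 4360L, stem = 10L, loop = 5L),
                                             list(at = 4400L, stem = 8L, loop = 4L, bulge = 2L)),
                             at_bias = 0.55,
                             seed = 1L) {
  bp <- structure(as.list(environment()), class = "genome_blueprint")
  .validate_blueprint(bp)
  bp
}

.pol_frame_phase <- function(bp) {
  # first post-shift codon starts 1 nt before the end of the last complete
  # Gag codon covering the heptamer
  slip_end <- bp$slippery_pos + 6L
  rel <- slip_end - (bp$gag_span[1] - 1L)
  shift_start <- bp$gag_span[1] + (rel %/% 3L) * 3L - 1L  # 1-based codon start
  shift_start %% 3L
}

.validate_blueprint <- function(bp) {
  conflict <- function(msg) totiscan_error(msg, "totiscan_blueprint_conflict")
  g <- bp$gag_span
  if ((g[2] - g[1] + 1L) %% 3L != 0L) conflict("Gag span not a codon multiple")
  if (g[2] > bp$canonical_len) conflict("Gag span outside the canonical genome")
  if (bp$slippery_pos <= g[1] || bp$slippery_pos + 6L > g[2] - 3L)
    conflict("slippery site must lie inside the Gag ORF, upstream of its stop")
  if ((bp$slippery_pos - g[1]) %% 3L != 0L)
    conflict("slippery site must be codon-aligned with the Gag frame")
  if (bp$reinit_pos <= g[2] || bp$reinit_pos + 9L >= bp$pol_stop)
    conflict("re-initiation site must lie between the Gag stop and the Pol stop")
  phase <- .pol_frame_phase(bp)
  if ((bp$reinit_pos + 6L) %% 3L != phase)
    conflict("re-initiation ATG is not in the Pol frame")
  if (bp$marker_pos %% 3L != phase || (bp$pol_stop %% 3L) != phase)
    conflict("Pol marker and Pol stop must be in the Pol frame")
  if (bp$pol_stop + 2L > bp$canonical_len - nchar(bp$motifs$three_prime_terminus))
    conflict("Pol stop overlaps the 3' terminal motif")
  locked <- rbind(c(1L, 6L), c(g[1], g[1] + 2L), c(g[2] - 2L, g[2]),
                  c(bp$slippery_pos, bp$slippery_pos + 8L),
                  c(bp$reinit_pos, bp$reinit_pos + 9L),
                  c(bp$marker_pos, bp$marker_pos + nchar(bp$pol_marker) - 1L),
                  c(bp$pol_stop, bp$pol_stop + 2L),
                  c(bp$canonical_len - nchar(bp$motifs$three_prime_terminus) + 1L,
                    bp$canonical_len))
  for (h in bp$hairpins) {
    span <- 2L * h$stem + h$loop + (if (is.null(h$bulge)) 0L else h$bulge)
    he <- h$at + span - 1L
    if (h$at <= 6L || he > bp$canonical_len - nchar(bp$motifs$three_prime_terminus))
      conflict("hairpin placement outside the available canonical span")
    if (any(h$at <= locked[, 2] & he >= locked[, 1]))
      conflict("hairpin placement overlaps a planted motif")
  }
  invisible(bp)
}

# --- low-level assembly helpers -------------------------------------------

.stamp <- function(cv, at, s) {
  cv[at:(at + nchar(s) - 1L)] <- strsplit(s, "")[[1]]
  cv
}

.codon_at <- function(cv, start) paste(cv[start:(start + 2L)], collapse = "")

# mutate position p to a base that kills a motif occurrence without creating
# a stop codon in the Gag or Pol frame; returns new cv or NULL
.safe_mutate <- function(cv, p, bp, phase) {
  g <- bp$gag_span
  ok_frames <- function(cv2) {
    if (p >= g[1] && p <= g[2] - 3L) {       # inside Gag coding (stop excluded)
      cs <- g[1] + ((p - g[1]) %/% 3L) * 3L
      if (.codon_at(cv2, cs) %in% .STOPS) return(FALSE)
    }
    pol_zone <- p >= g[1] && p < bp$pol_stop
    if (pol_zone) {
      cs <- p - ((p - phase) %% 3L)
      if (cs >= 1L && cs + 2L <= length(cv2) && cs %% 3L == phase &&
          .codon_at(cv2, cs) %in% .STOPS) return(FALSE)
    }
    TRUE
  }
  for (b in sample(setdiff(c("A", "C", "G", "T"), cv[p]))) {
    cv2 <- cv; cv2[p] <- b
    if (ok_frames(cv2)) return(cv2)
  }
  NULL
}

# build one extra region; returns list(seq, map) where map[[i]] locates the
# source of extra position i: list(kind = "canon"/"pad"/"decoy", pos)
.build_extra <- function(spec, cv, side, pad, decoy = NULL) {
  n <- length(cv)
  if (spec$len == 0L || spec$source == "none")
    return(list(seq = character(0), map = list()))
  if (spec$source == "random") {
    stopifnot(length(pad) >= spec$len)
    return(list(seq = pad[seq_len(spec$len)],
                map = lapply(seq_len(spec$len), function(i) list(kind = "pad", pos = i))))
  }
  if (spec$source == "rrna_decoy") {
    chars <- c(pad[seq_len(spec$offset)], decoy)
    chars <- c(chars, pad[seq_len(spec$len - length(chars)) + spec$offset])
    map <- c(lapply(seq_len(spec$offset), function(i) list(kind = "pad", pos = i)),
             lapply(seq_along(decoy), function(i) list(kind = "decoy", pos = i)),
             lapply(seq_len(spec$len - spec$offset - length(decoy)),
                    function(i) list(kind = "pad", pos = spec$offset + i)))
    return(list(seq = chars, map = map))
  }
  s <- spec$interval[1]; e <- spec$interval[2]
  if (spec$source == "minus") {
    copy_full <- rev(chartr_vec(cv[s:e]))        # revcomp as char vector
    in_extra <- length(copy_full) - spec$overlap # trailing overlap nt sit in canonical
    copy_part <- copy_full[seq_len(in_extra)]
    pad_len <- spec$len - in_extra
    stopifnot(pad_len >= 0L)
    chars <- c(pad[seq_len(pad_len)], copy_part)
    map <- c(lapply(seq_len(pad_len), function(i) list(kind = "pad", pos = i)),
             lapply(seq_len(in_extra), function(i) list(kind = "canon", pos = e - i + 1L)))
    return(list(seq = chars, map = map))
  }
  # plus-strand copy
  copy <- cv[s:e]
  if (side == "five") {                          # left-aligned, random pad toward canonical
    pad_len <- spec$len - length(copy)
    chars <- c(copy, pad[seq_len(pad_len)])
    map <- c(lapply(seq_along(copy), function(i) list(kind = "canon", pos = s + i - 1L)),
             lapply(seq_len(pad_len), function(i) list(kind = "pad", pos = i)))
  } else {                                       # offset pad, copy, tail pad
    tail_len <- spec$len - spec$offset - length(copy)
    chars <- c(pad[seq_len(spec$offset)], copy,
               if (tail_len > 0L) pad[spec$offset + seq_len(tail_len)])
    map <- c(lapply(seq_len(spec$offset), function(i) list(kind = "pad", pos = i)),
             lapply(seq_along(copy), function(i) list(kind = "canon", pos = s + i - 1L)),
             lapply(seq_len(max(0L, tail_len)),
                    function(i) list(kind = "pad", pos = spec$offset + i)))
  }
  list(seq = chars, map = map)
}

# vectorized complement (character vector in, complemented vector out)
chartr_vec <- function(x) c(A = "T", T = "A", C = "G", G = "C", N = "N")[x]

#' Generate a synthetic LBC-like genome with ground truth
#'
#' Builds the genome described by a [genome_blueprint()] and records the
#' exact coordinates of every planted feature, so pipeline output can be
#' validated against construction truth.
#'
#' @param blueprint [genome_blueprint()].
#' @return list: `genome` ([viral_genome()] over the full contig), `truth`
#'   (named list of planted coordinates and expected analysis results),
#'   `decoy_reference` (named character, when an rRNA-like decoy is
#'   planted).
#' @export
generate_genome <- function(blueprint) {
  bp <- .validate_blueprint(blueprint)
  set.seed(bp$seed)
  n <- bp$canonical_len
  phase <- .pol_frame_phase(bp)
  g <- bp$gag_span
  cv <- strsplit(random_seq(n, bp$at_bias), "")[[1]]

  # terminal motifs and AU-rich 5' head
  cv <- .stamp(cv, 1L, bp$motifs$five_prime_motif)
  if (g[1] > 8L)
    cv[7:(g[1] - 1L)] <- strsplit(random_seq(g[1] - 7L, 0.75), "")[[1]]
  term <- bp$motifs$three_prime_terminus
  cv <- .stamp(cv, n - nchar(term) + 1L, term)

  # Gag ORF: ATG, non-stop codons, TAA
  n_codons <- (g[2] - g[1] + 1L) %/% 3L
  body <- sample(.NONSTOP_CODONS, n_codons - 2L, replace = TRUE)
  cv <- .stamp(cv, g[1], paste(c("ATG", body, "TAA"), collapse = ""))

  # slippery heptamer + safe following codon (keeps both frames open)
  cv <- .stamp(cv, bp$slippery_pos, "GGATTTT")
  cv <- .stamp(cv, bp$slippery_pos + 7L, "CC")     # Gag codon TCC after the heptamer

  # Pol-frame codons from the first boundary past the Gag stop to the stop
  first_pol <- g[2] + 1L + ((phase - (g[2] + 1L)) %% 3L)
  pol_starts <- seq.int(first_pol, bp$pol_stop - 3L, by = 3L)
  cv <- .stamp(cv, first_pol,
               paste(sample(.NONSTOP_CODONS, length(pol_starts), replace = TRUE),
                     collapse = ""))
  cv <- .stamp(cv, bp$pol_stop, "TAA")

  # repair Pol-frame stops inside the Gag tail (both frames constrained);
  # resampling a Gag codon can perturb the neighbouring Pol codon, so scan
  # to a fixed point
  shift_start <- bp$slippery_pos + 5L              # first post-shift codon (1-based)
  pol_q <- seq.int(shift_start, g[2] - 3L, by = 3L)
  guard <- 0L
  repeat {
    bad <- pol_q[vapply(pol_q, function(q) .codon_at(cv, q) %in% .STOPS, logical(1))]
    if (!length(bad)) break
    q <- bad[1]
    for (cs in unique(c(g[1] + ((q - g[1]) %/% 3L) * 3L,
                        g[1] + ((q + 2L - g[1]) %/% 3L) * 3L))) {
      if (cs <= bp$slippery_pos + 9L && cs + 2L >= bp$slippery_pos) next
      if (cs >= g[2] - 2L || cs < g[1]) next
      cv <- .stamp(cv, cs, sample(.NONSTOP_CODONS, 1L))
    }
    guard <- guard + 1L
    if (guard > 1000L) totiscan_error("frame repair failed", "totiscan_blueprint_conflict")
  }

  # re-initiation block and Pol marker
  cv <- .stamp(cv, bp$reinit_pos, "GGGGAGATGA")
  cv <- .stamp(cv, bp$marker_pos, bp$pol_marker)

  # planted hairpins: G-arm / A-loop / C-arm (+ A-bulge)
  hairpin_truth <- list()
  for (h in bp$hairpins) {
    bulge <- if (is.null(h$bulge)) 0L else h$bulge
    s1 <- ceiling(h$stem / 2); s2 <- h$stem - s1
    insert <- if (bulge > 0L)
      paste0(strrep("G", s1), strrep("G", s2), strrep("A", h$loop),
             strrep("C", s2), strrep("A", bulge), strrep("C", s1))
    else paste0(strrep("G", h$stem), strrep("A", h$loop), strrep("C", h$stem))
    cv <- .stamp(cv, h$at, insert)
    span <- nchar(insert)
    # outermost G (local 1) pairs the outermost C (local span), inward
    left <- seq_len(h$stem)
    right <- if (bulge > 0L)
      c(span - seq_len(s1) + 1L,                  # G_1..G_s1 vs trailing C-arm
        h$stem + h$loop + s2 - seq_len(s2) + 1L)  # G_s1+1..G_stem vs inner C-arm
    else span - seq_len(h$stem) + 1L
    local_pairs <- cbind(i = as.integer(left), j = as.integer(right))
    hairpin_truth[[length(hairpin_truth) + 1L]] <-
      list(at = h$at, span = span, stem = h$stem, loop = h$loop, bulge = bulge,
           local_pairs = local_pairs,
           n_loops = if (bulge > 0L) 2L else 1L)
  }

  # guard bases so planted self-homology matches cannot extend by chance
  lock <- rep(FALSE, n)
  lock_span <- function(lock, at, len) { lock[at:(at + len - 1L)] <- TRUE; lock }
  lock <- lock_span(lock, 1L, 6L)
  lock <- lock_span(lock, g[1], 3L); lock <- lock_span(lock, g[2] - 2L, 3L)
  lock <- lock_span(lock, bp$slippery_pos, 9L)
  lock <- lock_span(lock, bp$reinit_pos, 10L)
  lock <- lock_span(lock, bp$marker_pos, nchar(bp$pol_marker))
  lock <- lock_span(lock, bp$pol_stop, 3L)
  lock <- lock_span(lock, n - nchar(term) + 1L, nchar(term))
  for (h in hairpin_truth) lock <- lock_span(lock, h$at, h$span)

  fe <- bp$five_extra; te <- bp$three_extra
  if (fe$source == "minus" && fe$overlap > 0L) {
    s <- fe$interval[1]
    # the copy's canonical overlap must equal the canonical 5' head
    cv <- .stamp(cv, s, paste(rev(chartr_vec(cv[seq_len(fe$overlap)])), collapse = ""))
    lock <- lock_span(lock, s, fe$overlap)
    # guard: stop the match extending past the overlap
    p <- s - 1L
    while (chartr_vec(cv[p]) == cv[fe$overlap + 1L]) cv[p] <- sample(c("A","C","G","T"), 1L)
    lock[p] <- TRUE
  }
  if (te$source == "plus") {
    s <- te$interval[1]; e <- te$interval[2]
    # left flank: preceded in the query by the canonical terminus (offset 0)
    if (te$offset == 0L) {
      p <- s - 1L
      while (p >= 1L && cv[p] == cv[n]) cv[p] <- sample(c("A","C","G","T"), 1L)
      if (p >= 1L) lock[p] <- TRUE
    }
    # right flank only matters when random tail follows the copy (guarded on
    # the pad side during assembly below)
  }

  # random pads for extras
  pad5 <- strsplit(random_seq(max(fe$len, 1L), bp$at_bias), "")[[1]]
  pad3 <- strsplit(random_seq(max(te$len, 1L), bp$at_bias), "")[[1]]

  decoy_reference <- NULL
  decoy_chars <- NULL
  if (te$source == "rrna_decoy" || fe$source == "rrna_decoy") {
    dl <- if (is.null(te$decoy_len)) fe$decoy_len else te$decoy_len
    dec <- make_rrna_decoy(dl, seed = bp$seed + 10000L)
    decoy_reference <- stats::setNames(dec$seq, dec$record$id)
    decoy_chars <- strsplit(dec$seq, "")[[1]]
    mut_spec <- if (te$source == "rrna_decoy") te else fe
    if (mut_spec$mutations > 0L) {
      mp <- sample(seq_along(decoy_chars), mut_spec$mutations)
      for (p in mp) decoy_chars[p] <- sample(setdiff(c("A","C","G","T"), decoy_chars[p]), 1L)
    }
  }

  build <- function() {
    b5 <- .build_extra(fe, cv, "five", pad5, decoy_chars)
    b3 <- .build_extra(te, cv, "three", pad3, decoy_chars)
    list(b5 = b5, b3 = b3)
  }
  bb <- build()

  # pad-side guards so copies flanked by random filler cannot extend
  if (fe$source == "minus") {
    in_extra <- (fe$interval[2] - fe$interval[1] + 1L) - fe$overlap
    pad_len <- fe$len - in_extra
    if (pad_len > 0L) {
      e <- fe$interval[2]
      while (e + 1L <= n && pad5[pad_len] == chartr_vec(cv[e + 1L]))
        pad5[pad_len] <- sample(c("A","C","G","T"), 1L)
      bb <- build()
    }
  }
  if (fe$source == "plus" && fe$len > length(cv[fe$interval[1]:fe$interval[2]])) {
    e <- fe$interval[2]
    while (e + 1L <= n && pad5[1] == cv[e + 1L]) pad5[1] <- sample(c("A","C","G","T"), 1L)
    bb <- build()
  }
  if (te$source == "plus") {
    s <- te$interval[1]; e <- te$interval[2]
    copy_len <- e - s + 1L
    if (te$offset > 0L)
      while (s - 1L >= 1L && pad3[te$offset] == cv[s - 1L])
        pad3[te$offset] <- sample(c("A","C","G","T"), 1L)
    tail_len <- te$len - te$offset - copy_len
    if (tail_len > 0L)
      while (e + 1L <= n && pad3[te$offset + 1L] == cv[e + 1L])
        pad3[te$offset + 1L] <- sample(c("A","C","G","T"), 1L)
    bb <- build()
  }

  # remove accidental 5' hexamer occurrences from the first quarter of the contig
  motif <- bp$motifs$five_prime_motif
  for (iter in 1:40) {
    full <- paste(c(bb$b5$seq, cv, bb$b3$seq), collapse = "")
    n5 <- length(bb$b5$seq)
    occ <- fixed_matches(motif, full)
    occ <- occ[occ <= ceiling(nchar(full) * 0.25) & occ != n5 + 1L]
    if (!length(occ)) break
    o <- occ[1]
    fixed <- FALSE
    for (cp in o:(o + 5L)) {
      if (cp <= n5) {
        src <- bb$b5$map[[cp]]
        if (src$kind == "pad") {
          pad5[src$pos] <- sample(setdiff(c("A","C","G","T"), pad5[src$pos]), 1L)
          fixed <- TRUE
        } else if (src$kind == "canon" && !lock[src$pos]) {
          cv2 <- .safe_mutate(cv, src$pos, bp, phase)
          if (!is.null(cv2)) { cv <- cv2; fixed <- TRUE }
        }
      } else if (cp <= n5 + n) {
        p <- cp - n5
        if (!lock[p]) {
          cv2 <- .safe_mutate(cv, p, bp, phase)
          if (!is.null(cv2)) { cv <- cv2; fixed <- TRUE }
        }
      }
      if (fixed) break
    }
    if (!fixed)
      totiscan_error("could not disambiguate the 5' anchor", "totiscan_blueprint_conflict")
    bb <- build()
  }

  full <- paste(c(bb$b5$seq, cv, bb$b3$seq), collapse = "")
  n5 <- length(bb$b5$seq)
  genome <- viral_genome(bp$id, full, n5, n5 + n, host = "synthetic")

  truth <- list(
    canonical_len = n,
    five_extra_len = n5,
    three_extra_len = length(bb$b3$seq),
    gag = list(start = g[1] - 1L, end = g[2], frame = (g[1] - 1L) %% 3L),
    slippery_pos = bp$slippery_pos,
    reinit = list(site_start = bp$reinit_pos, atg_start = bp$reinit_pos + 6L),
    pol_frame_anchor = bp$reinit_pos + 6L,
    pol_stop = bp$pol_stop,
    marker_peptide = translate_cdna(bp$pol_marker),
    shift_offset = bp$slippery_pos + 4L,   # 0-based start of first post-shift codon
    lis_blocks = bp$lis_blocks,
    hairpins = hairpin_truth,
    five_hit = if (fe$source %in% c("plus", "minus")) list(
      strand = fe$source,
      target_start = fe$interval[1], target_end = fe$interval[2],
      length = fe$interval[2] - fe$interval[1] + 1L,
      identity = 100) else NULL,
    three_hit = if (te$source == "plus") list(
      strand = "plus",
      target_start = te$interval[1], target_end = te$interval[2],
      length = te$interval[2] - te$interval[1] + 1L,
      identity = 100) else NULL,
    decoy = if (!is.null(decoy_reference)) list(
      length = length(decoy_chars),
      mutations = te$mutations,
      offset = te$offset) else NULL)

  list(genome = genome, truth = truth, decoy_reference = decoy_reference)
}

#' Random rRNA-like decoy reference
#'
#' A synthetic stand-in for a host rRNA reference, emitted both as a
#' reference record and (by the generator) embedded in a 3'-extra region so
#' the rRNA-mapping path is testable offline.
#'
#' @param length decoy length (>= 30 nt).
#' @param seed RNG seed.
#' @return list: `seq`, `record` (id and length).
#' @export
make_rrna_decoy <- function(length, seed) {
  stopifnot(length >= 30L)
  set.seed(seed)
  list(seq = random_seq(length, at_bias = 0.5),
       record = list(id = "synthetic_18S_rRNA_decoy", length = as.integer(length)))
}

#' Scramble designated blocks to create a divergent comparator
#'
#' Replaces each block of a canonical sequence with random sequence of equal
#' length (expected residual identity ~25%), leaving the rest untouched:
#' the comparator pair then carries planted low-identity stretches at known
#' coordinates.
#'
#' @param canonical canonical sequence (string).
#' @param blocks list of 1-based `c(start, end)` intervals.
#' @param seed RNG seed.
#' @param frame_anchor optional 1-based position marking a codon start of a
#'   reading frame that must stay open: stop codons arising inside scrambled
#'   blocks in that frame are repaired.
#' @return comparator sequence (string).
#' @export
make_lis_comparator <- function(canonical, blocks, seed, frame_anchor = NULL) {
  set.seed(seed)
  cv <- strsplit(normalize_seq(canonical), "")[[1]]
  for (b in blocks)
    cv[b[1]:b[2]] <- strsplit(random_seq(b[2] - b[1] + 1L, 0.5), "")[[1]]
  if (!is.null(frame_anchor)) {
    phase <- frame_anchor %% 3L
    for (b in blocks) {
      lo <- max(1L, b[1] - 2L)             # catch stops straddling the block start
      first <- lo + ((phase - lo) %% 3L)
      for (cs in seq.int(first, min(b[2], length(cv) - 2L), by = 3L)) {
        while (paste(cv[cs:(cs + 2L)], collapse = "") %in% .STOPS)
          cv[cs:(cs + 2L)] <- strsplit(sample(.NONSTOP_CODONS, 1L), "")[[1]]
      }
    }
  }
  paste(cv, collapse = "")
}

#' Simulate compensatory-frameshift evolution of a coding sequence
#'
#' Applies point substitutions and paired frameshifting indels: each pair is
#' a primary insertion/deletion of 1-2 nt followed, within
#' `max_pair_distance` nt downstream, by a compensatory indel restoring the
#' net frame (net length change of the pair is 0 mod 3). Outside the paired
#' windows the reading frame is preserved, so the translated sequence
#' diverges only inside the windows — the mechanism proposed to explain
#' low-identity stretches whose nucleotide identity stays high.
#'
#' @param coding coding nucleotide sequence (length a multiple of 3).
#' @param sub_rate per-site substitution probability in `[0, 1]`.
#' @param n_indel_pairs number of compensated indel pairs.
#' @param max_pair_distance maximum nt between primary and compensatory
#'   indel (default 60).
#' @param blocks optional list of 1-based intervals confining the primary
#'   indels (defaults to evenly spaced disjoint segments).
#' @param seed RNG seed.
#' @return list: `derived` (string), `trace` (class `evolution_trace`:
#'   `events` in application order, `pairs` linking compensated events,
#'   `windows` = codon-aligned ancestor intervals containing each pair,
#'   `seed`).
#' @export
evolve_with_compensatory_indels <- function(coding, sub_rate = 0,
                                            n_indel_pairs = 1L,
                                            max_pair_distance = 60L,
                                            blocks = NULL, seed = 1L) {
  coding <- normalize_seq(coding)
  nc <- nchar(coding)
  if (nc %% 3L != 0L || sub_rate < 0 || sub_rate > 1)
    totiscan_error("coding length must be a codon multiple and rates in [0,1]",
                   "totiscan_parameter_error")
  set.seed(seed)
  cv <- strsplit(coding, "")[[1]]
  events <- list()

  # substitutions (ancestor coordinates, applied first)
  if (sub_rate > 0) {
    hit <- which(runif(nc) < sub_rate)
    for (p in hit) {
      nb <- sample(setdiff(c("A", "C", "G", "T"), cv[p]), 1L)
      events[[length(events) + 1L]] <- list(type = "sub", pos = p, payload = nb)
    }
  }

  # paired indels in disjoint segments (or user blocks)
  pair_links <- list(); windows <- list()
  if (n_indel_pairs > 0L) {
    if (is.null(blocks)) {
      seg <- floor(nc / n_indel_pairs)
      if (seg < max_pair_distance + 20L)
        totiscan_error("sequence too short for the requested indel pairs",
                       "totiscan_parameter_error")
      blocks <- lapply(seq_len(n_indel_pairs), function(i)
        c((i - 1L) * seg + 10L, (i - 1L) * seg + seg - max_pair_distance - 10L))
    }
    blocks <- rep(blocks, length.out = n_indel_pairs)
    indels <- list()
    for (i in seq_len(n_indel_pairs)) {
      b <- blocks[[i]]
      p1 <- sample(b[1]:b[2], 1L)
      s1 <- sample(c(-2L, -1L, 1L, 2L), 1L)
      s2 <- sample(Filter(function(x) (s1 + x) %% 3L == 0L, c(-2L, -1L, 1L, 2L)), 1L)
      p2 <- p1 + sample(5L:max_pair_distance, 1L)
      indels[[length(indels) + 1L]] <- list(pos = p1, size = s1, mate = 2L * i)
      indels[[length(indels) + 1L]] <- list(pos = p2, size = s2, mate = 2L * i - 1L)
      w1 <- ((min(p1, p2) - 1L) %/% 3L) * 3L + 1L
      w2 <- min(nc, ((max(p1, p2) + 2L + 2L) %/% 3L) * 3L)
      windows[[i]] <- c(w1, w2)
    }
    # apply right-to-left so stored positions are valid at application time
    ord <- order(-vapply(indels, function(x) x$pos, numeric(1)))
    ev_idx <- integer(length(indels))
    for (k in ord) {
      id <- indels[[k]]
      if (id$size > 0L) {
        ins <- paste(sample(c("A", "C", "G", "T"), id$size, replace = TRUE), collapse = "")
        events[[length(events) + 1L]] <- list(type = "ins", pos = id$pos, payload = ins)
      } else {
        events[[length(events) + 1L]] <- list(type = "del", pos = id$pos, payload = -id$size)
      }
      ev_idx[k] <- length(events)
    }
    for (i in seq_len(n_indel_pairs))
      pair_links[[i]] <- c(primary = ev_idx[2L * i - 1L], compensatory = ev_idx[2L * i])
  }

  trace <- structure(list(events = events, pairs = pair_links,
                          windows = windows, seed = seed),
                     class = "evolution_trace")
  list(derived = replay_trace(coding, trace), trace = trace)
}

#' Replay an evolution trace on an ancestor sequence
#'
#' Events are applied in stored order; replay on the recorded ancestor
#' reproduces the derived sequence exactly.
#'
#' @param ancestor ancestor sequence (string).
#' @param trace `evolution_trace` from [evolve_with_compensatory_indels()].
#' @return derived sequence (string).
#' @export
replay_trace <- function(ancestor, trace) {
  cv <- strsplit(normalize_seq(ancestor), "")[[1]]
  for (ev in trace$events) {
    if (ev$type == "sub") cv[ev$pos] <- ev$payload
    else if (ev$type == "ins")
      cv <- append(cv, strsplit(ev$payload, "")[[1]], after = ev$pos)
    else cv <- cv[-(ev$pos:(ev$pos + ev$payload - 1L))]
  }
  paste(cv, collapse = "")
}

#' Identity contrast inside compensated windows
#'
#' For each compensated indel-pair window, computes the nucleotide and
#' translated (amino-acid) percent identity between ancestor and derived
#' sequence over the window span.
#'
#' @param ancestor,derived sequences from
#'   [evolve_with_compensatory_indels()].
#' @param trace the matching `evolution_trace`.
#' @return data.frame: one row per window with `nt_identity`,
#'   `aa_identity` (percent).
#' @export
compare_compensated_windows <- function(ancestor, derived, trace) {
  rows <- lapply(trace$windows, function(w) {
    a <- substr(ancestor, w[1], w[2])
    d <- substr(derived, w[1], w[2])
    v <- nt_vs_aa_identity(a, d)
    data.frame(window_start = w[1], window_end = w[2],
               nt_identity = v[["nt_identity"]], aa_identity = v[["aa_identity"]])
  })
  if (!length(rows))
    return(data.frame(window_start = integer(0), window_end = integer(0),
                      nt_identity = numeric(0), aa_identity = numeric(0)))
  do.call(rbind, rows)
}

#' Write a small synthetic 12-column tabular hit file
#'
#' Emits plausible hit rows spanning the keep/reject boundary of the
#' xenolog thresholds, for exercising [filter_xenolog_hits()] offline.
#'
#' @param path output file.
#' @param seed RNG seed.
#' @return `path`, invisibly.
#' @export
write_synthetic_blast_tab <- function(path, seed = 1L) {
  set.seed(seed)
  subj <- c("synthetic_mito_coxI", "synthetic_contig_0228346", "synthetic_chr18",
            "synthetic_VV78X249912.5", "synthetic_CP017761.1", "synthetic_chrB6",
            "synthetic_chr7", "synthetic_low_id", "synthetic_short")
  pid <- c(93, 95, 93, 80, 93, 89, 85, 79, 93)
  len <- c(30, 37, 30, 54, 30, 37, 40, 500, 25)
  qs <- sort(sample(100:4000, length(subj)))
  rows <- sprintf("query\t%s\t%.1f\t%d\t%d\t0\t%d\t%d\t1\t%d\t%.2g\t%.1f",
                  subj, pid, len, pmax(0L, round(len * (1 - pid / 100))),
                  qs, qs + len - 1L, len, 10^-runif(length(subj), 5, 20),
                  len * 1.8)
  writeLines(rows, path)
  invisible(path)
}
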