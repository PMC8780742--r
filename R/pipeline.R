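# Orchestration: run every stage over a set of genomes and emit an
# organization report (sequenced/canonical/extra lengths, best self-homology
# hits, stem-loop summaries, slippery and re-initiation sites, LIS against a
# configured comparator, xenolog candidates).

#' Pipeline configuration
#'
#' @param family family key per genome (single key recycled, or named
#'   character vector keyed by genome id) into [lbc_families()].
#' @param families family definitions (default: packaged).
#' @param comparator_pairs list of `c(A, B)` genome-id pairs for LIS calling
#'   (coordinates reported on A).
#' @param hits_table optional path to a 12-column tabular hit file for
#'   xenolog filtering.
#' @param rrna_reference optional named character vector of reference
#'   sequences for extra-vs-rRNA mapping.
#' @param min_len,min_identity homology thresholds (nt, percent).
#' @param fold_window nt of proximal canonical sequence folded together
#'   with each extra sequence (default 250).
#' @param lis_mode `"aa"` (default: the Gag-Pol fusion protein track, 20-aa
#'   windows — low-identity stretches are an amino-acid-level signal) or
#'   `"nt"` (canonical nucleotide track, 50-nt windows).
#' @param lis_window window size for LIS profiles (default 20 aa / 50 nt
#'   according to `lis_mode`).
#' @return list of class `totiscan_config`.
#' @export
pipeline_config <- function(family = "lbc-td", families = lbc_families(),
                            comparator_pairs = list(), hits_table = NULL,
                            rrna_reference = NULL,
                            min_len = 20L, min_identity = 95,
                            fold_window = 250L,
                            lis_mode = c("aa", "nt"),
                            lis_window = if (match.arg(lis_mode) == "aa") 20L else 50L) {
  lis_mode <- match.arg(lis_mode)
  structure(list(family = family, families = families,
                 comparator_pairs = comparator_pairs, hits_table = hits_table,
                 rrna_reference = rrna_reference, min_len = min_len,
                 min_identity = min_identity, fold_window = fold_window,
                 lis_mode = lis_mode, lis_window = lis_window),
            class = "totiscan_config")
}

#' Annotate and translate the Gag-Pol fusion of a canonical sequence
#'
#' Takes the first ORF of at least `min_aa` codons as Gag, then tries the
#' slippery heptamers found inside it (5' to 3') until one yields a -1
#' fusion extending past the Gag stop.
#'
#' @param canon canonical (+)strand sequence.
#' @param min_aa minimum Gag length in aa (default 300).
#' @return list: `protein` (fusion aa string), `gag_start0` (0-based),
#'   `shift0` (0-based first post-shift codon offset), `n_prefix_aa`; or
#'   NULL when no Gag ORF or no productive slippery site exists.
#' @export
gag_pol_protein <- function(canon, min_aa = 300L) {
  orfs <- find_orfs(canon, min_aa = min_aa)
  if (!nrow(orfs)) return(NULL)
  gag <- orfs[1, ]
  slp <- find_slippery_sites(canon)
  slp <- slp[slp$site_start > gag$start + 3L & slp$site_start + 6L <= gag$end - 3L, ]
  for (i in seq_len(nrow(slp))) {
    fus <- tryCatch(fuse_gag_pol(canon, gag, slp$site_start[i]),
                    totiscan_error = function(e) NULL)
    if (is.null(fus)) next
    npre <- (fus$shift_offset + 1L - gag$start) %/% 3L
    if (nchar(fus$fusion_protein) > nchar(gag$protein))
      return(list(protein = fus$fusion_protein, gag_start0 = gag$start,
                  shift0 = fus$shift_offset, n_prefix_aa = npre))
  }
  NULL
}

# 1-based canonical nt offset of the first base of fusion-protein residue aa
.fusion_aa_to_nt <- function(fus, aa) {
  ifelse(aa <= fus$n_prefix_aa,
         fus$gag_start0 + (aa - 1L) * 3L + 1L,
         fus$shift0 + (aa - fus$n_prefix_aa - 1L) * 3L + 1L)
}

.best_hit_string <- function(hits) {
  if (is.null(hits) || !nrow(hits)) return("None")
  h <- hits[1, ]
  sprintf("%d nt/%.1f%% to (%s) strand [%s-%s] -> [%d-%d]",
          h$length, h$identity, if (h$target_strand == "plus") "+" else "-",
          h$query_start, h$query_end, h$target_start, h$target_end)
}

.fold_extra_window <- function(genome, which_end, window) {
  reg <- extract_regions(genome)
  canon <- reg$canonical
  if (which_end == "five") {
    if (!nchar(reg$five_extra)) return(NULL)
    seq <- paste0(reg$five_extra, substr(canon, 1L, min(nchar(canon), window)))
  } else {
    if (!nchar(reg$three_extra)) return(NULL)
    nc <- nchar(canon)
    seq <- paste0(substr(canon, max(1L, nc - window + 1L), nc), reg$three_extra)
  }
  fold(seq)
}

#' Run the full genome-organization pipeline
#'
#' For every genome: anchor, partition, map extra-sequence self-homology,
#' fold extra+proximal windows and summarize hairpins, scan slippery and
#' re-initiation sites, check terminal motifs; optionally call LIS against
#' configured comparator genomes and filter a tabular hit file with the
#' xenolog thresholds. Deterministic given inputs and configuration.
#'
#' @param seqs named character vector of full contig sequences, or a
#'   character vector of FASTA paths (each file may hold several records).
#' @param config [pipeline_config()].
#' @return list of class `organization_report`: `table` (one row per
#'   genome), `details` (per-genome module outputs), `lis` (per comparator
#'   pair), `xenologs` (filtered hit rows or NULL).
#' @export
run_all <- function(seqs, config = pipeline_config()) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    seqs <- do.call(c, lapply(unname(seqs), read_fasta))
  }
  if (!length(seqs))
    return(structure(list(table = region_report(list()), details = list(),
                          lis = list(), xenologs = NULL),
                     class = "organization_report"))
  fam_of <- function(id) {
    key <- if (length(config$family) == 1L && is.null(names(config$family)))
      config$family else config$family[[id]]
    config$families[[key]]
  }
  genomes <- list(); details <- list()
  for (id in names(seqs)) {
    motifs <- fam_of(id)
    g <- anchor_genome(seqs[[id]], motifs, id = id)
    genomes[[id]] <- g
    reg <- extract_regions(g)
    hit5 <- if (nchar(reg$five_extra))
      map_extra_to_canonical(g, "FIVE_EXTRA", config$min_len, config$min_identity)
      else NULL
    hit3 <- if (nchar(reg$three_extra))
      map_extra_to_canonical(g, "THREE_EXTRA", config$min_len, config$min_identity)
      else NULL
    rrna3 <- if (!is.null(config$rrna_reference) && nchar(reg$three_extra))
      map_to_reference(reg$three_extra, config$rrna_reference[[1]],
                       min_len = 30L, min_identity = config$min_identity)
      else NULL
    f5 <- .fold_extra_window(g, "five", config$fold_window)
    f3 <- .fold_extra_window(g, "three", config$fold_window)
    hp5 <- if (!is.null(f5)) find_hairpins(f5) else list()
    hp3 <- if (!is.null(f3)) find_hairpins(f3) else list()
    slp <- find_slippery_sites(reg$canonical)
    motif_report <- check_terminal_motifs(g, motifs)
    details[[id]] <- list(genome = g, hit5 = hit5, hit3 = hit3, rrna3 = rrna3,
                          hairpins5 = hp5, hairpins3 = hp3,
                          slippery = slp, motifs = motif_report)
  }
  tab <- region_report(genomes)
  tab$five_homology <- vapply(names(seqs), function(id)
    .best_hit_string(details[[id]]$hit5), character(1))
  tab$three_homology <- vapply(names(seqs), function(id)
    .best_hit_string(details[[id]]$hit3), character(1))
  tab$n_hairpins_5 <- vapply(names(seqs), function(id)
    length(details[[id]]$hairpins5), integer(1))
  tab$n_hairpins_3 <- vapply(names(seqs), function(id)
    length(details[[id]]$hairpins3), integer(1))
  tab$n_slippery <- vapply(names(seqs), function(id)
    nrow(details[[id]]$slippery), integer(1))
  rownames(tab) <- NULL

  lis <- list()
  for (pr in config$comparator_pairs) {
    a <- extract_regions(genomes[[pr[1]]])$canonical
    b <- extract_regions(genomes[[pr[2]]])$canonical
    if (config$lis_mode == "aa") {
      fa <- gag_pol_protein(a); fb <- gag_pol_protein(b)
      if (is.null(fa) || is.null(fb)) {
        lis[paste(pr, collapse = "|")] <- list(NULL)
        next
      }
      aln <- global_align(fa$protein, fb$protein, scoring_scheme("protein"))
    } else {
      aln <- global_align(a, b, scoring_scheme("nucleotide"))
    }
    prof <- windowed_identity(aln, config$lis_window)
    stretches <- detect_lis(prof)
    if (nrow(stretches)) {
      stretches$span_identity <- vapply(seq_len(nrow(stretches)), function(i)
        span_identity(aln, stretches$start_a[i], stretches$end_a[i]), numeric(1))
      if (config$lis_mode == "aa") {
        stretches$start_nt <- .fusion_aa_to_nt(fa, stretches$start_a)
        stretches$end_nt <- .fusion_aa_to_nt(fa, stretches$end_a) + 2L
      }
    }
    lis[[paste(pr, collapse = "|")]] <- stretches
  }
  xen <- if (!is.null(config$hits_table))
    filter_xenolog_hits(read_blast_tab(config$hits_table)) else NULL
  structure(list(table = tab, details = details, lis = lis, xenologs = xen),
            class = "organization_report")
}

#' Write an organization report's main table as TSV
#'
#' Identities are formatted with one decimal inside the homology summary
#' strings; output is byte-stable for identical inputs.
#'
#' @param report [run_all()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  write.table(report$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
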