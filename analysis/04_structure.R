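#!/usr/bin/env Rscript
# Secondary structure of the genome ends: fold each extra sequence together
# with proximal canonical sequence, report hairpins (stems, loops,
# palindromes) and search for kissing-loop complementarity between hairpin
# loops. Writes a hairpin table and dot-bracket strings.

suppressMessages(library(totiscan))
seqs <- read_fasta("results/genomes.fasta")
fams <- lbc_families()
family_of <- c(td1 = "lbc-td", td2 = "lbc-td", sc1 = "lbc-sc")

rows <- list(); db_lines <- character(0)
for (id in names(seqs)) {
  g <- anchor_genome(seqs[[id]], fams[[family_of[[id]]]], id = id)
  reg <- extract_regions(g)
  nc <- nchar(reg$canonical)
  windows <- list()
  if (nchar(reg$five_extra))
    windows$five <- paste0(reg$five_extra, substr(reg$canonical, 1, 250))
  if (nchar(reg$three_extra))
    windows$three <- paste0(substr(reg$canonical, nc - 249, nc), reg$three_extra)
  for (end in names(windows)) {
    w <- windows[[end]]
    st <- fold(w)
    db_lines <- c(db_lines, sprintf(">%s_%s_end", id, end), w, dot_bracket(st))
    hps <- find_hairpins(st, min_stem = 4L)
    pal <- find_palindromes(w)
    kp <- find_kissing_pairs(hps, w, min_run = 5L)
    for (h in hps)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = id, end = end, outer_start = h$outer[1], outer_end = h$outer[2],
        stem_pairs = nrow(h$stem_pairs), n_loops = length(h$loops),
        pseudo_energy = h$score)
    cat(sprintf("%s %s' end: %d hairpins (stem >= 4), %d palindromes >= 6 nt, %d kissing pairs\n",
                id, if (end == "five") "5" else "3", length(hps), nrow(pal), nrow(kp)))
  }
}
hairpins <- do.call(rbind, rows)
write.table(hairpins, "results/hairpins.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(db_lines, "results/structures.dbn")
cat("\nLargest stem per genome end:\n")
agg <- aggregate(stem_pairs ~ genome_id + end, hairpins, max)
print(agg)
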