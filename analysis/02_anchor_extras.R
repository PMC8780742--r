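#!/usr/bin/env Rscript
# Anchor each simulated contig on its family's terminal motifs, partition it
# into 5'-extra / canonical / 3'-extra, and map the extra sequences against
# the canonical (+)/(-) strands and the rRNA-like reference. Writes the
# region table and homology hits under results/.

suppressMessages(library(totiscan))
seqs <- read_fasta("results/genomes.fasta")
fams <- lbc_families()
family_of <- c(td1 = "lbc-td", td2 = "lbc-td", sc1 = "lbc-sc")
decoy <- read_fasta("results/rrna_decoy.fasta")

genomes <- lapply(names(seqs), function(id)
  anchor_genome(seqs[[id]], fams[[family_of[[id]]]], id = id))
names(genomes) <- names(seqs)
regions <- region_report(genomes)
write.table(regions, "results/regions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

hits <- list()
for (id in names(genomes)) {
  for (side in c("FIVE_EXTRA", "THREE_EXTRA")) {
    h <- tryCatch(map_extra_to_canonical(genomes[[id]], side),
                  totiscan_empty_region = function(e) NULL)
    if (!is.null(h) && nrow(h)) hits[[length(hits) + 1L]] <- cbind(genome_id = id, h)
  }
  r <- map_to_reference(extract_regions(genomes[[id]])$three_extra, decoy[[1]],
                        min_len = 30L, min_identity = 95)
  if (nrow(r))
    cat(sprintf("%s 3'-extra carries an rRNA-like stretch: %d nt at %.1f%% identity\n",
                id, r$length[1], r$identity[1]))
}
hits <- do.call(rbind, hits)
write.table(hits, "results/self_homology.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("\nRegion lengths:\n"); print(regions)
cat("\nBest self-homology per genome/end:\n")
print(hits[!duplicated(hits[c("genome_id", "query_region")]),
           c("genome_id", "query_region", "target_strand", "length", "identity",
             "query_start", "query_end", "target_start", "target_end")])
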