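#!/usr/bin/env Rscript
# Simulate the study genome set: two Td-LBCbarr-like genomes and one
# Sc-LBC-like genome whose extra-sequence geometries mirror the published
# organization table (170/28-nt extras with a 173-nt minus-strand
# self-homology; 219/331-nt extras; 143-nt plus-strand copy plus an
# rRNA-like 3' carryover). Writes FASTA, the decoy reference, ground truth
# and a synthetic tabular hit file under results/.

suppressMessages(library(totiscan))
dir.create("results", showWarnings = FALSE)
seed <- 20260901L

sims <- list(
  td1 = generate_genome(genome_blueprint(id = "td1", seed = seed + 1L)),
  td2 = generate_genome(genome_blueprint(
    id = "td2", seed = seed + 2L,
    five_extra = extra_spec(219L, "minus", interval = c(31L, 181L), overlap = 3L),
    three_extra = extra_spec(331L, "plus", interval = c(3175L, 3481L), offset = 24L))),
  sc1 = generate_genome(genome_blueprint(
    id = "sc1", seed = seed + 3L, canonical_len = 4615L,
    motifs = terminal_motif_set("GAATTT", "CTACGCG", canonical_length_hint = 4615L),
    reinit_pos = 2324L,
    five_extra = extra_spec(143L, "plus", interval = c(65L, 159L)),
    three_extra = extra_spec(213L, "rrna_decoy", offset = 12L,
                             decoy_len = 201L, mutations = 1L))))

write_fasta(vapply(sims, function(s) s$genome$seq, character(1)),
            "results/genomes.fasta")
write_fasta(sims$sc1$decoy_reference, "results/rrna_decoy.fasta")
write_synthetic_blast_tab("results/hits.tsv", seed = seed + 4L)
truth <- lapply(sims, `[[`, "truth")
jsonlite::write_json(truth, "results/ground_truth.json", auto_unbox = TRUE,
                     digits = NA, null = "null")

cat("Simulated", length(sims), "genomes:\n")
for (nm in names(sims))
  cat(sprintf("  %s: %d nt sequenced (%d canonical, 5'-extra %d, 3'-extra %d)\n",
              nm, nchar(sims[[nm]]$genome$seq), sims[[nm]]$truth$canonical_len,
              sims[[nm]]$truth$five_extra_len, sims[[nm]]$truth$three_extra_len))
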