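---
title: "Genome organization analysis of yeast dsRNA LBC totiviruses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome organization analysis of yeast dsRNA LBC totiviruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(totiscan)
```

## The biological problem

Killer yeasts of *Saccharomyces cerevisiae* (Sc) and *Torulaspora
delbrueckii* (Td) carry cytoplasmic double-stranded RNA totiviruses. A large
helper virus (V-LA or V-LBC, ~4.6 kb) encodes the coat protein (Gag) and an
RNA-dependent RNA polymerase (RdRp, "Pol") expressed as a Gag-Pol fusion via
−1 ribosomal frameshifting at a slippery heptamer (`GGAUUUU` in LBC-type
viruses, `GGGUUUA` in LA-type). A smaller satellite virus (V-M) encodes the
killer toxin and borrows the helper's capsid and polymerase.

Full-length contigs of LBC genomes assembled from high-throughput sequencing
are longer than the canonical genome: *extra sequences* flank the conserved
terminal motifs (the 5' hexamer `GAATTT` in Sc-LBC / `GAAATT` in Td-LBCbarr,
and a family-specific 3' terminus such as `CTACGCG` or `CCATAAGC`). This
package implements the full organization analysis of such genomes:

1. **Anchoring** — locate the canonical ends, partition a contig into
   5'-extra / canonical / 3'-extra, and expose the literature's signed
   coordinate scheme (canonical 1..N from the 5' G; (−)k upstream; (+)k
   downstream; no position 0).
2. **Identity** — global pairwise alignment (affine gaps), windowed identity
   profiles, and low-identity-stretch (LIS) calling.
3. **Frameshift** — ORFs, slippery sites, `GGGGAG`+ATG translation
   re-initiation sites, and Gag-Pol fusion translation across the −1 shift.
4. **Homology** — self-homology of extra sequences against the canonical
   (+)/(−) strands, mapping against user references (rRNA), and xenolog
   filtering of tabular search hits (identity ≥ 80%, length ≥ 30 nt).
5. **RNA structure** — nested-pairing (Nussinov) folding, hairpin and
   palindrome reporting, kissing-loop search.
6. **Simulation** — a genome generator that plants every feature above with
   recorded ground truth, and a compensatory-frameshift evolution model.

## Coordinates

Internally every sequence is 0-based half-open cDNA (`U` normalized to `T`
on input); the signed 1-based scheme exists only at the presentation layer
(`signed_position()`, `format_signed()`), which avoids off-by-one drift
between modules. Reports print positions like `G(-)170`, `T31`, `C(+)28`.

## Anchoring rules

The 5' anchor is the occurrence of the family hexamer; if it occurs more
than once in the first quarter of the contig, the occurrence maximizing
downstream ORF coverage wins, then the leftmost (published genomes assume
uniqueness; the tie rule only guarantees determinism). The 3' terminus is
chosen by proximity to a per-family canonical length hint (4615 nt for
Sc-LBC, 4565 nt for TdV-LBCbarr); equidistant candidates are an error rather
than a guess, and without a hint the last occurrence is used. How the
canonical 3' end of a brand-new virus family would be fixed de novo is not
derivable from sequence alone, so the hint is a required configuration
input. Ambiguity codes (N) never match a motif.

## Alignment and identity

Nucleotide scoring follows the linear desktop-aligner convention the
original analyses used — mismatch 2, gap open 4, gap extend 1 — with the
(unstated) match bonus set to +2; protein scoring is BLOSUM62 with gap open
11 / extend 1 (community defaults; the source analyses do not state protein
gap costs). A length-L gap costs `open + L·extend`. The DP itself is
delegated to `Biostrings::pairwiseAlignment`, whose gap convention was
verified against an exhaustive enumeration oracle before freezing; its
traceback is deterministic. Stops (`*`) translate and align as ordinary
symbols.

Percent identity needs a denominator, which published analyses rarely state.
The default counts all alignment columns excluding terminal overhangs, with
internal gaps as mismatches; a shorter-sequence rule is selectable. Windowed
profiles anchor windows to ungapped A-coordinates (50 nt or 20 aa windows,
step 1); a window's value is the number of match columns over its span
divided by the window size, so insertions in B count against identity.

### Why LIS calling runs on the protein track

An LIS is a maximal run of windows below 50% identity (runs separated by
fewer than half a window merge; merged spans shorter than one window drop).
A practical finding governs the default: under the nucleotide scoring
above, *optimal gapped alignment of mutually random nucleotide blocks
plateaus at ~47–50% windowed identity* — the aligner buys matches with cheap
gap extensions — so the 50% threshold barely discriminates random divergence
at the nucleotide level. At the amino-acid level random identity stays near
10–25% even after gapped alignment. The published LIS boundaries are
amino-acid coordinates for the same reason. The pipeline therefore calls LIS
on the Gag-Pol fusion protein by default (20-aa windows), mapping the
boundaries back to canonical nucleotide coordinates through the fusion
geometry; a nucleotide mode remains available
(`pipeline_config(lis_mode = "nt")`).

## Frameshift conventions

An ORF is any ATG with an in-frame downstream stop (nested starts included);
the span includes the stop, the protein excludes it. The −1 shift point
follows a documented convention the source analyses leave open: translation
proceeds through the last complete codon ending at or before the heptamer's
final nucleotide, then the ribosome re-reads that final base — the next
codon starts one position back. A hand-translated 27-nt construct pins this
down in the tests. Re-initiation sites are `GGGGAG` hexamers whose nearest
downstream ATG (within 30 nt; published examples are adjacent) is checked
for frame against a configured Pol anchor — the module deliberately does not
infer RdRp motifs.

## Self-homology and xenolog thresholds

Published self-homology stretches are 99–100% identity, so the matching
kernel is exact k-mer seeding (k = 15) with same-diagonal chaining across
pure mismatch columns; no indels are modelled. Queries are the extra
sequence plus 10 nt of adjoining canonical sequence, because the published
173-nt stretch runs 3 nt into the canonical 5' end. Hits on the (−) strand
are reported in (+)-strand coordinates, matching the published notation
(`[T31–C203] in the (+)RNA strand`). Xenolog filtering reads the classic
12-column tabular dialect; the thresholds are applied inclusively
(≥ 80%, ≥ 30 nt) because reported hits sit exactly at 30 nt and 80%, with a
strict (>) mode behind a flag since the methods prose says "above".

## RNA structure model

Thermodynamic folding energies of the original analyses are *not*
reproduced: the folder is a Nussinov base-pair-maximization DP (GU wobble
allowed, minimum loop 3, deterministic leftmost-first traceback), and a
simple stacking pseudo-energy (GC 3, AU 2, GU 1 per stack, averaged) is used
only to rank hairpins. Acceptance is on structure topology — stem and loop
layout — never on energy values. Hairpins are maximal single-child chains of
pairs ending in a hairpin loop, reporting each unpaired run ("two contiguous
loops" = hairpin loop + bulge). Palindromes are maximal even-length
intervals equal to their own reverse complement. Kissing-loop search looks
for antiparallel Watson–Crick runs (default ≥ 5 nt) between unpaired loop
positions of hairpin pairs. Folding windows are each extra sequence plus
250 nt of proximal canonical sequence. The DP is cubic; windows of a few
hundred nt fold in well under a second, and the hard cap is 5000 nt.

## The synthetic genome generator

`generate_genome(genome_blueprint())` builds a Td-like genome and records
ground truth for every planted feature. Default study conditions:

* canonical length 4565 nt (Td-like; the Sc-like blueprints in the analysis
  scripts use 4615 nt), background A+T 0.55, the first 30 nt at A+T 0.75 to
  emulate the AU-rich 5' region;
* Gag ORF at nt 204–2129 — downstream of nt 31–203, which is reserved as the
  source of the 5'-extra copy; the published geometry stamps canonical
  nt 31–33 as the reverse complement of the 5' head, which would collide
  with a Gag start placed at nt 30;
* `GGATTTT` slippery heptamer at nt 1998 (codon-aligned), Pol continuation
  in the −1 frame kept stop-free to a planted TAA at nt 4340, with a marker
  peptide at nt 3200 whose translation must surface in the fusion;
* `GGGGAGATGA` re-initiation block at nt 2153 with the ATG in the Pol frame;
* a 170-nt 5'-extra copied from the canonical (−) strand nt 31–203 with a
  3-nt canonical overlap (the published 173-nt, 100% geometry) and a 28-nt
  3'-extra copied from the (+) strand nt 4466–4493;
* two stem-loops planted between the Pol stop and the 3' terminus.

Three construction devices keep ground truth *exact* rather than
approximate. Planted hairpins are G-arm/A-loop/C-arm constructs: with no T
present, the pair-maximal nested structure of the planted interval is
provably the intended stem, the traceback is unique, and no reading frame
can gain a stop codon. Every planted sequence copy is flanked by guard bases
chosen so a perfect match cannot extend by chance, keeping hit coordinates
exact across seeds. Accidental occurrences of the 5' hexamer in the first
quarter of the contig are removed by frame-safe point edits (mapped back
through the extra-sequence copy when necessary), so anchoring is never
ambiguous. Because the Gag and Pol frames overlap in the Gag tail, stop
removal there runs to a fixed point — resampling a Gag codon can perturb the
neighbouring Pol codon.

What the generator does **not** emulate: phylogenetically realistic
substitution processes (no codon model, no transition/transversion bias),
assembly artefacts, sequencing error, or genuine thermodynamic RNA
structure. Passing tests therefore demonstrate that the pipeline recovers
the organizational features it models, not that it would resolve every
ambiguity of real HTS contigs.

## The compensatory-frameshift simulator

`evolve_with_compensatory_indels()` embodies the explanatory model for the
low-identity stretches: a primary 1–2-nt indel shifts the reading frame and
a compensatory indel within `max_pair_distance` (default 60 nt; the
replicate analyses use 150 nt) restores it, net length change 0 mod 3 per
pair. Substitutions are uniform per site. Events replay exactly on the
ancestor; outside the paired windows the frame — and, absent substitutions,
the translation — is untouched. `compare_compensated_windows()` then
measures the model's signature: inside compensated windows nucleotide
identity stays high (≈90% at the default 2% substitution rate) while
amino-acid identity collapses (≈10–15%), the direction tested by a one-sided
sign test across replicates.

## Problem sizes and tolerances

The test suite validates every kernel against an independent oracle:
exhaustive alignment-path enumeration on all {A,C} pairs up to 2 nt plus an
independently written three-state affine DP on **all** pairs up to 6 nt over
{A,C} and up to 5 aa over {A,R}; a memoised max-pairing recursion against
the folder on all ACGT sequences up to 6 nt plus 800 random sequences up to
12 nt; a quadratic interval scan against the palindrome finder on 100 random
300-mers; 10^4 signed-coordinate round trips; the fusion-prefix property on
100 generated genomes; exact planted-feature recovery on 50 seeded
blueprints with LIS boundary error bounded by one window (20 aa = 60 nt);
and a 200-replicate sign test (p < 0.01) for the compensatory-frameshift
direction. These sizes are the package's chosen balance between exhaustive
coverage and a test suite that runs in minutes on one CPU.

## Known limitations

* The pairmax folder ranks but does not estimate stability; published ΔG
  values are treated as labels, not targets.
* The homology kernel does not model indels, by design — it targets the
  99–100% identity class of hits the organization analysis reports.
* Anchoring requires per-family motif configuration; it cannot discover a
  new family's terminal motifs.
* Nucleotide-level LIS calling is threshold-marginal (see above); protein
  mode is the supported default.
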