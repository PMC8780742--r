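Package: totiscan
Title: Genome Organization Analysis for Yeast dsRNA LBC Totiviruses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse the genome organization of yeast double-stranded
    RNA LBC totiviruses from full-length (+)strand contigs: anchoring of
    canonical genome ends on conserved terminal motifs with the signed
    coordinate scheme used for 5'/3' extra sequences; global pairwise
    alignment with sliding-window percent-identity profiles and low-identity
    stretch (LIS) calling; ORF, -1 ribosomal frameshift slippery-site and
    translation re-initiation site annotation with Gag-Pol fusion
    translation; self-homology mapping of extra sequences against the
    canonical (+)/(-) strands and xenolog filtering of tabular search hits;
    Nussinov-style RNA secondary structure prediction with hairpin,
    palindrome and kissing-loop reporting; and a synthetic genome generator
    plus a compensatory-frameshift indel simulator that provide fully
    annotated fixtures for every analysis step.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
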