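Package: ciliateCUB
Title: Codon Usage Bias Analysis for Ciliate Macronuclear Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing synonymous codon usage bias in coding-sequence
    collections, with first-class support for the non-standard nuclear genetic
    codes of ciliates (NCBI translation tables 6 and 10). Provides coding-sequence
    quality filtering, per-gene composition indices (GC, GC1/GC2/GC3, GC12, GC3s,
    A3s/T3s/C3s/G3s), Wright's effective number of codons (ENC) with the expected
    ENC-GC3 curve, relative synonymous codon usage (RSCU), parity-rule-2 and
    neutrality-plot analyses, optimal-codon determination from high- and low-bias
    gene deciles, cross-species RSCU matrices with distance-based clustering trees,
    CRISPR/Cas9 NGG PAM-site scanning with optimal-codon transgene rewriting, and a
    synthetic CDS generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
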