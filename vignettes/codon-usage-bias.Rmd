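---
title: "Codon usage bias in ciliate macronuclear genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias in ciliate macronuclear genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliateCUB)
```

## The problem

Synonymous codons are not used uniformly. In ciliate macronuclear (MAC)
genomes this codon usage bias (CUB) is shaped by two forces that the field
routinely tries to separate: directional mutation pressure (which drags the
whole genome's base composition, most visibly at third codon positions) and
translational selection (which favours particular synonymous codons in highly
expressed genes). Ciliates add a twist: most use non-standard nuclear genetic
codes. Under NCBI translation table 6 (ciliate/hypotrich nuclear) TAA and TAG
encode glutamine and only TGA stops; under table 10 (euplotid nuclear) TGA
encodes cysteine. Every downstream statistic — synonymous-family structure,
GC3s, RSCU, the effective number of codons — changes with the table, so the
package treats the genetic code as a first-class object
(`genetic_code(1 | 6 | 10)`).

This package implements the full desk workflow: CDS quality control,
per-gene composition indices, ENC with its expected-GC3 curve, parity-rule-2
(PR2) and neutrality analyses, correlation matrices, optimal-codon
determination from high/low-bias gene tails, cross-species RSCU matrices and
clustering trees, plus two CRISPR/Cas9 support steps (NGG PAM scanning and
optimal-codon rewriting of a transgene). A synthetic CDS generator with
exhaustive ground truth validates every stage.

## Quality filtering

`filter_cds()` keeps "perfect" CDSs: unambiguous bases, length a multiple of
3, ATG start, a terminal TAA/TAG/TGA, no internal stop codon of the working
genetic code, and length strictly greater than 300 nt. Exact duplicates and
exact reverse-complement duplicates are removed, keeping the first
occurrence.

Design choices worth spelling out:

* **Duplicate checks run before the structural rules**, on the raw
  sequences. The reverse complement of a valid CDS necessarily starts with
  the complement of a stop codon, so checking duplicates last would relabel
  every reverse-complement copy as a bad-start rejection and hide its
  origin. Deduplication is collection cleanup, not sequence validation.
* **The terminal-stop rule uses the universal triplet set** {TAA, TAG, TGA}
  regardless of the working table: ciliate CDS records conventionally end in
  one of these even where the table reassigns it (a table-6 gene ending in
  TAA terminates by context in vivo). Internal-stop detection, by contrast,
  respects the working code: TAA inside a table-6 gene is glutamine, not an
  error.
* **Two internal-stop conventions coexist in practice**: rejecting the gene
  (`internal_stop_mode = "reject"`, the default — strict and conservative)
  or excising the offending codon in frame (`"delete_codon"`), with the
  event logged. Both are exposed because published pipelines are not
  consistent about which they used; the excision mode changes the length
  test (applied after excision) but not the reading frame.
* **Records containing N are rejected** rather than imputed; every
  downstream count assumes unambiguous codons.
* `min_len = 300` is strict ("more than 300 bp"), and one primary reason is
  reported per rejected record in a fixed order, so reports are
  deterministic.

## Composition indices

`count_codons()` counts in-frame codons of a filtered CDS, excluding the
terminal stop and including the start ATG (as Met).
`composition_profiles()` then computes, per gene: overall base fractions and
GC; positional GC1/GC2/GC3 over all counted codons; GC12 = (GC1 + GC2)/2;
and the synonymous third-position statistics GC3s and A3s/T3s/C3s/G3s,
computed only over codons of families with degeneracy ≥ 2 (Met, Trp and
stops excluded — the CodonW convention). Undefined values (a gene with no
synonymous-family codons) are NA, never silently zero.

X3s has no universally agreed denominator. The default here divides the
third-position count of base X by the total number of synonymous-family
codons, so A3s + T3s + C3s + G3s = 1 — a normalized, testable definition.
The historical CodonW variant (per-base denominators restricted to families
that offer base X at the third position) is available via
`composition_profiles(..., x3s = "codonw")`.

## Effective number of codons

`enc()` implements Wright's estimator. Per family with degeneracy k ≥ 2 and
n observed codons, codon homozygosity is

F = (n · Σ p² − 1) / (n − 1),

with p the within-family proportions. Families with n < 2 or F ≤ 0 are
excluded from their degeneracy-class average (the F ≤ 0 test uses a 1e-12
rounding guard, since an all-singleton family lands at exactly 0 only in
exact arithmetic). ENC is then

ENC = N₁ + Σ_k (number of k-fold families) / (mean F of the k-fold class),

where N₁ counts 1-fold families. A missing 3-fold class mean is imputed as
the average of the 2-fold and 4-fold means (Wright's rule); if any other
class mean is missing, ENC is reported NA. The result is capped to
[2, sense-codon count] — 61 for table 1, 63 for table 6, 62 for table 10.
Maximal bias (one codon per family) gives exactly 20 under the standard
code; uniform usage approaches the cap.

The null expectation under third-position composition alone is

ENC_expected = 2 + GC3 + 29 / (GC3² + (1 − GC3)²),

and `enc_plot_table()` tabulates observed/expected ratios. A genome whose
usage is shaped only by composition scatters around ratio 1; sustained
ratios well below 1 indicate selection beyond composition.

## RSCU, PR2, neutrality, correlations

`rscu()` computes k · count / family-total per codon; family sums equal the
degeneracy whenever the family is observed. `pr2_points()` plots
A3/(A3 + T3) against G3/(G3 + C3) over third positions of counted codons
(stops excluded); (0.5, 0.5) is intra-strand parity. The default uses all
third positions because that is the common reading of "the third base";
`site_set = "fourfold_third"` restricts to fourfold-degenerate families,
Sueoka's original site choice, which removes the amino-acid-composition
signal at the cost of fewer sites. `neutrality_fit()` regresses GC12 on
GC3s by OLS with a Pearson correlation (two-sided); the slope is the usual
mutation-vs-selection indicator. `correlation_matrix()` reports pairwise
Pearson (or Spearman) correlations with two-sided p-values over
pairwise-complete genes.

## Optimal codons

`optimal_codons()` ranks genes by ENC ascending — ENC is the package's (and
the source workflow's) only per-gene bias statistic, so low ENC defines the
high-bias tail. Tails are ⌈0.10 · n⌉ genes (minimum 2; ties at the boundary
broken by gene id, lexicographically, and logged). Counts are pooled within
each tail, RSCU computed on the pools, and ΔRSCU = RSCU(high) − RSCU(low).
Codons with ΔRSCU strictly above 0.08 are called optimal; the stricter
convention that additionally requires RSCU(high) > 1 is available via
`require_high_rscu_gt1 = TRUE` but off by default, reproducing the plain
threshold rule. Genes with undefined ENC cannot be ranked and are dropped
with a message. `shared_optimal_codons()` intersects per-species optimal
sets.

### A tail-selection artifact worth knowing about

When per-gene ENC differences are mostly sampling noise (a homogeneous
population), the ENC-top "low-bias" tail is selected for *looking* uniform,
which systematically deflates every majority codon's RSCU in the low pool.
On synthetic data this inflates ΔRSCU of completely unbiased families by
0.06–0.17 — above the 0.08 threshold — regardless of gene length. A
composition-matched contrast (pooling by the generator's true bias flags)
shows no such excess (max |ΔRSCU| ≈ 0.04 at the scales below). Two
consequences: per-species optimal sets should be expected to carry
composition- and selection-artifact passengers, and intersecting across
many species — as the workflow does — is what makes the shared set
trustworthy. The package's tests check designated-codon recovery through
the real ENC-tail path, cleanliness through the matched contrast, and
exact shared-set recovery through the nine-species intersection.

## Cross-species comparison

`pooled_rscu_matrix()` pools counts per species and carries codons that are
stops under one code as missing for that species (TAA is a Gln codon for a
table-6 species, missing for table 1). `rscu_distance()` computes Euclidean
(default) or Manhattan distances over pairwise-shared codon columns, with
the summed difference rescaled by total/shared columns so pairs with
different overlap remain comparable; pairs sharing fewer than 10 columns
are refused. `build_tree()` produces UPGMA (default; ultrametric) or
neighbour-joining trees as Newick with branch lengths. Labels are sorted
lexicographically before clustering so tied merges resolve deterministically
to the first pair in label order. UPGMA on Euclidean RSCU distance is the
simplest defensible default for a usage-similarity dendrogram; it is a
phenogram of codon usage, not a phylogeny, and no bootstrap support is
computed.

## CRISPR support

`scan_pam_sites()` reports every 20-nt protospacer immediately followed by
NGG, on both strands; minus-strand sites carry plus-strand coordinates
(0-based leftmost protospacer base) with sequences in minus orientation.
Windows containing N are skipped and counted. No guide scoring or
off-target search is attempted — scanning and PAM tallying only.
`optimize_codons()` rewrites a CDS so that every codon whose amino acid has
a designated optimal codon becomes that codon; the start and terminal stop
are never touched, the amino-acid sequence is invariant by construction,
and the operation is idempotent. A preference table may name at most one
target codon per synonymous family; an `optimal_codon_report` resolves
multiple optimal codons in one family to the largest ΔRSCU.

## The synthetic generator

`generate_cds()` emulates the statistical structure the analyses assume:

* **Per-gene GC3 targets** are normal across genes (clamped to
  [0.02, 0.98]). Defaults: mean 0.30, sd 0.12. The sd mirrors the very wide
  per-genome GC3s ranges seen in AT-rich ciliate MAC genomes (ranges
  spanning 40–70 percentage points, i.e. an across-gene sd on the order of
  0.1); the mean sits in the AT-rich regime.
* **Body lengths** are uniform over 150–600 codons (about 450–1800 bp),
  typical protein-coding lengths above the 300-bp QC floor.
* **The neutrality coupling** sets each gene's GC12 target as
  slope · GC3-target + intercept + N(0, noise_sd) (defaults 0.40, 0.22,
  0.02). Amino-acid families are drawn from a background distribution
  (uniform over families by default, keeping family sample sizes balanced
  for ENC stability) under an exponential tilt solved per gene so the
  expected first/second-position GC matches the target; the achieved GC12
  and GC3s are recorded in the truth table.
* **Codon choice within a family** has weight ∝ (third-position base weight
  implied by the gene's GC3 target) × exp(s) for designated optimal codons
  in biased genes. The first `round(bias_fraction · n)` genes are biased
  (defaults: fraction 0.15, s = 2 — roughly 7-fold within-family odds,
  a strong but realistic preference).
* Every gene gets an ATG start and a stop valid under the chosen code, so
  the output passes strict filtering by construction; an emission ledger
  (64-codon counts, start included, terminal stop excluded) is conserved
  exactly against `count_codons()`.

Because the GC12 target derives from the gene's *target* (not realized) GC3,
the regression of observed GC12 on observed GC3s is attenuated by the
per-gene sampling variance of GC3s — about 4–6% at these lengths and
spreads, so a true coupling of 0.40 is recovered near 0.38. The recovery
checks use a ±0.05 band around the true slope, which comfortably absorbs
this known attenuation without hiding a real failure.

`nine_species_scenario()` builds nine AT-rich sets with GC3 means from 0.18
to 0.40 (eight species on table 6, one on table 10), all sharing a
designated 8-codon optimal set (one codon per family, A/T-ending, as
AT-rich genomes prefer) plus two private preferred codons per species. The
within-species GC3 spread is deliberately narrow (sd 0.015) so that ENC
ranking isolates the translational-preference channel from compositional
drift; with a realistic within-species spread the tails also differ in
composition, which is exactly the passenger problem the cross-species
intersection exists to solve.

What the generator does **not** emulate: expression levels (bias is a
binary flag), realistic amino-acid composition, length–expression
correlations, introns/UTRs, phylogenetic correlation among species, and
context-dependent stop readthrough. Passing tests therefore certify the
statistics and their bookkeeping, not the biology of any particular genome.

## Problem sizes and numerical conventions

Test and acceptance runs use: 500 genes × 10 seeds for slope recovery;
nine species × 400 genes × 10 base seeds for shared-set recovery; 3000
genes per seed for the preference-recovery and truth-contrast checks
(large pools keep 6-fold-family RSCU noise a few sigma below the 0.08
threshold); 5600 genes for the no-preference null contrast (the |ΔRSCU| <
0.05 bound sits ~3.5 sigma above 6-fold sampling noise at that scale); 1000
genes for PR2 parity, using a background restricted to fourfold families at
GC3 = 0.5, which is the complement-balanced condition under which the
(0.5, 0.5) centroid is the exact expectation.

Other conventions: all codons are DNA-alphabet internally (T, not U);
fractions are kept in [0, 1] internally and rendered as percentages with
two decimals only in output tables; ENC is reported to two decimals in
outputs but kept in double precision internally; every stochastic routine
is driven by one explicit seed and the pipeline records it in its JSON
summary.
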