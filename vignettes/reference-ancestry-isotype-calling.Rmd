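---
title: "Modelling reference-ancestry bias in immunoglobulin isotype calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reference-ancestry bias in immunoglobulin isotype calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoref)
```

## The model

`isoref` treats isotype mis-calling as a purely mechanical consequence of
three ingredients:

1. **Paralogy.** The heavy-chain subclass genes (IGHG1-4, IGHA1-2) differ
   over their terminal (CH3-CHS) exon at only a handful of positions.
2. **Allelic divergence between references.** Those distinguishing
   positions are themselves polymorphic, so two genome references of
   different ancestry present different variant inventories.
3. **Best-match read assignment.** A 3' tag read is placed at every
   ungapped offset of every candidate exon; the unique best-scoring gene
   wins, score ties across genes are discarded as multi-mapping, and ties
   confined to one gene id are kept (gene-level rescue).

Given a donor whose alleles match reference B but are mapped to reference
A, every start offset of the terminal exon falls into one of a small
number of deterministic outcome classes (correct gene, wrong gene,
discarded, unmapped). `scan_window_outcomes()` enumerates these exactly,
and `decompose_regions()` gives the coarser ambiguity classification: a
window is *ambiguous* in a reference iff the two paralogs are identical
over it. With reference A in the ancestry-mismatched role, windows
ambiguous in B only are coloured blue, ambiguous in A only orange,
distinguishable in both red. All cell-level artifacts follow from these
per-offset outcomes plus the read start-position law: the expected
double-positive (DP) rate computed by `expected_dp_rate()` is a sum of
binomial tail probabilities per cell, with no free parameters.

Assumptions worth stating: reads are ungapped and confined to a single
exon (indel alleles and splicing are out of scope); "distinguishable" is
exact-match at the window level, with sequencing errors handled by the
assignment policy rather than the region decomposition; and score is an
affine function of the mismatch count, so score ranking equals mismatch
ranking.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `read_length` | 90 bp | 3' tag read length |
| `max_mismatch` | 6 | placement retention floor (~94% identity for 90-mers) |
| match / mismatch weights | +1 / −2 | integer score (AS analogue); monotone in mismatches |
| `call_threshold` | 0.85 | isotype call: fraction of isotype counts |
| DP thresholds | 0.5/0.5 (IgG1/2), 0.8/0.3 (IgA1/2) | percent of total cell counts |
| QC | 10% mito, 1500 reads, 450 genes, 0.5% prevalence | four-step filter, in that order |
| ASC rule | >10% Ig counts | in every compared output (barcode intersection) |
| `position_bias` | 3'-geometric, rate 0.03 | start offsets concentrate at the 3' end |
| `libsize_log_mean/sd` | log 80 / 0.5 | log-normal molecules per cell |
| `doublet_rate` | 0.02 | independent per barcode; doublet depth = sum of two draws |
| `pcr_duplication_mean` | 1.5 | copies per molecule, 1 + Poisson(mean − 1) |
| `error_rate` | 0.005 | i.i.d. substitution errors per base |

Percent thresholds are interpreted as percent of **total** cell counts
(consistent with reads-per-hundred axes), computed on raw count
fractions; the `log1p(y/L * 1e4)` transform is a display convention only
(`expression_value()`). Whether thresholds should instead be percent of
isotype counts is genuinely ambiguous; the choice is isolated in
`detect_dp()`.

## What the generator emulates — and what it does not

Synthetic panels place substitutions on a shared random backbone exon
(300 bp by default, of which the last 120 bp play the 3'-UTR role), so
every declared variant is present and nothing else differs. The two
shipped configurations reproduce the qualitative patterns that drive the
artifact: `ighg_swap_spec()` (seven separating variants in the matched
reference, three allelic substitutions in the mismatched one, so a
3'-terminal donor IGHG2 read shows mismatch counts 2/1/0/7 and flips its
assignment) and `igha_shared_tail_spec()` (a 180 bp identical tail in the
matched reference — one interior distinguishing variant — against nine
tail variants in the mismatched one, yielding the orange/red/blue interval
topology and the multi-mapping read loss the rescue annotation repairs).

Cells carry one true isotype; doublets carry two, with library size the
sum of two independent log-normal draws — which is exactly the signal the
library-size doublet diagnostic exploits. Background (housekeeping,
ribosomal, mitochondrial) counts are added per cell, scaled against the
cell's true molecule count so the background block is identical across
references, with the mitochondrial fraction drawn Beta(2, 38) (mean 5%).

Not emulated: ambient RNA and empty droplets, chimeric reads, spliced or
intronic reads, barcode sequencing errors (whitelist matching is exact; no
1-Hamming rescue), quality-score-aware alignment, and indel alleles.
Passing tests therefore demonstrate that the *assignment mechanics*
reproduce and resolve the artifact under controlled allele panels — not
that the simulator captures every nuisance process of real droplet data.

## Numerical and design choices

* **Pairwise alignment** uses unit mismatch and linear unit gap costs with
  deterministic traceback (diagonal, then up, then left); equal-length
  sequences take a gapless fast path, appropriate for the near-isometric
  CH3-CHS paralogs. Coordinates are 0-based half-open internally and
  1-based closed in every emitted table, matching GTF convention.
* **Family-level variant totals** are counted as the union of pairwise
  variant columns against an anchor gene (`variant_union_count()`); the
  alternative (sum over pairs) double-counts shared columns.
* **Tie handling**: equal-score placements within one gene keep the gene
  and record the smallest offset; strict integer score equality defines a
  tie. With `gene_level_rescue = FALSE` any placement tie discards the
  read, modelling an aligner without gene-level rescue.
* **Rescue boundary**: the split is placed exactly at the identity
  boundary (maximal common 3' suffix). A placement straddling the boundary
  necessarily covers the last distinguishing variant, so it keeps the
  original gene label; only windows wholly inside the shared segment are
  labelled with the merged gene. This guarantees rescue never changes a
  read that was uniquely assigned under the plain annotation.
* **Rescue bookkeeping** is checked at the mapping level (effective + PCR
  duplicate): UMI deduplication can collapse two distinct molecules that
  collide on (barcode, UMI, gene), which is a deduplication event, not a
  mapping one. The rescue identity experiment sets
  `pcr_duplication_mean = 1` so the two tallies coincide up to such
  collisions.
* **Doublet diagnostic**: the rank-sum test is implemented in-repo
  (tie-corrected normal approximation with continuity correction) and
  guarded by a permutation version that enumerates all splits when
  `choose(n, n1)` is at most 2e5 and otherwise uses a seeded Monte-Carlo
  permutation (20,000–40,000 draws); an exhaustive enumeration at
  realistic group sizes is impossible. Empty groups skip the diagnostic
  with a notice. Doublets are excluded from the analytic DP-rate
  comparison because their DP status reflects genuine co-occurrence.
* **Degenerate inputs**: cells with zero isotype counts get all-zero
  fractions and an `unassigned` call; zero-length shared segments leave
  the annotation unchanged with a warning; empty read sets write valid
  header-only fixtures.

## Problem sizes

The shipped experiments use 300 bp exons, 90 bp reads and populations of
1,000–5,000 cells with ~80 molecules per cell: large enough that DP rates,
call accuracies and the analytic/simulated comparison are stable to well
under the tolerances tested, while a full matched-plus-swapped experiment
runs in seconds thanks to the compiled block-wise mismatch scan.

## Known limitations

The aligner model is ungapped and transcript-local, so it cannot express
reference bias driven by indels, splice junctions or intergenic
homology. Real allele inventories (e.g. full hg38/T2T-CHM13 variant
totals for the whole IgG family) require the actual reference sequences
and annotations; the synthetic panels reproduce the patterns, not the
genome-wide counts. The merged-gene rescue is supported
for terminal-exon homology only — interior homology blocks would need a
three-way split that the underlying mechanism (same-gene multi-mapper
rescue) does not obviously license.
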