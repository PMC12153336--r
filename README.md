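# isoref

Reference-ancestry effects on immunoglobulin isotype calling from 3'
single-cell RNA-seq, as a tested, desk-scale R package.

## The problem

Antibody-secreting cells (ASCs) obey the one-cell-one-antibody principle:
class switch recombination physically deletes the unused heavy-chain
constant regions, so each plasma cell transcribes exactly one isotype gene
(IGHM, IGHD, IGHG1-4, IGHA1-2 or IGHE). 10x Chromium 3' scRNA-seq reads
from these transcripts pile up on the most 3' constant-region exon
(CH3-CHS), where the isotype subclass genes are paralogs differing at only
a handful of positions — and those positions are *allelic*: they differ
between genome references of different ancestry. When the donor's alleles
do not match the reference, a read from gene B can sit closer (fewer
mismatches) to the reference's gene A, so the aligner assigns it to the
wrong paralog; where two paralogs are identical over a read-length window,
the read is discarded as multi-mapping. The visible symptoms are
"double-positive" (DP) cells that appear to express two isotypes at once,
and large blocks of discarded reads — both artifacts of the reference, not
biology.

`isoref` models this inference chain end to end on synthetic data:

* **synthetic data** — paralog allele panels with configurable variant
  placement, cell populations with doublets and log-normal library sizes,
  barcode/UMI-tagged 3'-biased reads with sequencing errors and PCR
  duplication, written as FASTA/GTF/FASTQ/TSV fixtures;
* **paralog divergence** — variant enumeration within and across
  references (coding/UTR compartments, duplicated gene copies) and the
  decomposition of the terminal exon into ambiguity regions: windows
  identical in one reference only ("blue"/"orange") or distinguishable in
  both ("red");
* **read assignment** — an ungapped mismatch-scan model of the aligner:
  unique-best-gene assignment, multi-mapping discard, gene-level rescue of
  same-gene ties, UMI deduplication, and Matrix Market quantification with
  per-class read tallies (the xf/GN/AS/nM analogues);
* **isotype calling** — four-step QC, the >10% immunoglobulin ASC rule,
  the >85% isotype call, DP detection at percent-of-total thresholds
  (0.5%/0.5% for IGHG1/IGHG2; 0.8%/0.3% for IGHA1/IGHA2), and a rank-sum
  library-size doublet diagnostic with an exact-permutation oracle;
* **annotation rescue** — splitting each paralog's terminal exon at the
  identity boundary and assigning the shared 3' segments to a merged
  artificial gene, so gene-level rescue recovers the multi-mapped reads;
* **pipeline** — `run_experiment()` orchestrates simulate → map under two
  references → quantify → QC → call → DP/doublet report (plus optional
  rescue output) from an `experiment_config()` or YAML file, with
  deterministic seeding throughout.

## A worked example

The shipped IgG configuration places seven separating substitutions in the
matched reference (refB) and three allelic substitutions in the mismatched
one (refA), reproducing the illustrative read whose mismatch counts flip
its assignment:

```r
library(isoref)
we  <- ighg_worked_example(seed = 1)
pol <- assignment_policy(max_mismatch = 10)
sapply(seq_len(nrow(we$regions)), function(i)
  min(align_read(we$read, we$regions[i, , drop = FALSE], pol)$mismatches))
#> IGHG1-refA IGHG2-refA IGHG1-refB IGHG2-refB
#>          1          2          7          0
```

Against the mismatched reference the donor IGHG2 read has *fewer*
mismatches to IGHG1 (1 vs 2) and is assigned to the wrong paralog; against
the matched reference it matches IGHG2 perfectly (0 vs 7). Run the full
experiment and the artifact appears at the cell level:

```r
cfg <- experiment_config(
  specs = list(ighg_swap_spec()),
  isotype_proportions = c(IGHG1 = 0.5, IGHG2 = 0.5),
  n_cells = 1000, doublet_rate = 0.02, error_rate = 0,
  background_fraction = 0, pcr_duplication_mean = 1,
  dp_pairs = list(list(pair = c("IGHG1", "IGHG2"),
                       thresholds = c(0.5, 0.5))),
  seed = 7)
b <- run_experiment(cfg)
sapply(b$refs, function(r) r$dp[[1]]$n_dp)   # DP cells among 997 ASCs
#> refA refB
#>  484   23
```

Under the mismatched reference half the cells look double-positive; under
the matched reference the DP rate collapses to the planted 2% doublet
rate. `decompose_regions()` explains why in sequence space:

```r
decompose_regions(b$panels, "IGHG1/IGHG2", 90)$intervals
#>   start end            class colour
#> 1     1 125   ambiguous_both   grey
#> 2   126 140 ambiguous_A_only orange
#> 3   141 211    distinct_both    red
```

and `expected_dp_rate()` turns those interval lengths plus the read
start-position law into a closed-form DP-rate expectation that matches the
simulation to well under 1%.

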