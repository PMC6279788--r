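---
title: "dropquant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dropquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dropquant re-implements, as a tested and reusable R package, a processing
pipeline for inDrops V3 droplet single-cell RNA-seq libraries aligned to a
de novo (transcript-level, multi-isoform) reference transcriptome, such as
those assembled for species without a finished genome. This document
explains the model behind each stage, the tunable parameters and their
defaults, what the bundled simulator does and does not emulate, and the
design choices made where the procedure left room.

## 1. Read structure and extraction

An inDrops V3 run produces four parallel FASTQ streams per read: a 61-cycle
biological read (R1), a 14-cycle barcode/UMI read (R2), and two 8-cycle
index reads (I1, I2). The layout object maps each logical field to a
stream and a 0-based half-open slice. The default V3 assignment is:

| field               | stream | slice    |
|---------------------|--------|----------|
| biological sequence | R1     | [0, 61)  |
| cell barcode half 1 | I2     | [0, 8)   |
| cell barcode half 2 | R2     | [0, 8)   |
| UMI                 | R2     | [8, 14)  |
| library index       | I1     | [0, 8)   |

Only the cycle counts are fixed by the run configuration; the assignment of
the 8+6 split of R2 and of the barcode half to I2 follows the inDrops V3
convention and is fully configurable through `readLayout()`, because runs
processed with other basecalling settings can permute the streams.

Extraction rules, in order:

* a quartet whose streams are shorter than the layout requires is rejected
  (`short_read`);
* a UMI containing N is rejected (`N_in_umi`) -- an ambiguous molecule tag
  cannot be deduplicated;
* each barcode half is corrected against its whitelist by Hamming distance
  (substitutions only, N counts as a mismatch, default radius 1). A unique
  in-range entry corrects the read; no entry rejects it (`no_match`); a tie
  at the minimal distance rejects it (`ambiguous`) rather than guessing;
* the library index must match the sample sheet exactly; there is no index
  correction, mismatches are tallied and dropped;
* quality strings are carried through but never used for filtering.

Accepted reads are written as a single annotated FASTQ whose header grammar
is `@library:cell_barcode:umi:read_id`, with `:` forbidden inside fields.
The grammar is bit-stable: `decodeAnnotatedFastq(encodeAnnotatedFastq(x))`
recovers `x` exactly, which the test suite asserts on 10,000 random reads.
Every input quartet ends in exactly one tally (accepted or one rejection
reason), so extraction is fully accounted.

## 2. UMI-unique fractional quantification

Alignment of the annotated FASTQ against the transcriptome is external (a
bowtie invocation reporting all best-stratum hits per read, stored verbatim
as the default command template in `pipelineConfig()`); the package
consumes the resulting SAM. Reads with more than `max_targets` (default
200) distinct targets are dropped, mirroring the aligner's own reporting
cap for SAMs produced by other means.

The unit of counting is the **UMI group**: all reads sharing one
(cell barcode, UMI) pair are treated as observations of a single captured
molecule, so PCR/optical duplication never adds mass. A group's target set
is, by default, the **union** of its member reads' deduplicated target
sets. The union is the simplest rule consistent with one count unit per
(cell, UMI); an intersection variant (falling back to the union when the
intersection is empty) is available via `groupUmis(rule =
"intersection")` for users who prefer to let concordant reads narrow the
target set.

Each group then distributes exactly one unit of mass equally over its `k`
targets (1/k per target), accumulated in double precision and stored
sparsely without thresholding. Two invariants follow and are tested
exactly: the matrix total equals the number of UMI groups, and appending a
duplicate read changes nothing.

Isoform rows are aggregated to genes by summation, which preserves the
total exactly; in particular a read that multi-maps only within one gene's
isoforms still contributes exactly 1.0 to that gene. The aggregated row is
labeled by the gene's *representative isoform*: the isoform with the
highest dataset-wide total, ties broken lexicographically. The selection
rule is a package decision (only the existence of a representative is
given); it affects labels, never values.

## 3. QC, normalization, variable genes, PCA

* **Gene filter.** A gene is retained iff it is detected (any positive
  fractional mass) in at least `min_cells_per_gene` cells (default 8) in
  *every* sample of the analysis group. The scope is the group under
  analysis -- each time point separately -- not the whole study. The filter
  is monotone in the threshold.
* **Cell filter.** Cells with fewer than `min_genes_per_cell` detected
  genes (default 500) or a mitochondrial mass fraction above
  `max_mito_fraction` (default 0.2) are removed. No published thresholds
  exist for these cuts, so both are prominent, logged knobs; mitochondrial
  features are matched by configurable identifier patterns (an empty
  pattern list disables the mito cut, which matters for references whose
  mitochondrial transcripts are unannotated).
* **Normalization.** Counts are scaled per cell to `scale_factor` (default
  10,000) and transformed as log2(1 + x), matching the log2
  normalized-expression scale used for display and testing downstream.
  Zero stays exactly zero; zero-total cells are an error by design (filter
  first).
* **Variable genes.** On un-logged normalized values, genes are placed in
  20 equal-occupancy mean bins; within each bin the dispersion
  (variance/mean) is z-scored and genes above `z_cutoff` (default 1) are
  kept. A single-gene or zero-spread bin yields z = 0. The procedure is
  deterministic.
* **PCA.** Genes are scaled to zero mean, unit variance (zero-variance
  genes dropped, values clipped at 10 SD) and cells are embedded with
  `prcomp`. The number of components replaces visual inspection of the
  standard-deviation plot with an automated elbow rule: each drop
  sdev[i] - sdev[i+1] is measured relative to the leading component, and
  the chosen n is the last drop of at least `drop_tol` (default 0.05).
  With no such drop (isotropic spectra) the rule returns 1; this
  degenerate behavior is deliberate and documented. When many balanced
  populations spread signal over near-equal components the rule is
  conservative, which is why the evaluation protocol below fixes the
  embedding depth instead.

## 4. Cluster validation: over-cluster, score, merge

Cells are clustered on a shared-nearest-neighbor graph (k = 30 neighbors
by default, scran's SNN weighting) with Louvain modularity optimization at
a deliberately high resolution (default 2.0), so that populations with
highly similar programs come apart. Distinctiveness of each cluster pair
is then measured as the held-out accuracy of a random-forest classifier
(ranger, 200 trees) on the variable-gene expression values: classes are
balanced by downsampling the larger side and evaluated by stratified
3-fold cross-validation. Held-out accuracy was chosen over out-of-bag
error for portability of the evaluation scheme; both estimate the same
quantity.

Accuracy near 0.5 means the split carries no information; the merge loop
repeatedly merges the lowest-scoring pair while that score is below
`acc_threshold` (default 0.85, a knob -- no published value exists), ties
broken toward the smaller id pair, re-scoring only pairs that touch the
merged cluster. The loop performs at most k - 1 merges. Clusters smaller
than `min_size` (default 10) cannot be scored reliably and are first
absorbed into their nearest cluster by centroid distance; because real
rare populations (a dozen cells) exist in droplet data, this minimum and
its fallback are prominently configurable and every merge is recorded in a
replayable history with its score. All per-pair seeds derive
deterministically from the single run seed.

## 5. The simulator and what passing tests mean

`simConfig()` fixes the study conditions the package is verified under:

* **Transcriptome**: 100 genes x 2 isoforms of 500 nt; isoforms of a gene
  share their leading 20% block, and 5 paralog gene pairs share a block
  across genes. Reads drawn entirely inside a shared block multi-map to
  every isoform carrying it -- exactly and knowably, which is what lets
  `emitSam()` stand in for an aligner with a controlled truth.
* **Expression**: baseline gene means are gamma draws (shape 2, scale 1);
  each population's program genes (20 by default) are shifted by
  `de_log2fc` (default 2); molecule counts are negative binomial
  (gamma-mixed Poisson, size 2), the standard droplet overdispersion
  assumption. Program genes have their baseline floored at the gamma
  median: a fold change planted on a never-expressed gene would not
  constitute a distinct program, so the floor is what makes "populations
  separated by a stated fold change" mean what it says.
* **Reads**: 3 populations x 70 cells, 1000 molecules per cell; each
  molecule gets a UMI and `umi_duplication_rate` (default 0.5) adds
  geometric extra reads, giving about 2000 reads per cell; 1% of reads
  carry one barcode substitution; 2% are ambient molecules drawn from the
  pooled profile. Whitelist halves are generated at pairwise Hamming
  distance of at least 3, so single substitutions are always unambiguously
  correctable.
* **UMIs** are drawn without replacement within a cell while the
  4^umi_length space allows, so at the default length (6 nt, 4096 tags vs
  1000 molecules) molecules and UMI groups coincide exactly and
  conservation can be asserted as an identity. When the space saturates
  (the test suite drives this with 2-nt UMIs) collisions occur naturally
  and the estimator visibly undercounts -- the documented collision bias.

What the simulator does *not* emulate: sequencing errors in the biological
read (alignment is not the artifact under test; optional substitution
noise would only exercise the external aligner), doublets, saturation
chemistry, realistic per-cycle error profiles, or batch structure.
Passing the end-to-end tests therefore shows the bookkeeping -- extraction,
deduplication, fractional assignment, aggregation, clustering -- is
correct under the stated noise model; it does not certify performance on
any particular real library.

## 6. Evaluation protocol and problem sizes

The verification suite computes, among others:

* exact agreement (to 1e-9) with a brute-force counting oracle on 100
  random instances of up to 500 reads, 20 transcripts, 8 cells;
* Spearman correlation between true and estimated per-cell gene counts on
  the full raw-read pipeline at the default study scale (210 cells, about
  430,000 reads);
* an exact molecules = UMI-groups identity in the noise-free regime;
* recovery of planted population counts for k in 3..8 (40 cells per
  population, 50 program genes at log2 fold change 2, 3000 molecules per
  cell -- the deeper sampling reflects a well-covered cell) over 20 seeded
  runs, scored by exact k and adjusted Rand index >= 0.9. Because 80% of
  simulated genes carry some program, the evaluation selects features at
  z > 0.5 and clusters in a fixed 10-PC embedding rather than relying on
  the elbow rule, whose conservatism on flat spectra is documented above;
* merging of a randomly over-split homogeneous population back to a
  single cluster in 20 seeded runs;
* the Wilcoxon marker test against full enumeration for all group sizes
  n, m <= 6, and its family-wise error control under 50 permuted-label
  nulls.

The Wilcoxon implementation enumerates all choose(n+m, n) rank assignments
when n + m <= 12 -- valid under ties, where the classical exact
distribution is unavailable (all-tied samples give p = 1 rather than
NaN) -- and otherwise uses the normal approximation with tie and
continuity corrections. Bonferroni adjustment multiplies by the number of
tests actually performed.

## 7. Known limitations

* Barcode correction is substitution-only; indels shift the UMI frame and
  are rejected downstream rather than recovered.
* UMI sequencing errors are not network-collapsed; two UMIs at Hamming
  distance 1 in one cell count as two molecules.
* The union rule can let one chimeric read widen a group's target set;
  the intersection variant narrows it but discards genuine multi-mapping.
* The elbow rule under-selects components when many balanced populations
  produce a flat spectrum; fix the embedding depth in such designs.
* Cross-time-point integration, imputation and doublet detection are out
  of scope.
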