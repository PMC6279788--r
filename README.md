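# dropquant

Quantification and cluster validation for inDrops V3 droplet single-cell
RNA-seq data aligned to a de novo transcriptome.

Droplet experiments on organisms without a finished genome — regenerating
axolotl limb tissue is the motivating case — are aligned to an assembled
transcriptome in which each gene is represented by several highly similar
isoforms, and paralogous genes share long identical stretches. A large
fraction of reads therefore aligns equally well to multiple targets, and
discarding them biases every downstream count. dropquant implements the
full path from raw sequencer output to validated cell populations:

1. **Extraction** — the four parallel FASTQ streams of an inDrops V3 run
   (61-cycle biological read, 14-cycle barcode/UMI read, two 8-cycle
   indices) are parsed into annotated reads; the two cell-barcode halves
   are corrected against whitelists (Hamming radius 1, ties rejected) and
   everything is written as one annotated FASTQ
   (`@library:barcode:umi:read_id`).
2. **UMI-unique fractional quantification** — alignments (SAM, from an
   external aligner reporting all best-stratum hits) are collapsed to one
   counting unit per (cell barcode, UMI) pair. A group whose union of
   targets has size *k* adds 1/*k* to each target, so for cell *c* and
   transcript *t*

       n_ct = sum over UMI groups g in c of [ t in T(g) ] / |T(g)|

   and the matrix total equals the number of UMI groups exactly.
3. **Gene aggregation** — isoform rows are summed per gene and labeled by
   the gene's representative isoform (highest total, ties lexicographic).
4. **QC and normalization** — genes kept if detected in ≥ 8 cells in every
   sample; cells filtered on detected genes and mitochondrial fraction;
   per-cell scaling to 10,000 followed by log2(1 + x); binned-dispersion
   variable genes; PCA with an automated elbow rule.
5. **Cluster validation** — deliberate over-clustering (SNN graph +
   Louvain at high resolution), then pairwise distinctiveness scoring
   with a cross-validated random forest and iterative merging of pairs
   the classifier cannot separate (accuracy < 0.85).
6. **Markers** — cluster-vs-rest Wilcoxon rank-sum tests (exact by full
   enumeration for small groups, tie-corrected normal approximation
   otherwise) with Bonferroni correction.

A fully ground-truthed simulator (`simConfig()`, `makeTranscriptome()`,
`drawExpression()`, `emitReads()`, `emitSam()`) generates raw read
quartets over a toy multi-isoform transcriptome with known multi-mapping,
planted cell populations, UMI duplication, barcode errors and ambient
reads, so every stage is verified end to end against truth.

## Worked example

Simulate a small three-population experiment and run the whole pipeline:

```r
library(dropquant)

cfg <- simConfig(seed = 1, n_genes = 60, n_populations = 3,
                 cells_per_population = 50, molecules_per_cell = 800,
                 de_genes_per_population = 12)
pipe <- pipelineConfig(seed = 1, outdir = file.path(tempdir(), "demo"),
                       sim = cfg,
                       qc = qcParams(min_cells_per_gene = 8,
                                     min_genes_per_cell = 20,
                                     mito_patterns = character(0)),
                       z_cutoff = 0.5, k_neighbors = 15,
                       min_cluster_size = 5)
res <- runPipeline(pipe)

res$quantification$tallies
#>           lines           reads        unmapped over_target_cap      umi_groups
#>          274565          244276               0               0          123377

res$quantification$gene
#> CountMatrix (gene level): 60 features x 150 cells, 8615 nonzero

res$clusters
#> ClusterAssignment: 150 cells in 3 clusters (resolution 2.00, 3 merges)

head(res$markers[order(res$markers$p_adj),
                 c("gene", "cluster", "p_adj", "log2_fc")], 5)
#>        gene cluster        p_adj  log2_fc
#> 54 G0023.i1       3 1.975159e-16 2.347970
#> 53 G0019.i2       3 1.346838e-15 2.142227
#> 52 G0017.i2       3 1.775451e-15 2.472503
#> 14 G0031.i2       1 3.149066e-14 2.076390
#> 25 G0008.i1       2 1.078507e-13 1.859813
```

Reading the output: 244,276 raw reads collapse to 123,377 UMI groups
(about half, matching the configured 0.5 duplication rate); the 60 x 150
gene matrix carries fractional counts whose total equals the group count;
over-clustering split the 150 cells into six pieces and three
classifier-driven merges restored the three planted populations; the top
markers are exactly the planted population-program genes (log2 fold
changes near the configured value of 2).

The output directory is self-describing: count matrices in MatrixMarket
form with `features.tsv`/`barcodes.tsv` sidecars, per-cell QC and marker
tables as TSV, cluster labels, a replayable merge history (JSON), the
verbatim config (YAML), a stage log and a manifest with input hashes.
Re-running the same config and seed reproduces the matrices and labels
bit-identically.

A thin command-line wrapper over the same functions ships in
`inst/scripts/dropquant.R` with subcommands `simulate`, `extract`,
`count`, `qc`, `cluster`, `markers`, `run`.

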