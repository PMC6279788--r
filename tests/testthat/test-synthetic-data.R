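smallCfg <- function(seed = 1, ...) {
    args <- list(seed = seed, n_genes = 20L, n_populations = 2L,
                 cells_per_population = 10L, molecules_per_cell = 80L,
                 de_genes_per_population = 5L, whitelist_size = 6L)
    args[names(list(...))] <- list(...)
    do.call(simConfig, args)
}

test_that("the toy transcriptome is deterministic and structurally correct", {
    cfg <- smallCfg(3)
    tx1 <- makeTranscriptome(cfg)
    tx2 <- makeTranscriptome(cfg)
    f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
    writeTranscriptome(tx1, f1, tempfile())
    writeTranscriptome(tx2, f2, tempfile())
    expect_identical(readLines(f1), readLines(f2))   # byte-identical

    ## isoforms of a gene share exactly the leading block
    info <- tx1$iso_info
    seqs <- as.character(tx1$sequences)
    g1 <- info$isoform[info$gene == "G0001"]
    B <- info$block_len[1]
    expect_identical(unname(substr(seqs[g1[1]], 1, B)),
                     unname(substr(seqs[g1[2]], 1, B)))
    expect_false(substr(seqs[g1[1]], B + 1, 500) ==
                 substr(seqs[g1[2]], B + 1, 500))
    ## paralog pair genes share the block across genes
    pg <- info$isoform[info$gene %in% c("G0001", "G0002")]
    expect_equal(length(unique(substr(seqs[pg], 1, B))), 1L)

    ## single-isoform, no-paralog config: the map is a bijection
    cfgB <- smallCfg(4, isoforms_per_gene = 1L, n_paralog_pairs = 0L)
    txB <- makeTranscriptome(cfgB)
    expect_equal(length(txIds(txB$map)), length(unique(geneIds(txB$map))))

    ## shared_block_fraction 0: all isoforms pairwise distinct
    cfg0 <- smallCfg(5, shared_block_fraction = 0)
    tx0 <- makeTranscriptome(cfg0)
    expect_equal(anyDuplicated(as.character(tx0$sequences)), 0L)
    expect_true(all(tx0$iso_info$block_len == 0))
})

test_that("drawn expression matches its configured means and programs", {
    ## law of large numbers at 1000 cells: empirical gene means near mu
    cfg <- simConfig(seed = 9, n_genes = 25, n_populations = 1,
                     cells_per_population = 1000, de_genes_per_population = 0,
                     molecules_per_cell = 500)
    truth <- drawExpression(cfg)
    cnt <- trueCounts(truth)
    expect_equal(ncol(cnt), 1000L)
    ## gene means sum to molecules_per_cell, so cell totals average to it
    tot <- colSums(cnt)
    expect_lt(abs(mean(tot) - 500), 5 * sd(tot) / sqrt(1000))
    ## per-gene overdispersion follows the negative-binomial variance law
    emp <- rowMeans(cnt)
    vr <- apply(cnt, 1, var)
    expected <- emp * (1 + emp / cfg$nb_dispersion)
    expect_gt(cor(vr, expected), 0.95)

    ## de_log2fc = 0 leaves populations exchangeable
    cfgNull <- simConfig(seed = 2, n_genes = 30, n_populations = 2,
                         cells_per_population = 300,
                         de_genes_per_population = 5, de_log2fc = 0,
                         molecules_per_cell = 300)
    tN <- drawExpression(cfgNull)
    expect_equal(length(unique(trueLabels(tN))), 2L)
    p1 <- rowMeans(trueCounts(tN)[, trueLabels(tN) == "pop1"])
    p2 <- rowMeans(trueCounts(tN)[, trueLabels(tN) == "pop2"])
    expect_gt(cor(p1, p2), 0.9)

    ## population-specific genes are shifted by the configured fold change
    cfgDe <- simConfig(seed = 8, n_genes = 40, n_populations = 2,
                       cells_per_population = 400,
                       de_genes_per_population = 10, de_log2fc = 2)
    tD <- drawExpression(cfgDe)
    m1 <- rowMeans(trueCounts(tD)[, trueLabels(tD) == "pop1"])
    lfc <- log2((m1[1:10] + 0.1) / (rowMeans(
        trueCounts(tD)[, trueLabels(tD) == "pop2"])[1:10] + 0.1))
    expect_gt(median(lfc), 1.2)
})

test_that("read emission conserves molecules when all noise is off", {
    cfg <- smallCfg(6, umi_duplication_rate = 0, barcode_error_rate = 0,
                    ambient_fraction = 0)
    tx <- makeTranscriptome(cfg)
    truth <- drawExpression(cfg)
    sim <- emitReads(truth, tx, tempfile("sim"), cfg)
    prov <- readProvenance(sim$truth)
    expect_equal(nrow(prov), sum(trueCounts(truth)))   # one read per molecule
    expect_true(all(!prov$is_ambient))
    expect_identical(prov$cb_observed, prov$cb_true)
    ## every emitted read is a substring of its source isoform
    seqs <- as.character(tx$sequences)
    idx <- sample(nrow(prov), 50)
    r1 <- dropquant:::.readFastq(sim$files$r1)
    m <- match(prov$read_id[idx], r1$id)
    expect_identical(r1$seq[m],
                     unname(substr(seqs[prov$isoform[idx]],
                                   prov$start[idx] + 1,
                                   prov$start[idx] + cfg$read_length)))
})

test_that("zero cells produce empty outputs and no reads", {
    cfg <- smallCfg(7, cells_per_population = 0L)
    truth <- drawExpression(cfg)
    expect_equal(ncol(trueCounts(truth)), 0L)
    sim <- emitReads(truth, makeTranscriptome(cfg), tempfile("sim"), cfg)
    expect_equal(nrow(readProvenance(sim$truth)), 0L)
    expect_equal(file.size(sim$files$r1), 0)
})

test_that("emitted SAM multi-mapping mirrors the shared-block structure", {
    cfg <- smallCfg(10, umi_duplication_rate = 0, barcode_error_rate = 0,
                    ambient_fraction = 0, n_paralog_pairs = 0L)
    tx <- makeTranscriptome(cfg)
    sim <- emitReads(drawExpression(cfg), tx, tempfile("sim"), cfg)
    sam <- tempfile(fileext = ".sam")
    emitSam(sim$truth, tx, sam)
    ing <- ingestSam(sam)
    prov <- readProvenance(sim$truth)
    nt <- table(ing$targets$read_id)
    B <- tx$iso_info$block_len[1]
    inBlock <- prov$start + cfg$read_length <= B
    ## reads outside any shared block align once; block reads hit both isoforms
    expect_true(all(nt[prov$read_id[!inBlock]] == 1))
    if (any(inBlock))
        expect_true(all(nt[prov$read_id[inBlock]] == 2))
})

test_that("counting emitted SAM reproduces truth exactly in the clean regime", {
    cfg <- smallCfg(11, umi_duplication_rate = 0, barcode_error_rate = 0,
                    ambient_fraction = 0, n_paralog_pairs = 0L,
                    molecules_per_cell = 150L)
    tx <- makeTranscriptome(cfg)
    sim <- emitReads(drawExpression(cfg), tx, tempfile("sim"), cfg)
    sam <- tempfile(fileext = ".sam")
    emitSam(sim$truth, tx, sam)
    q <- countSam(sam, tx$map, transcripts = txIds(tx$map))
    ## UMI groups = true molecules (UMIs drawn without replacement per cell)
    expect_equal(q$tallies[["umi_groups"]], sum(trueCounts(sim$truth)))
    ## gene totals match truth exactly: blocks never span genes here
    g <- as.matrix(counts(q$gene))
    gene <- geneIds(tx$map)[match(rownames(g), txIds(tx$map))]
    prov <- readProvenance(sim$truth)
    cbMap <- unique(prov[, c("cell", "cb_true")])
    truthM <- trueCounts(sim$truth)[, cbMap$cell[match(colnames(g),
                                                       cbMap$cb_true)]]
    rownames(g) <- gene
    keep <- rownames(truthM) %in% gene
    expect_equal(g[rownames(truthM)[keep], ],
                 unname(as.matrix(truthM[keep, ])), ignore_attr = TRUE)
    expect_true(all(truthM[!keep, ] == 0))
})

test_that("UMI saturation at tiny lengths biases counting low", {
    cfg <- smallCfg(12, umi_length = 2L, umi_duplication_rate = 0,
                    barcode_error_rate = 0, ambient_fraction = 0,
                    molecules_per_cell = 120L)
    tx <- makeTranscriptome(cfg)
    sim <- emitReads(drawExpression(cfg), tx, tempfile("sim"), cfg)
    sam <- tempfile(fileext = ".sam")
    emitSam(sim$truth, tx, sam)
    q <- countSam(sam, tx$map, transcripts = txIds(tx$map))
    ## only 16 UMIs per cell: collisions force undercounting
    expect_lt(q$tallies[["umi_groups"]], sum(trueCounts(sim$truth)))
    expect_lte(q$tallies[["umi_groups"]], 16 * ncol(trueCounts(sim$truth)))
})

test_that("recovery does not improve as barcode error rates rise", {
    cors <- vapply(c(0, 0.01, 0.05), function(e) {
        cfg <- smallCfg(13, barcode_error_rate = e,
                        cells_per_population = 15L,
                        molecules_per_cell = 200L)
        tx <- makeTranscriptome(cfg)
        sim <- emitReads(drawExpression(cfg), tx, tempfile("sim"), cfg)
        ex <- extractReads(sim$files$r1, sim$files$r2, sim$files$i1,
                           sim$files$i2, whitelist1 = sim$whitelist1,
                           whitelist2 = sim$whitelist2,
                           sample_sheet = sim$sample_sheet)
        sam <- tempfile(fileext = ".sam")
        emitSam(sim$truth, tx, sam, reads = ex$reads)
        q <- countSam(sam, tx$map, transcripts = txIds(tx$map))
        g <- as.matrix(counts(q$gene))
        gene <- geneIds(tx$map)[match(rownames(g), txIds(tx$map))]
        prov <- readProvenance(sim$truth)
        cbMap <- unique(prov[, c("cell", "cb_true")])
        truthM <- trueCounts(sim$truth)
        est <- matrix(0, nrow(truthM), ncol(truthM),
                      dimnames = dimnames(truthM))
        cells <- cbMap$cell[match(colnames(g), cbMap$cb_true)]
        for (j in seq_len(ncol(g)))
            est[gene[gene %in% rownames(est)], cells[j]] <-
                g[gene %in% rownames(est), j]
        cor(as.vector(est), as.vector(truthM), method = "spearman")
    }, 0)
    expect_true(all(diff(cors) <= 1e-9))
    expect_gt(cors[1], 0.9)
})
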