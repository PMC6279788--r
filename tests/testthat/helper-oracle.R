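## Brute-force counting oracle: enumerates every (cell, UMI) pair with
## explicit loops and splits one unit of mass over the union of the pair's
## targets. Independent of the package's data.table implementation.
oracleCounts <- function(reads, transcripts, cells) {
    m <- matrix(0, nrow = length(transcripts), ncol = length(cells),
                dimnames = list(transcripts, cells))
    keys <- unique(paste(reads$cell, reads$umi, sep = "\r"))
    for (key in keys) {
        parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
        sel <- reads$cell == parts[1L] & reads$umi == parts[2L]
        tgt <- unique(unlist(reads$targets[sel]))
        for (t in tgt)
            m[t, parts[1L]] <- m[t, parts[1L]] + 1 / length(tgt)
    }
    m
}

## gene-level oracle: plain per-gene row sums of the transcript oracle
oracleGeneCounts <- function(txMat, iso2gene) {
    genes <- sort(unique(unlist(iso2gene[rownames(txMat)])))
    g <- matrix(0, nrow = length(genes), ncol = ncol(txMat),
                dimnames = list(genes, colnames(txMat)))
    for (i in rownames(txMat))
        g[iso2gene[[i]], ] <- g[iso2gene[[i]], ] + txMat[i, ]
    g
}

## random counting instance: reads with random (cell, UMI, target set)
randomCountInstance <- function(seed, n_reads = 500L, n_tx = 20L,
                                n_cells = 8L) {
    set.seed(seed)
    nr <- sample(n_reads, 1L)
    tx <- sprintf("T%02d", seq_len(sample(n_tx, 1L)))
    cells <- sprintf("CELL%d", seq_len(sample(n_cells, 1L)))
    reads <- data.frame(
        read_id = sprintf("r%04d", seq_len(nr)),
        cell = sample(cells, nr, replace = TRUE),
        umi = sprintf("U%02d", sample(30L, nr, replace = TRUE)))
    reads$targets <- lapply(seq_len(nr), function(i)
        sample(tx, sample(min(3L, length(tx)), 1L)))
    list(reads = reads, transcripts = tx, cells = cells)
}

## write a read table as a minimal SAM of annotated queries
writeInstanceSam <- function(inst, path, lib = "L1") {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:100", inst$transcripts))
    r <- inst$reads
    k <- lengths(r$targets)
    qn <- paste(lib, r$cell, r$umi, r$read_id, sep = ":")
    body <- sprintf("%s\t%d\t%s\t1\t255\t10M\t*\t0\t0\t*\t*",
                    rep(qn, k),
                    unlist(lapply(k, function(kk) c(0L, rep(256L, kk - 1L)))),
                    unlist(r$targets))
    writeLines(c(hdr, body), path)
    path
}

## quantify an instance through the package path
quantifyInstance <- function(inst, rule = "union") {
    sam <- tempfile(fileext = ".sam")
    on.exit(unlink(sam))
    writeInstanceSam(inst, sam)
    ing <- ingestSam(sam)
    grp <- groupUmis(ing$targets, rule = rule)
    fractionalCount(grp, transcripts = inst$transcripts, cells = inst$cells)
}

## random annotated reads for round-trip tests
randomAnnotatedReads <- function(n, seed = 1L) {
    set.seed(seed)
    bases <- c("A", "C", "G", "T")
    rand <- function(len) vapply(seq_len(n), function(i)
        paste(sample(bases, len, replace = TRUE), collapse = ""),
        character(1L))
    data.frame(library_id = sample(c("S1", "S2"), n, replace = TRUE),
               cell_barcode = rand(16L), umi = rand(6L),
               read_id = sprintf("r%06d", seq_len(n)),
               bio_seq = rand(61L),
               bio_qual = vapply(seq_len(n), function(i)
                   paste(sample(c("I", "F", "#", "5"), 61L, replace = TRUE),
                         collapse = ""), character(1L)))
}

## Hamming distance between two equal-length strings (test-side re-measure)
strHamming <- function(a, b)
    sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])

## expression-only simulation run through QC + clustering, for recovery tests
clusterRecoveryRun <- function(k, seed, cells_per_pop = 40L, n_genes = 500L,
                               de_genes = 50L, molecules = 3000L,
                               resolution = 2, acc_threshold = 0.85) {
    cfg <- simConfig(seed = seed, n_genes = n_genes, n_populations = k,
                     cells_per_population = cells_per_pop,
                     de_genes_per_population = de_genes, de_log2fc = 2,
                     molecules_per_cell = molecules)
    truth <- drawExpression(cfg)
    norm <- normalizeLog2(trueCounts(truth) + 0, scale_factor = 1e4)
    ## most genes carry a population program here, so feature selection
    ## is deliberately inclusive
    vg <- selectVariableGenes(norm, z_cutoff = 0.5)
    if (length(vg) < 10L) vg <- rownames(norm)
    scaled <- scaleGenes(norm, vg)
    emb <- pcaEmbed(scaled, n_pcs_max = 10L)
    cl <- validateClusters(emb$embedding,
                           norm[vg, , drop = FALSE],
                           k_neighbors = 15L, resolution = resolution,
                           acc_threshold = acc_threshold, seed = seed)
    list(labels = clusterLabels(cl), truth = trueLabels(truth),
         assignment = cl)
}
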