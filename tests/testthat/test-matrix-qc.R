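randSparse <- function(seed, ng = 60, nc = 40, density = 0.15) {
    set.seed(seed)
    m <- matrix(0, ng, nc, dimnames = list(sprintf("g%03d", 1:ng),
                                           sprintf("c%03d", 1:nc)))
    nz <- round(density * ng * nc)
    m[sample(length(m), nz)] <- rpois(nz, 3) + 1
    m
}

test_that("the gene filter keeps >= 8 detected cells in every sample", {
    ng <- 5
    mk <- function(detected) {
        m <- matrix(0, ng, 12, dimnames = list(sprintf("g%d", 1:ng),
                                               sprintf("c%d", 1:12)))
        for (g in seq_len(ng)) if (detected[g] > 0)
            m[g, seq_len(detected[g])] <- 0.5   # fractional mass counts
        m
    }
    sA <- mk(c(8, 8, 12, 7, 0))
    sB <- mk(c(8, 7, 12, 9, 0))
    kept <- filterGenes(list(A = sA, B = sB), qcParams(min_cells_per_gene = 8))
    expect_identical(kept, c("g1", "g3"))   # g2: 7 in B; g4: 7 in A
})

test_that("gene filtering matches a recount oracle and is monotone", {
    for (seed in 1:5) {
        sams <- list(a = randSparse(seed), b = randSparse(seed + 100))
        prev <- NULL
        for (thr in c(2, 4, 6, 8)) {
            kept <- filterGenes(sams, qcParams(min_cells_per_gene = thr))
            oracle <- rownames(sams$a)[
                vapply(rownames(sams$a), function(g)
                    sum(sams$a[g, ] > 0) >= thr && sum(sams$b[g, ] > 0) >= thr,
                    TRUE)]
            expect_identical(kept, oracle)
            if (!is.null(prev)) expect_true(all(kept %in% prev))
            prev <- kept
        }
    }
})

test_that("cell filtering removes planted low-gene and high-mito cells", {
    m <- randSparse(2, ng = 30, nc = 20)
    m[m > 0] <- m[m > 0] + 1    # every cell reasonably covered
    rownames(m)[1:2] <- c("MITO-1", "MITO-2")
    ## plant one empty-ish cell and one mito-dominated cell
    m[, 1] <- 0; m[5, 1] <- 1
    m[, 2] <- 0; m[1:2, 2] <- 50; m[10, 2] <- 1
    res <- filterCells(m, qcParams(min_genes_per_cell = 2,
                                   max_mito_fraction = 0.5,
                                   mito_patterns = "^MITO"))
    expect_false("c001" %in% res$cells)
    expect_false("c002" %in% res$cells)
    expect_equal(res$qc$mito_fraction[2], 100 / 101)
    expect_equal(nrow(res$qc), 20)
    expect_identical(res$cells, res$qc$cell[res$qc$keep])

    ## a cell whose only mass is mitochondrial has fraction exactly 1
    m2 <- m; m2[, 3] <- 0; m2[1, 3] <- 7
    r2 <- filterCells(m2, qcParams(min_genes_per_cell = 1,
                                   max_mito_fraction = 0.99,
                                   mito_patterns = "^MITO"))
    expect_false("c003" %in% r2$cells)
    expect_warning(filterCells(m, qcParams(mito_patterns = "^ZZZ")),
                   "no features match")
})

test_that("log2 normalization hits the documented arithmetic and conserves totals", {
    m <- matrix(c(10, 90, 0, 50, 25, 25), nrow = 3,
                dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
    norm <- normalizeLog2(m, scale_factor = 1e4)
    expect_equal(norm["g1", "a"], log2(1001))   # 10/100 * 1e4 -> log2(1+1000)
    expect_equal(norm["g3", "a"], 0)            # zeros stay zero
    ## un-logged columns re-sum to the scale factor
    for (seed in 1:3) {
        x <- randSparse(seed)
        x <- x[, colSums(x) > 0]
        n <- normalizeLog2(x, 1e4)
        expect_lt(max(abs(Matrix::colSums(2^n - 1) - 1e4)), 1e-9)
    }
    bad <- m; bad[, 2] <- 0
    expect_error(normalizeLog2(bad), "zero-total")
})

test_that("variable-gene selection flags excess dispersion within mean bins", {
    set.seed(4)
    ng <- 80; nc <- 200
    mu <- rep(5, ng)
    m <- matrix(rpois(ng * nc, mu), ng, nc,
                dimnames = list(sprintf("g%02d", 1:ng), sprintf("c%03d", 1:nc)))
    ## one gene with the same mean but far larger dispersion
    m[7, ] <- rnbinom(nc, size = 0.3, mu = 5)
    m <- m[, colSums(m) > 0]
    norm <- normalizeLog2(m, 1e4)
    vg <- selectVariableGenes(norm, n_bins = 5, z_cutoff = 1)
    expect_true("g07" %in% vg)
    ## identically-distributed genes: selection stays a small tail
    expect_lt(length(vg), ng / 4)
    expect_error(selectVariableGenes(norm, n_bins = 200), "n_bins")
})

test_that("PCA embedding reconstructs the scaled data and finds planted rank", {
    set.seed(9)
    ## cells on a 2-D plane in 30-D gene space, plus tiny jitter
    basis <- matrix(rnorm(30 * 2), 30, 2)
    scores <- matrix(rnorm(2 * 100, sd = c(8, 4)), 2, 100)
    x <- basis %*% scores + matrix(rnorm(3000, sd = 0.01), 30, 100)
    dimnames(x) <- list(sprintf("g%02d", 1:30), sprintf("c%03d", 1:100))
    xs <- scaleGenes(x, clip_max = Inf)
    emb <- pcaEmbed(xs, n_pcs_max = 30)
    expect_equal(choosePCs(emb$sdev, 0.05), 2)
    ## full-rank reconstruction
    rec <- emb$rotation %*% Matrix::t(emb$embedding)
    expect_lt(max(abs(rec - xs)), 1e-6)
    ## isotropic noise has no elbow: the rule falls back to 1
    iso <- matrix(rnorm(30 * 400), 30, 400,
                  dimnames = list(sprintf("g%02d", 1:30), sprintf("c%03d", 1:400)))
    embI <- pcaEmbed(scaleGenes(iso), n_pcs_max = 20)
    expect_equal(choosePCs(embI$sdev, 0.05), 1)
    expect_warning(pcaEmbed(xs, n_pcs_max = 500), "available")
})

test_that("the elbow rule lands in a sane range on planted programs", {
    picks <- vapply(1:10, function(s) {
        cfg <- simConfig(seed = s, n_genes = 500, n_populations = 5,
                         cells_per_population = 40,
                         de_genes_per_population = 50, de_log2fc = 2)
        norm <- normalizeLog2(trueCounts(drawExpression(cfg)) + 0, 1e4)
        emb <- pcaEmbed(scaleGenes(norm, selectVariableGenes(norm)), 20)
        choosePCs(emb$sdev)
    }, 0)
    expect_true(all(picks >= 3 & picks <= 10))
})

test_that("exact rank-sum p-values match enumeration and handle ties", {
    ## {1,2} vs {3,4}: 6 equally likely rank assignments, two as extreme
    expect_equal(rankSumTest(c(1, 2), c(3, 4))$p.value, 1 / 3)
    ## all-tied samples carry no evidence
    expect_equal(rankSumTest(c(5, 5, 5), c(5, 5))$p.value, 1)
    ## tie-free small samples agree exactly with the classical distribution
    set.seed(31)
    for (n in 2:6) for (m in 2:6) {
        x <- sample(seq(0, 1, by = 1e-4), n)
        y <- sample(seq(2, 3, by = 1e-4), m) - runif(1)
        ours <- rankSumTest(x, y)
        expect_identical(ours$method, "exact")
        ref <- stats::wilcox.test(x, y, exact = TRUE)
        expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
        expect_equal(ours$statistic, unname(ref$statistic))
    }
    ## large-sample mode agrees with the corrected normal approximation
    set.seed(8)
    x <- rnorm(30); y <- rnorm(35, 0.5)
    ours <- rankSumTest(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_identical(ours$method, "normal")
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("marker testing applies Bonferroni over the tests performed", {
    set.seed(12)
    ng <- 10; nc <- 30
    m <- matrix(rpois(ng * nc, 5) + 1, ng, nc,
                dimnames = list(sprintf("g%02d", 1:ng), sprintf("c%02d", 1:nc)))
    labels <- rep(c(1, 2), each = 15)
    m[3, labels == 1] <- m[3, labels == 1] + 40   # planted marker
    norm <- normalizeLog2(m, 1e4)
    res <- wilcoxonMarkers(norm, labels)
    expect_equal(nrow(res), ng * 2)
    expect_equal(res$p_adj, pmin(1, res$p_value * nrow(res)))
    top <- res[res$cluster == "1", ]
    expect_equal(top$gene[which.min(top$p_adj)], "g03")
    expect_gt(top$log2_fc[top$gene == "g03"], 1)
    expect_lt(min(top$p_adj), 0.05)
    ## a 1-cell cluster is skipped with a warning
    expect_warning(wilcoxonMarkers(norm, c(3, labels[-1])), "skipped")
})
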