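#' @importFrom Matrix rowSums colSums Diagonal drop0
#' @importFrom stats prcomp quantile rank pnorm var sd
#' @importFrom utils combn
NULL

#' QC parameter set
#'
#' Defaults follow the pipeline's stated filters: a gene must be detected
#' (any positive mass) in at least 8 cells in every sample of the analysis
#' group; cells with few detected genes or a high mitochondrial fraction
#' are removed. The cell thresholds have no published values and are
#' deliberately prominent knobs.
#'
#' @param min_cells_per_gene detection threshold per sample (default 8)
#' @param min_genes_per_cell minimum detected genes per cell (default 500)
#' @param max_mito_fraction maximum mitochondrial mass fraction (default 0.2)
#' @param mito_patterns regex patterns identifying mitochondrial features
#' @param scale_factor per-cell library size after normalization (default 1e4)
#' @param n_pcs_max maximum principal components to compute (default 50)
#' @return a list of class \code{QCParams}
#' @export
qcParams <- function(min_cells_per_gene = 8L, min_genes_per_cell = 500L,
                     max_mito_fraction = 0.2,
                     mito_patterns = c("^MT-", "^mt-"),
                     scale_factor = 1e4, n_pcs_max = 50L) {
    stopifnot(min_cells_per_gene >= 0, min_genes_per_cell >= 0,
              max_mito_fraction >= 0, max_mito_fraction <= 1,
              scale_factor > 0)
    structure(list(min_cells_per_gene = as.integer(min_cells_per_gene),
                   min_genes_per_cell = as.integer(min_genes_per_cell),
                   max_mito_fraction = max_mito_fraction,
                   mito_patterns = mito_patterns,
                   scale_factor = scale_factor,
                   n_pcs_max = as.integer(n_pcs_max)),
              class = "QCParams")
}

.asSparse <- function(x) {
    if (is(x, "CountMatrix")) counts(x)
    else as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

#' Gene filter across all samples of an analysis group
#'
#' A gene is retained iff it is detected (value > 0) in at least
#' \code{min_cells_per_gene} cells in \emph{every} sample of the group.
#' "All samples" is scoped to the group under analysis (each time point is
#' analyzed separately). Raising the threshold can only shrink the
#' retained set.
#'
#' @param samples named list of gene-level matrices /
#'   \linkS4class{CountMatrix}es sharing a feature namespace
#' @param params a [qcParams()] list (or an integer threshold)
#' @return character vector of retained gene features
#' @export
filterGenes <- function(samples, params = qcParams()) {
    minCells <- if (is.numeric(params)) as.integer(params)
                else params$min_cells_per_gene
    stopifnot(length(samples) >= 1L)
    mats <- lapply(samples, .asSparse)
    feats <- rownames(mats[[1L]])
    if (is.null(feats) || !length(feats)) stop("empty feature namespace")
    for (m in mats) stopifnot(identical(rownames(m), feats))
    keep <- rep(TRUE, length(feats))
    for (m in mats)
        keep <- keep & (rowSums(m > 0) >= minCells)
    feats[keep]
}

#' Cell filter: detected genes and mitochondrial fraction
#'
#' A cell is retained iff it has at least \code{min_genes_per_cell}
#' detected genes and a mitochondrial mass fraction at most
#' \code{max_mito_fraction}. Mitochondrial features are matched by the
#' configured identifier patterns; if none match, a warning is issued and
#' all mito fractions are 0.
#'
#' @param m gene-level matrix or \linkS4class{CountMatrix}
#' @param params a [qcParams()] list
#' @param mito_features optional explicit feature list overriding patterns
#' @return list with \code{cells} (retained ids) and \code{qc}
#'   (data.frame: cell, n_genes, mito_fraction, keep)
#' @export
filterCells <- function(m, params = qcParams(), mito_features = NULL) {
    x <- .asSparse(m)
    if (is.null(mito_features)) {
        if (length(params$mito_patterns)) {
            pat <- paste(params$mito_patterns, collapse = "|")
            mito_features <- grep(pat, rownames(x), value = TRUE)
            if (!length(mito_features))
                warning("no features match the mitochondrial patterns; ",
                        "mito fraction is 0 for all cells")
        } else mito_features <- character(0L)   # mito QC disabled
    }
    nGenes <- colSums(x > 0)
    tot <- colSums(x)
    mito <- if (length(mito_features))
        colSums(x[rownames(x) %in% mito_features, , drop = FALSE]) else 0
    frac <- ifelse(tot > 0, mito / tot, 0)
    keep <- nGenes >= params$min_genes_per_cell &
            frac <= params$max_mito_fraction
    qc <- data.frame(cell = colnames(x), n_genes = as.integer(nGenes),
                     mito_fraction = as.numeric(frac), keep = keep,
                     row.names = NULL)
    list(cells = colnames(x)[keep], qc = qc)
}

#' Library-size normalization on a log2 scale
#'
#' Scales each cell to a common total (\code{scale_factor}) and applies
#' log2(1 + x), giving the log2 normalized-expression scale used
#' throughout downstream analysis. Zero counts stay exactly 0; zero-total
#' cells are an error (filter cells first).
#'
#' @param m gene-level matrix or \linkS4class{CountMatrix}
#' @param scale_factor target per-cell total before the log (default 1e4)
#' @return sparse matrix of log2 normalized expression (features x cells)
#' @export
normalizeLog2 <- function(m, scale_factor = 1e4) {
    x <- .asSparse(m)
    tot <- colSums(x)
    if (any(tot <= 0)) stop("zero-total cell: filter cells before normalizing")
    y <- x %*% Diagonal(x = scale_factor / tot)
    y@x <- log2(1 + y@x)
    dimnames(y) <- dimnames(x)
    as(y, "CsparseMatrix")
}

#' Variable-gene selection by binned dispersion z-scores
#'
#' Works on the un-logged normalized values (2^log2value - 1). Genes are
#' placed into \code{n_bins} equal-occupancy bins of mean expression;
#' within each bin the dispersion (variance / mean) is z-scored, and genes
#' exceeding \code{z_cutoff} are selected. A bin with a single gene or
#' zero dispersion spread gets z = 0. Deterministic for fixed input.
#'
#' @param norm log2 normalized matrix from [normalizeLog2()]
#' @param n_bins number of mean-expression bins (default 20)
#' @param z_cutoff dispersion z-score cutoff (default 1)
#' @return character vector of selected genes
#' @export
selectVariableGenes <- function(norm, n_bins = 20L, z_cutoff = 1) {
    x <- .asSparse(norm)
    x@x <- 2^x@x - 1
    mu <- rowSums(x) / ncol(x)
    ex2 <- rowSums(x^2) / ncol(x)
    v <- (ex2 - mu^2) * ncol(x) / max(1, ncol(x) - 1)
    pos <- mu > 0
    if (sum(pos) < n_bins)
        stop("need at least n_bins genes with positive mean")
    disp <- rep(0, length(mu))
    disp[pos] <- v[pos] / mu[pos]
    bin <- rep(NA_integer_, length(mu))
    bin[pos] <- as.integer(cut(rank(mu[pos], ties.method = "first"),
                               breaks = n_bins, labels = FALSE))
    z <- rep(0, length(mu))
    for (b in unique(bin[pos])) {
        idx <- which(!is.na(bin) & bin == b)
        if (length(idx) < 2L) next
        s <- sd(disp[idx])
        if (is.na(s) || s == 0) next
        z[idx] <- (disp[idx] - mean(disp[idx])) / s
    }
    rownames(x)[z > z_cutoff]
}

#' Gene-wise scaling to zero mean and unit variance
#'
#' Zero-variance genes are dropped; values are clipped at \code{clip_max}
#' absolute standard deviations to bound outlier leverage.
#'
#' @param norm log2 normalized matrix (features x cells)
#' @param genes optional subset of features (e.g. variable genes)
#' @param clip_max clipping bound in SD units (default 10)
#' @return dense scaled matrix (features x cells)
#' @export
scaleGenes <- function(norm, genes = NULL, clip_max = 10) {
    x <- as.matrix(.asSparse(norm))
    if (!is.null(genes)) x <- x[genes, , drop = FALSE]
    mu <- rowMeans(x)
    s <- apply(x, 1L, sd)
    keep <- s > 0
    x <- (x[keep, , drop = FALSE] - mu[keep]) / s[keep]
    x[x > clip_max] <- clip_max
    x[x < -clip_max] <- -clip_max
    x
}

#' PCA embedding of cells
#'
#' Principal components of the scaled matrix (cells as observations).
#' Requesting more components than min(cells, genes) allows caps the
#' number with a warning.
#'
#' @param scaled scaled matrix from [scaleGenes()] (features x cells)
#' @param n_pcs_max number of components to keep (default 50)
#' @return list with \code{embedding} (cells x PCs), \code{sdev},
#'   \code{rotation}
#' @export
pcaEmbed <- function(scaled, n_pcs_max = 50L) {
    avail <- min(dim(scaled))
    if (n_pcs_max > avail) {
        warning("requested ", n_pcs_max, " PCs; only ", avail, " available")
        n_pcs_max <- avail
    }
    p <- prcomp(Matrix::t(scaled), center = FALSE, scale. = FALSE)
    k <- min(n_pcs_max, ncol(p$x))
    list(embedding = p$x[, seq_len(k), drop = FALSE],
         sdev = p$sdev[seq_len(k)],
         rotation = p$rotation[, seq_len(k), drop = FALSE])
}

#' Automated elbow rule for the number of components
#'
#' Replaces visual inspection of the component standard-deviation plot:
#' each drop sdev[i] - sdev[i+1] is measured relative to the leading
#' component, and the chosen n is the smallest value beyond which every
#' drop falls under \code{drop_tol} (i.e. the curve has flattened). With
#' no drop of that size anywhere - isotropic noise, no elbow - the rule
#' returns 1.
#'
#' @param sdev component standard deviations (decreasing)
#' @param drop_tol relative-drop threshold (default 0.05)
#' @return number of components to use
#' @export
choosePCs <- function(sdev, drop_tol = 0.05) {
    if (length(sdev) < 2L) return(length(sdev))
    rel <- (sdev[-length(sdev)] - sdev[-1L]) / sdev[1L]
    big <- which(rel >= drop_tol)
    if (!length(big)) 1L else max(big)
}

## ---- Wilcoxon rank-sum -----------------------------------------------------

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact mode (full enumeration of the \code{choose(n+m, n)} assignments
#' of pooled ranks, valid under ties) when \code{n + m <= exact_limit};
#' otherwise the normal approximation with tie and continuity corrections.
#' All-tied samples give p = 1. The statistic is the Mann-Whitney U of
#' \code{x}.
#'
#' @param x,y numeric samples
#' @param exact_limit switch to the approximation above this pooled size
#' @return list with \code{statistic} (U), \code{p.value}, \code{method}
#' @export
rankSumTest <- function(x, y, exact_limit = 12L) {
    n <- length(x); m <- length(y)
    stopifnot(n >= 1L, m >= 1L)
    r <- rank(c(x, y))
    U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    mu <- n * m / 2
    if (n + m <= exact_limit) {
        idx <- combn(n + m, n)
        Uall <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
        p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-12)
        return(list(statistic = U, p.value = p, method = "exact"))
    }
    N <- n + m
    ties <- table(r)
    sig2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0)
        return(list(statistic = U, p.value = 1, method = "normal"))
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sqrt(sig2)
    list(statistic = U, p.value = min(1, 2 * pnorm(-abs(z))),
         method = "normal")
}

#' Cluster marker testing with Wilcoxon rank-sum and Bonferroni
#'
#' For every gene and every cluster with at least 2 cells on both sides,
#' tests cluster-vs-rest on the log2 normalized values with
#' [rankSumTest()]. The Bonferroni factor is the number of tests actually
#' performed (genes x clusters tested); adjusted p = min(1, p x factor).
#' The log2 fold change compares un-logged normalized means with a
#' pseudocount of 1.
#'
#' @param norm log2 normalized matrix (features x cells)
#' @param labels cluster labels, one per cell
#' @param genes optional gene subset to test (default all)
#' @return data.frame: gene, cluster, statistic, p_value, p_adj, log2_fc
#' @export
wilcoxonMarkers <- function(norm, labels, genes = NULL) {
    x <- as.matrix(.asSparse(norm))
    if (!is.null(genes)) x <- x[genes, , drop = FALSE]
    labels <- as.character(labels)
    stopifnot(length(labels) == ncol(x))
    cl <- sort(unique(labels))
    if (length(cl) < 2L) stop("need at least 2 clusters")
    lin <- 2^x - 1
    rows <- list()
    for (cc in cl) {
        inC <- labels == cc
        if (sum(inC) < 2L || sum(!inC) < 2L) {
            warning("cluster ", cc, " skipped: fewer than 2 cells on a side")
            next
        }
        for (g in seq_len(nrow(x))) {
            t <- rankSumTest(x[g, inC], x[g, !inC])
            lfc <- log2((mean(lin[g, inC]) + 1) / (mean(lin[g, !inC]) + 1))
            rows[[length(rows) + 1L]] <-
                data.frame(gene = rownames(x)[g], cluster = cc,
                           statistic = t$statistic, p_value = t$p.value,
                           log2_fc = lfc)
        }
    }
    res <- do.call(rbind, rows)
    res$p_adj <- stats::p.adjust(res$p_value, method = "bonferroni")
    res[, c("gene", "cluster", "statistic", "p_value", "p_adj", "log2_fc")]
}
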