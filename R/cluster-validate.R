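#' @importFrom igraph cluster_louvain membership
#' @importFrom ranger ranger
#' @importFrom Matrix rowMeans colMeans t
#' @importFrom stats dist predict
NULL

#' Over-cluster cells in PC space
#'
#' Builds a shared-nearest-neighbor graph on the PCA embedding (k nearest
#' neighbors, scran's SNN weighting) and partitions it with Louvain
#' modularity optimization at a deliberately high resolution, so that
#' populations with highly similar expression programs come apart and can
#' be re-merged on evidence by [mergeSimilar()].
#'
#' @param embedding cells x PCs matrix from [pcaEmbed()]
#' @param k_neighbors neighbors for the SNN graph (default 30)
#' @param resolution Louvain resolution; > 1 over-clusters (default 2)
#' @param seed RNG seed for the community detection
#' @return a \linkS4class{ClusterAssignment}
#' @export
overcluster <- function(embedding, k_neighbors = 30L, resolution = 2,
                        seed = 0L) {
    n <- nrow(embedding)
    if (n < k_neighbors + 1L)
        stop("too_few_cells: ", n, " cells for k_neighbors = ", k_neighbors)
    g <- scran::buildSNNGraph(embedding, k = k_neighbors, transposed = TRUE)
    set.seed(seed)
    cl <- cluster_louvain(g, resolution = resolution)
    lab <- as.integer(membership(cl))
    lab <- match(lab, sort(unique(lab)))
    cells <- rownames(embedding)
    if (is.null(cells)) cells <- paste0("cell", seq_len(n))
    new("ClusterAssignment", labels = setNames(lab, cells),
        resolution = as.numeric(resolution),
        mergeHistory = .emptyHistory())
}

.emptyHistory <- function()
    data.frame(cluster_a = integer(), cluster_b = integer(),
               accuracy = numeric(), reason = character())

## stratified k-fold assignment: shuffle within class, deal folds round-robin
.stratifiedFolds <- function(cls, k) {
    fold <- integer(length(cls))
    for (cc in unique(cls)) {
        idx <- sample(which(cls == cc))
        fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
}

#' Distinctiveness of a cluster pair
#'
#' Held-out accuracy of a random-forest classifier separating the two
#' clusters on the variable-gene expression values: classes are balanced
#' by downsampling the larger side, then evaluated by stratified k-fold
#' cross-validation. Accuracy near 0.5 means the clusters are
#' statistically indistinguishable; near 1, clearly distinct. Pairs with a
#' side below \code{min_size} cells are unevaluable.
#'
#' @param x features x cells matrix of normalized expression restricted to
#'   informative (e.g. variable) genes
#' @param labels integer cluster labels per cell
#' @param pair length-2 vector of distinct cluster ids
#' @param n_trees random-forest size (default 200)
#' @param seed RNG seed (downsampling, folds, forests)
#' @param min_size minimum cells per side (default 10)
#' @param folds cross-validation folds (default 3)
#' @return list: \code{pair}, \code{accuracy} (NA if unevaluable),
#'   \code{n_a}, \code{n_b}, \code{evaluable}
#' @export
scorePair <- function(x, labels, pair, n_trees = 200L, seed = 0L,
                      min_size = 10L, folds = 3L) {
    if (length(pair) != 2L || pair[1L] == pair[2L])
        stop("invalid_pair: need two distinct cluster ids")
    ia <- which(labels == pair[1L])
    ib <- which(labels == pair[2L])
    res <- list(pair = sort(pair), accuracy = NA_real_,
                n_a = length(ia), n_b = length(ib), evaluable = FALSE)
    if (length(ia) < min_size || length(ib) < min_size) return(res)
    set.seed(seed)
    nPer <- min(length(ia), length(ib))
    ia <- sample(ia, nPer)
    ib <- sample(ib, nPer)
    idx <- c(ia, ib)
    cls <- factor(rep(c("a", "b"), each = nPer))
    feat <- t(as.matrix(x[, idx, drop = FALSE]))
    colnames(feat) <- paste0("f", seq_len(ncol(feat)))
    fold <- .stratifiedFolds(cls, folds)
    correct <- 0L
    for (f in seq_len(folds)) {
        tr <- fold != f
        fit <- ranger(x = feat[tr, , drop = FALSE], y = cls[tr],
                      num.trees = n_trees, seed = seed + f,
                      num.threads = 1L)
        pred <- predict(fit, feat[!tr, , drop = FALSE],
                        num.threads = 1L)$predictions
        correct <- correct + sum(pred == cls[!tr])
    }
    res$accuracy <- correct / length(cls)
    res$evaluable <- TRUE
    res
}

#' Merge indistinct clusters
#'
#' Implements the merge phase of the over-cluster / classifier-merge
#' procedure. Clusters smaller than \code{min_size} are first absorbed
#' into their nearest cluster by centroid distance (they cannot be scored;
#' the fallback keeps rare-but-real populations configurable via
#' \code{min_size}). Then all cluster pairs are scored with [scorePair()]
#' and, while the lowest accuracy falls below \code{acc_threshold}, that
#' pair is merged (ties by the smaller id pair), pairs touching the merged
#' cluster re-scored, and the loop repeats. At most k - 1 merges can
#' occur. Every merge is recorded in the history with its score.
#'
#' @param assignment a \linkS4class{ClusterAssignment} (or integer labels
#'   named by cell)
#' @param x features x cells expression matrix (variable genes)
#' @param acc_threshold accuracy below which a pair is merged (default 0.85)
#' @param min_size minimum scoreable cluster size (default 10)
#' @param n_trees forest size per comparison (default 200)
#' @param seed run seed; all per-pair seeds derive from it
#' @param folds cross-validation folds (default 3)
#' @return a \linkS4class{ClusterAssignment} with contiguous labels and
#'   the merge history
#' @export
mergeSimilar <- function(assignment, x, acc_threshold = 0.85, min_size = 10L,
                         n_trees = 200L, seed = 0L, folds = 3L) {
    if (is(assignment, "ClusterAssignment")) {
        labels <- clusterLabels(assignment)
        resol <- assignment@resolution
    } else {
        labels <- assignment
        resol <- NA_real_
    }
    stopifnot(!is.null(names(labels)), ncol(x) == length(labels))
    history <- .emptyHistory()
    lab <- as.integer(labels)

    centroid <- function(id) rowMeans(x[, lab == id, drop = FALSE])
    ## absorb unevaluably small clusters into nearest centroid
    repeat {
        sizes <- table(lab)
        ids <- as.integer(names(sizes))
        if (length(ids) < 2L) break
        small <- ids[sizes < min_size]
        if (!length(small)) break
        s <- small[which.min(sizes[as.character(small)])]
        cen <- vapply(ids, centroid, numeric(nrow(x)))
        d <- colSums((cen - cen[, match(s, ids)])^2)
        d[match(s, ids)] <- Inf
        tgt <- ids[which.min(d)]
        history <- rbind(history,
                         data.frame(cluster_a = min(s, tgt),
                                    cluster_b = max(s, tgt),
                                    accuracy = NA_real_,
                                    reason = "small_cluster"))
        lab[lab == s] <- tgt
    }

    ## iterative classifier-driven merging with a per-pair score cache
    pairSeed <- function(a, b) (seed * 1000L + a * 31L + b * 7L) %% 2147483647L
    cache <- new.env(parent = emptyenv())
    key <- function(a, b) paste(a, b, sep = "_")
    score <- function(a, b) {
        k <- key(a, b)
        if (!exists(k, envir = cache, inherits = FALSE))
            assign(k, scorePair(x, lab, c(a, b), n_trees = n_trees,
                                seed = pairSeed(a, b),
                                min_size = min_size, folds = folds)$accuracy,
                   envir = cache)
        get(k, envir = cache, inherits = FALSE)
    }
    repeat {
        ids <- sort(unique(lab))
        if (length(ids) < 2L) break
        pairs <- combn(ids, 2L)
        accs <- vapply(seq_len(ncol(pairs)),
                       function(i) score(pairs[1L, i], pairs[2L, i]),
                       numeric(1L))
        best <- which.min(accs)   # ties: first = smallest (a, b) pair
        if (!length(best) || !is.finite(accs[best]) ||
            accs[best] >= acc_threshold) break
        a <- pairs[1L, best]; b <- pairs[2L, best]
        history <- rbind(history,
                         data.frame(cluster_a = a, cluster_b = b,
                                    accuracy = accs[best],
                                    reason = "below_threshold"))
        lab[lab == b] <- a
        rm(list = ls(cache)[grepl(paste0("(^|_)(", a, "|", b, ")(_|$)"),
                                  ls(cache))],
           envir = cache)
    }
    lab <- match(lab, sort(unique(lab)))
    new("ClusterAssignment", labels = setNames(lab, names(labels)),
        resolution = resol, mergeHistory = history)
}

#' Over-cluster then merge: full cluster validation
#'
#' @inheritParams overcluster
#' @inheritParams mergeSimilar
#' @return a \linkS4class{ClusterAssignment}
#' @export
validateClusters <- function(embedding, x, k_neighbors = 30L, resolution = 2,
                             acc_threshold = 0.85, min_size = 10L,
                             n_trees = 200L, seed = 0L) {
    oc <- overcluster(embedding, k_neighbors = k_neighbors,
                      resolution = resolution, seed = seed)
    mergeSimilar(oc, x, acc_threshold = acc_threshold, min_size = min_size,
                 n_trees = n_trees, seed = seed)
}
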