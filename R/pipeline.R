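#' @importFrom jsonlite write_json
#' @importFrom yaml write_yaml read_yaml
#' @importFrom tools md5sum
NULL

## the external alignment command the pipeline documents and, on request,
## invokes verbatim; alignment itself is never re-implemented here
.DEFAULT_ALIGNER_TEMPLATE <- paste(
    "bowtie Axo.Trin.fasta.bowtie -q -p 20 -a --best --strata",
    "--chunkmbs 1000 --sam -m 200 -n 1 -l 15 -e 100 {fastq} > {sam}")

#' Pipeline configuration
#'
#' One config drives the whole run: simulation (or external inputs),
#' extraction, counting, QC, clustering and marker testing. The seed is
#' mandatory and threads through every stochastic stage; the config is
#' serialized verbatim into the output directory for provenance.
#'
#' @param seed run seed (mandatory)
#' @param outdir output directory
#' @param sim a [simConfig()] to simulate inputs, or NULL when external
#'   inputs are supplied
#' @param inputs optional named list of external inputs (r1, r2, i1, i2,
#'   whitelist1, whitelist2, sample_sheet, sam, map)
#' @param max_hamming barcode correction radius (default 1)
#' @param umi_rule "union" or "intersection" (default union)
#' @param max_targets per-read target cap at ingestion (default 200)
#' @param qc a [qcParams()] list
#' @param n_bins,z_cutoff variable-gene selection parameters
#' @param drop_tol elbow-rule tolerance for choosing PCs
#' @param k_neighbors,resolution,acc_threshold,min_cluster_size clustering
#'   parameters (see [overcluster()] and [mergeSimilar()])
#' @param aligner_template external aligner command template (documented
#'   default: the verbatim bowtie invocation); only invoked when
#'   \code{use_aligner = TRUE}
#' @param use_aligner invoke the external aligner instead of [emitSam()]
#' @return a list of class \code{PipelineConfig}
#' @export
pipelineConfig <- function(seed, outdir, sim = NULL, inputs = NULL,
                           max_hamming = 1L,
                           umi_rule = c("union", "intersection"),
                           max_targets = 200L, qc = qcParams(),
                           n_bins = 20L, z_cutoff = 1, drop_tol = 0.05,
                           k_neighbors = 30L, resolution = 2,
                           acc_threshold = 0.85, min_cluster_size = 10L,
                           aligner_template = .DEFAULT_ALIGNER_TEMPLATE,
                           use_aligner = FALSE) {
    if (missing(seed)) stop("seed is mandatory")
    umi_rule <- match.arg(umi_rule)
    structure(as.list(environment()), class = "PipelineConfig")
}

.logStage <- function(log, stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    cat(line, "\n", file = log, append = TRUE)
    invisible(line)
}

#' Run the full pipeline
#'
#' Stages: simulate (when a sim config is present), extract, align (via
#' [emitSam()] or the configured external command), count, qc, cluster,
#' markers. Writes count matrices (MatrixMarket), QC and marker tables
#' (TSV), per-cell labels, a merge-history JSON, a plain-text log, the
#' verbatim config (YAML) and a manifest with input hashes. Re-running
#' with the same config and inputs reproduces the matrices bit-identically
#' and, given the seed, the classifier stages too.
#'
#' @param config a [pipelineConfig()]
#' @return invisibly, a list with the main in-memory results and the
#'   manifest
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    log <- file.path(config$outdir, "pipeline.log")
    file.create(log)
    stages <- character(0L)
    fail <- function(stage, ...) stop("[stage ", stage, "] ", ...,
                                      call. = FALSE)
    yaml::write_yaml(.serializableConfig(config),
                     file.path(config$outdir, "config.yaml"))

    ## ---- simulate ----
    if (!is.null(config$sim)) {
        txome <- makeTranscriptome(config$sim)
        truth <- drawExpression(config$sim)
        sim <- emitReads(truth, txome, file.path(config$outdir, "sim"),
                         config$sim)
        truth <- sim$truth
        writeTranscriptome(txome, file.path(config$outdir, "sim", "txome.fasta"),
                           file.path(config$outdir, "sim", "tx2gene.tsv"))
        inputs <- c(sim$files[c("r1", "r2", "i1", "i2")],
                    list(whitelist1 = sim$files$whitelist1,
                         whitelist2 = sim$files$whitelist2,
                         sample_sheet = sim$files$sample_sheet,
                         map = file.path(config$outdir, "sim", "tx2gene.tsv")))
        stages <- c(stages, "simulate")
        .logStage(log, "simulate",
                  sprintf("%d cells, %d true molecules, %d reads",
                          ncol(trueCounts(truth)), sum(trueCounts(truth)),
                          nrow(readProvenance(truth))))
    } else {
        inputs <- config$inputs
        txome <- NULL; truth <- NULL
    }

    ## ---- extract ----
    need <- c("r1", "r2", "i1", "i2", "whitelist1", "whitelist2",
              "sample_sheet")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) fail("extract", "missing inputs: ",
                           paste(miss, collapse = ", "))
    for (f in need) if (!file.exists(inputs[[f]]))
        fail("extract", "input not found: ", inputs[[f]])
    annotated <- file.path(config$outdir, "annotated.fastq.gz")
    ex <- extractReads(inputs$r1, inputs$r2, inputs$i1, inputs$i2,
                       whitelist1 = readBarcodeWhitelist(inputs$whitelist1),
                       whitelist2 = readBarcodeWhitelist(inputs$whitelist2),
                       sample_sheet = readSampleSheet(inputs$sample_sheet),
                       max_hamming = config$max_hamming, output = annotated)
    stages <- c(stages, "extract")
    .logStage(log, "extract", paste(names(ex$tallies), ex$tallies,
                                    sep = "=", collapse = " "))

    ## ---- align ----
    sam <- file.path(config$outdir, "alignments.sam")
    if (!is.null(inputs[["sam"]])) {
        sam <- inputs[["sam"]]
        .logStage(log, "align", paste("using supplied SAM", sam))
    } else if (config$use_aligner) {
        cmd <- sub("{fastq}", annotated,
                   sub("{sam}", sam, config$aligner_template, fixed = TRUE),
                   fixed = TRUE)
        .logStage(log, "align", cmd)
        if (system(cmd) != 0L) fail("align", "aligner exited non-zero")
    } else if (!is.null(truth)) {
        emitSam(truth, txome, sam, reads = ex$reads)
        .logStage(log, "align", "emitted exact-multimapping SAM from truth")
    } else {
        fail("align", "no SAM supplied, no aligner requested, no simulation")
    }
    stages <- c(stages, "align")

    ## ---- count ----
    if (is.null(inputs$map)) fail("count", "missing isoform-to-gene map")
    map <- readTranscriptGeneMap(inputs$map)
    q <- countSam(sam, map, rule = config$umi_rule,
                  max_targets = config$max_targets, transcripts = txIds(map))
    writeCountMatrix(q$transcript, file.path(config$outdir, "counts_transcript"))
    writeCountMatrix(q$gene, file.path(config$outdir, "counts_gene"))
    stages <- c(stages, "count")
    .logStage(log, "count", paste(names(q$tallies), q$tallies,
                                  sep = "=", collapse = " "))

    ## ---- qc ----
    genesKept <- filterGenes(list(sample1 = q$gene), config$qc)
    gm <- counts(q$gene)[genesKept, , drop = FALSE]
    fc <- filterCells(gm, config$qc)
    .logStage(log, "qc", sprintf("genes %d -> %d, cells %d -> %d",
                                 nrow(counts(q$gene)), length(genesKept),
                                 ncol(gm), length(fc$cells)))
    if (length(fc$cells) < 2L) fail("qc", "fewer than 2 cells survive QC")
    gm <- gm[, fc$cells, drop = FALSE]
    norm <- normalizeLog2(gm, config$qc$scale_factor)
    utils::write.table(fc$qc, file.path(config$outdir, "cell_qc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stages <- c(stages, "qc")

    ## ---- cluster ----
    vg <- selectVariableGenes(norm, n_bins = min(config$n_bins,
                                                 max(2L, nrow(norm) %/% 2L)),
                              z_cutoff = config$z_cutoff)
    if (length(vg) < 2L) vg <- rownames(norm)
    scaled <- scaleGenes(norm, vg)
    emb <- pcaEmbed(scaled, n_pcs_max = min(config$qc$n_pcs_max,
                                            min(dim(scaled)) - 1L))
    npc <- choosePCs(emb$sdev, config$drop_tol)
    npc <- max(npc, 2L)
    assign <- validateClusters(emb$embedding[, seq_len(npc), drop = FALSE],
                               norm[vg, , drop = FALSE],
                               k_neighbors = min(config$k_neighbors,
                                                 ncol(norm) - 1L),
                               resolution = config$resolution,
                               acc_threshold = config$acc_threshold,
                               min_size = config$min_cluster_size,
                               seed = config$seed)
    utils::write.table(data.frame(cell = names(clusterLabels(assign)),
                                  cluster = clusterLabels(assign)),
                       file.path(config$outdir, "cluster_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json(mergeHistory(assign),
               file.path(config$outdir, "merge_history.json"),
               dataframe = "rows", auto_unbox = TRUE, na = "null")
    stages <- c(stages, "cluster")
    .logStage(log, "cluster",
              sprintf("%d PCs, %d variable genes, %d final clusters",
                      npc, length(vg),
                      length(unique(clusterLabels(assign)))))

    ## ---- markers ----
    markers <- NULL
    if (length(unique(clusterLabels(assign))) >= 2L) {
        markers <- wilcoxonMarkers(norm[vg, , drop = FALSE],
                                   clusterLabels(assign))
        utils::write.table(markers, file.path(config$outdir, "markers.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        stages <- c(stages, "markers")
        .logStage(log, "markers", sprintf("%d tests", nrow(markers)))
    } else {
        .logStage(log, "markers", "skipped: single cluster")
    }

    ## ---- manifest ----
    hashes <- vapply(inputs, function(f)
        if (is.character(f) && file.exists(f)) unname(md5sum(f))
        else NA_character_, character(1L))
    manifest <- list(stages = stages,
                     seed = config$seed,
                     package_version = as.character(
                         utils::packageVersion("dropquant")),
                     r_version = R.version.string,
                     input_md5 = as.list(hashes))
    write_json(manifest, file.path(config$outdir, "manifest.json"),
               auto_unbox = TRUE, pretty = TRUE)
    invisible(list(extraction = ex, quantification = q, qc = fc,
                   normalized = norm, variable_genes = vg,
                   embedding = emb, n_pcs = npc, clusters = assign,
                   markers = markers, truth = truth, manifest = manifest))
}

## config as plain YAML-serializable values
.serializableConfig <- function(config) {
    x <- unclass(config)
    x$sim <- if (!is.null(x$sim)) unclass(x$sim) else NULL
    x$qc <- unclass(x$qc)
    x
}

#' Read a pipeline config from YAML
#'
#' @param path YAML written by [runPipeline()] or by hand; fields mirror
#'   [pipelineConfig()] (a \code{sim} block becomes a [simConfig()])
#' @export
readPipelineConfig <- function(path) {
    x <- yaml::read_yaml(path)
    if (!is.null(x$sim)) x$sim <- do.call(simConfig, x$sim)
    if (!is.null(x$qc)) x$qc <- do.call(qcParams, x$qc)
    do.call(pipelineConfig, x)
}
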