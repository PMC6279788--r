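#' @import data.table
#' @importFrom Matrix sparseMatrix readMM writeMM Diagonal rowSums colSums t
NULL

## silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
    "read_id", "cell_barcode", "umi", "transcript", "targets", "n_reads",
    "n_targets", "w", ".N", "qname"))

#' Construct a transcript-to-gene map
#'
#' @param isoform,gene parallel character vectors (one row per isoform)
#' @param representative optional named character (gene -> isoform); unset
#'   representatives are NA until chosen with [representativeIsoforms()]
#' @return a \linkS4class{TranscriptGeneMap}
#' @export
transcriptGeneMap <- function(isoform, gene, representative = NULL) {
    genes <- unique(gene)
    rep <- setNames(rep(NA_character_, length(genes)), genes)
    if (!is.null(representative))
        rep[names(representative)] <- representative
    new("TranscriptGeneMap", isoform = as.character(isoform),
        gene = as.character(gene), representative = rep)
}

#' @rdname transcriptGeneMap
#' @param path two-column TSV (isoform_id TAB gene_id, no header)
#' @export
readTranscriptGeneMap <- function(path) {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("isoform", "gene"),
                           colClasses = "character")
    transcriptGeneMap(x$isoform, x$gene)
}

#' @rdname transcriptGeneMap
#' @param object a TranscriptGeneMap
#' @export
writeTranscriptGeneMap <- function(object, path) {
    utils::write.table(data.frame(object@isoform, object@gene), path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}

#' Construct a CountMatrix
#'
#' @param m a features x cells matrix (coerced to sparse) with dimnames
#' @param level "transcript" or "gene"
#' @export
countMatrix <- function(m, level = c("transcript", "gene")) {
    level <- match.arg(level)
    m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    m <- Matrix::drop0(m)
    new("CountMatrix", counts = m, level = level)
}

## ---- SAM ingestion ---------------------------------------------------------

#' Ingest a SAM stream of annotated reads
#'
#' Consumes the SAM an external aligner (the bowtie invocation with
#' \code{-a --best --strata -m 200}, or [emitSam()]) produced from the
#' single annotated FASTQ: multiple alignment lines per query are the
#' multi-mapping reporting mode. Query names must follow the annotated
#' header grammar \code{library:cell_barcode:umi:read_id}. Unmapped
#' records (FLAG 0x4) are dropped and tallied; reads whose deduplicated
#' target set exceeds \code{max_targets} are dropped and tallied (a guard
#' for SAMs produced without the aligner's own \code{-m} cap).
#'
#' @param path SAM file
#' @param max_targets drop reads hitting more than this many transcripts
#' @return list with \code{targets} (data.table: library_id, cell_barcode,
#'   umi, read_id, transcript - one row per distinct read/transcript pair)
#'   and \code{tallies} (alignment lines, reads, unmapped reads,
#'   reads dropped over the target cap)
#' @export
ingestSam <- function(path, max_targets = 200L) {
    hdr <- 0L
    con <- file(path, "r")
    repeat {
        ln <- readLines(con, n = 1L)
        if (!length(ln) || !startsWith(ln, "@")) break
        hdr <- hdr + 1L
    }
    close(con)
    body <- data.table::fread(path, sep = "\t", header = FALSE, skip = hdr,
                              fill = TRUE, select = 1:3,
                              col.names = c("qname", "flag", "transcript"),
                              colClasses = list(character = c(1L, 3L)))
    if (nrow(body) == 0L) {
        return(list(targets = data.table(library_id = character(),
                                         cell_barcode = character(),
                                         umi = character(),
                                         read_id = character(),
                                         transcript = character()),
                    tallies = c(lines = 0L, reads = 0L, unmapped = 0L,
                                over_target_cap = 0L)))
    }
    if (anyNA(body$flag)) stop("truncated SAM record at line ",
                               hdr + which(is.na(body$flag))[1L])
    nLines <- nrow(body)
    nReads <- data.table::uniqueN(body$qname)
    unmapped <- bitwAnd(body$flag, 4L) != 0L
    nUnmapped <- data.table::uniqueN(body$qname[unmapped])
    body <- body[!unmapped]
    fields <- data.table::tstrsplit(body$qname, ":", fixed = TRUE)
    if (length(fields) != 4L || anyNA(fields[[4L]])) {
        bad <- if (length(fields) >= 1L) body$qname[1L] else ""
        stop("malformed_query: query name not in library:barcode:umi:id form: ",
             bad)
    }
    tg <- data.table(library_id = fields[[1L]], cell_barcode = fields[[2L]],
                     umi = fields[[3L]], read_id = fields[[4L]],
                     transcript = body$transcript)
    tg <- unique(tg)
    nt <- tg[, .(n_targets = .N), by = read_id]
    over <- nt$read_id[nt$n_targets > max_targets]
    tg <- tg[!read_id %in% over]
    list(targets = tg[],
         tallies = c(lines = nLines, reads = nReads, unmapped = nUnmapped,
                     over_target_cap = length(over)))
}

## ---- UMI grouping ----------------------------------------------------------

#' Collapse per-read target sets into UMI groups
#'
#' The unit of counting is the (cell barcode, UMI) pair: all reads sharing
#' one are a single molecule observation, so read duplication never adds
#' mass. Under the default \code{"union"} rule a group's target set is the
#' union of its member reads' sets; under \code{"intersection"} it is the
#' intersection of the member sets, falling back to the union when that
#' intersection is empty.
#'
#' @param targets data.table/data.frame as returned in
#'   \code{ingestSam()$targets}
#' @param rule "union" (default) or "intersection"
#' @return data.table with cell_barcode, umi, targets (list column of
#'   transcript ids) and n_reads
#' @export
groupUmis <- function(targets, rule = c("union", "intersection")) {
    rule <- match.arg(rule)
    tg <- data.table::as.data.table(targets)
    if (nrow(tg) == 0L)
        return(data.table(cell_barcode = character(), umi = character(),
                          targets = list(), n_reads = integer()))
    if (rule == "union") {
        grp <- tg[, .(targets = list(sort(unique(transcript))),
                      n_reads = data.table::uniqueN(read_id)),
                  by = .(cell_barcode, umi)]
    } else {
        perRead <- tg[, .(set = list(sort(unique(transcript)))),
                      by = .(cell_barcode, umi, read_id)]
        grp <- perRead[, {
            inter <- Reduce(intersect, set)
            if (!length(inter)) inter <- sort(unique(unlist(set)))
            .(targets = list(sort(inter)), n_reads = .N)
        }, by = .(cell_barcode, umi)]
    }
    grp[]
}

## ---- fractional counting ---------------------------------------------------

#' Fractionally-weighted transcript count matrix from UMI groups
#'
#' Each UMI group distributes one unit of mass equally over its k target
#' transcripts (1/k each), so the matrix total always equals the number of
#' UMI groups. Weights are accumulated in double precision and stored
#' sparsely without thresholding.
#'
#' @param groups output of [groupUmis()]
#' @param transcripts optional full feature namespace; every group target
#'   must be in it (error \code{unknown_transcript} otherwise). Defaults to
#'   the transcripts observed.
#' @param cells optional full cell namespace
#' @return transcript-level \linkS4class{CountMatrix}
#' @export
fractionalCount <- function(groups, transcripts = NULL, cells = NULL) {
    grp <- data.table::as.data.table(groups)
    if (nrow(grp) == 0L) {
        m <- sparseMatrix(i = integer(), j = integer(), x = numeric(),
                          dims = c(length(transcripts), length(cells)),
                          dimnames = list(transcripts, cells))
        return(countMatrix(m, "transcript"))
    }
    k <- lengths(grp$targets)
    long <- data.table(cell_barcode = rep(grp$cell_barcode, k),
                       transcript = unlist(grp$targets, use.names = FALSE),
                       w = rep(1 / k, k))
    if (is.null(transcripts)) transcripts <- sort(unique(long$transcript))
    else if (!all(long$transcript %in% transcripts))
        stop("unknown_transcript: ",
             setdiff(long$transcript, transcripts)[1L])
    if (is.null(cells)) cells <- sort(unique(long$cell_barcode))
    agg <- long[, .(w = sum(w)), by = .(cell_barcode, transcript)]
    m <- sparseMatrix(i = match(agg$transcript, transcripts),
                      j = match(agg$cell_barcode, cells),
                      x = agg$w,
                      dims = c(length(transcripts), length(cells)),
                      dimnames = list(transcripts, cells))
    countMatrix(m, "transcript")
}

## ---- gene aggregation ------------------------------------------------------

#' Choose each gene's representative isoform from the data
#'
#' The representative is the isoform with the highest dataset-wide total
#' count; ties break lexicographically. Isoforms of the gene absent from
#' the matrix count as zero.
#'
#' @param cm transcript-level \linkS4class{CountMatrix}
#' @param map a \linkS4class{TranscriptGeneMap}
#' @return the map with representatives filled in
#' @export
representativeIsoforms <- function(cm, map) {
    stopifnot(countLevel(cm) == "transcript")
    tot <- setNames(rep(0, length(map@isoform)), map@isoform)
    present <- intersect(map@isoform, featureIds(cm))
    tot[present] <- rowSums(counts(cm)[present, , drop = FALSE])
    ord <- order(map@gene, -tot, map@isoform)
    iso <- map@isoform[ord]
    gen <- map@gene[ord]
    first <- !duplicated(gen)
    rep <- setNames(iso[first], gen[first])
    map@representative[names(rep)] <- rep
    validObject(map)
    map
}

#' Aggregate a transcript matrix to gene level
#'
#' Sums each gene's isoform rows per cell; the resulting row is labeled by
#' the gene's representative isoform (chosen with
#' [representativeIsoforms()] if the map does not fix one). Aggregation
#' preserves total mass exactly, so a read multi-mapping only within one
#' gene still contributes exactly 1 to that gene per UMI group.
#'
#' @param cm transcript-level \linkS4class{CountMatrix}
#' @param map a \linkS4class{TranscriptGeneMap} covering every matrix feature
#' @return gene-level \linkS4class{CountMatrix} (rows = representative
#'   isoforms, in gene order)
#' @export
aggregateGenes <- function(cm, map) {
    stopifnot(countLevel(cm) == "transcript")
    feats <- featureIds(cm)
    miss <- setdiff(feats, map@isoform)
    if (length(miss)) stop("unmapped_isoform: ", miss[1L])
    if (anyNA(map@representative)) map <- representativeIsoforms(cm, map)
    gene <- map@gene[match(feats, map@isoform)]
    genes <- sort(unique(gene))
    A <- sparseMatrix(i = match(gene, genes), j = seq_along(feats), x = 1,
                      dims = c(length(genes), length(feats)),
                      dimnames = list(genes, feats))
    gm <- A %*% counts(cm)
    rownames(gm) <- unname(map@representative[genes])
    countMatrix(gm, "gene")
}

## ---- MTX I/O ---------------------------------------------------------------

#' Write / read a CountMatrix as MatrixMarket with sidecars
#'
#' Writes \code{matrix.mtx}, \code{features.tsv} (feature id and level) and
#' \code{barcodes.tsv} into a directory.
#'
#' @param cm a \linkS4class{CountMatrix}
#' @param dir output directory (created if needed)
#' @export
writeCountMatrix <- function(cm, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeMM(counts(cm), file.path(dir, "matrix.mtx"))
    writeLines(paste(featureIds(cm), countLevel(cm), sep = "\t"),
               file.path(dir, "features.tsv"))
    writeLines(cellIds(cm), file.path(dir, "barcodes.tsv"))
    invisible(dir)
}

#' @rdname writeCountMatrix
#' @export
readCountMatrix <- function(dir) {
    m <- as(readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
    feat <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                              colClasses = "character")
    rownames(m) <- feat[[1L]]
    colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
    countMatrix(m, feat[[2L]][1L])
}

#' One call from SAM to gene matrix
#'
#' Convenience wrapper: [ingestSam()] then [groupUmis()],
#' [fractionalCount()] and [aggregateGenes()].
#'
#' @inheritParams ingestSam
#' @inheritParams groupUmis
#' @param map a \linkS4class{TranscriptGeneMap}
#' @param transcripts optional full transcript namespace
#' @return list: \code{transcript} and \code{gene}
#'   \linkS4class{CountMatrix}es, \code{map} (with representatives),
#'   \code{groups}, \code{tallies}
#' @export
countSam <- function(path, map, rule = c("union", "intersection"),
                     max_targets = 200L, transcripts = NULL) {
    ing <- ingestSam(path, max_targets = max_targets)
    grp <- groupUmis(ing$targets, rule = rule)
    tx <- fractionalCount(grp, transcripts = transcripts)
    map <- representativeIsoforms(tx, map)
    gene <- aggregateGenes(tx, map)
    tallies <- c(ing$tallies, umi_groups = nrow(grp))
    list(transcript = tx, gene = gene, map = map, groups = grp,
         tallies = tallies)
}
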