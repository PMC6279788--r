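#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

## A stream slice is list(stream = "r1"|"r2"|"i1"|"i2", start, end),
## 0-based half-open, matching how sequencer cycle windows are quoted.

.validSlice <- function(s, what) {
    if (!is.list(s) || !all(c("stream", "start", "end") %in% names(s)))
        return(sprintf("%s must be list(stream, start, end)", what))
    if (!s$stream %in% c("r1", "r2", "i1", "i2"))
        return(sprintf("%s: unknown stream '%s'", what, s$stream))
    if (s$start < 0 || s$end <= s$start)
        return(sprintf("%s: need 0 <= start < end", what))
    NULL
}

#' ReadLayout: where each field lives in the four sequencer streams
#'
#' Describes the inDrops V3 run geometry: which of the four parallel
#' streams (biological read \code{r1}, barcode/UMI read \code{r2}, sample
#' index \code{i1}, second barcode index \code{i2}) carries the biological
#' sequence, the two cell-barcode halves, the UMI and the library index,
#' each as a 0-based half-open slice.
#'
#' @slot bio,cb1,cb2,umi,lib each a \code{list(stream, start, end)}
#' @seealso [indropsV3Layout()] for the default V3 geometry
#' @export
setClass("ReadLayout",
    representation(bio = "list", cb1 = "list", cb2 = "list",
                   umi = "list", lib = "list"))

setValidity("ReadLayout", function(object) {
    msgs <- character()
    parts <- list(bio = object@bio, cb1 = object@cb1, cb2 = object@cb2,
                  umi = object@umi, lib = object@lib)
    for (nm in names(parts)) {
        m <- .validSlice(parts[[nm]], nm)
        if (!is.null(m)) msgs <- c(msgs, m)
    }
    if (length(msgs)) return(msgs)
    ## slices must not overlap within a stream
    for (st in c("r1", "r2", "i1", "i2")) {
        sl <- Filter(function(s) s$stream == st, parts)
        if (length(sl) > 1L) {
            iv <- do.call(rbind, lapply(sl, function(s) c(s$start, s$end)))
            iv <- iv[order(iv[, 1L]), , drop = FALSE]
            if (any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
                msgs <- c(msgs, sprintf("overlapping slices in stream %s", st))
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' BarcodeWhitelist: the set of legal barcode half sequences
#'
#' @slot entries unique nucleotide strings, all of the same width
#' @slot width common barcode length
#' @export
setClass("BarcodeWhitelist",
    representation(entries = "character", width = "integer"))

setValidity("BarcodeWhitelist", function(object) {
    e <- object@entries
    if (!length(e)) return("whitelist is empty")
    if (anyDuplicated(e)) return("whitelist entries must be unique")
    if (any(nchar(e) != object@width))
        return("all whitelist entries must have the stated width")
    if (any(grepl("[^ACGT]", e)))
        return("whitelist entries must be over {A,C,G,T}")
    TRUE
})

#' TranscriptGeneMap: isoform-to-gene mapping with representative isoforms
#'
#' Every isoform maps to exactly one gene. A gene's representative isoform
#' (the label used for its aggregated count row) is one of its isoforms;
#' it may be unset (\code{NA}) until chosen from data.
#'
#' @slot isoform,gene parallel character vectors
#' @slot representative named character, one entry per gene (possibly NA)
#' @export
setClass("TranscriptGeneMap",
    representation(isoform = "character", gene = "character",
                   representative = "character"))

setValidity("TranscriptGeneMap", function(object) {
    if (length(object@isoform) != length(object@gene))
        return("isoform and gene vectors differ in length")
    if (anyDuplicated(object@isoform))
        return("an isoform may map to only one gene")
    rep <- object@representative
    genes <- unique(object@gene)
    if (!all(names(rep) %in% genes))
        return("representative entries for unknown genes")
    ok <- is.na(rep) | rep %in% object@isoform
    if (!all(ok)) return("a representative must be one of the gene's isoforms")
    for (g in names(rep)[!is.na(rep)]) {
        if (object@gene[match(rep[[g]], object@isoform)] != g)
            return(sprintf("representative of %s is not its own isoform", g))
    }
    TRUE
})

#' CountMatrix: sparse features x cells matrix of fractional UMI counts
#'
#' Rows are features (transcripts, or representative isoforms after gene
#' aggregation), columns are cell barcodes. Values are non-negative
#' fractional UMI-group masses; explicit zeros are dropped.
#'
#' @slot counts a \linkS4class{dgCMatrix}
#' @slot level "transcript" or "gene"
#' @export
setClass("CountMatrix",
    representation(counts = "dgCMatrix", level = "character"))

setValidity("CountMatrix", function(object) {
    m <- object@counts
    if (!length(object@level) == 1L || !object@level %in% c("transcript", "gene"))
        return("level must be 'transcript' or 'gene'")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("counts must carry feature and cell names")
    if (anyDuplicated(rownames(m))) return("duplicate feature identifiers")
    if (anyDuplicated(colnames(m))) return("duplicate cell identifiers")
    v <- m@x
    if (length(v) && (any(!is.finite(v)) || any(v < 0)))
        return("counts must be finite and non-negative")
    TRUE
})

#' ClusterAssignment: per-cell labels plus a replayable merge history
#'
#' @slot labels integer labels, contiguous from 1, named by cell
#' @slot resolution the community-detection resolution used
#' @slot mergeHistory data.frame with one row per merge
#'   (\code{cluster_a}, \code{cluster_b}, \code{accuracy}, \code{reason})
#' @export
setClass("ClusterAssignment",
    representation(labels = "integer", resolution = "numeric",
                   mergeHistory = "data.frame"))

setValidity("ClusterAssignment", function(object) {
    l <- object@labels
    if (!length(l)) return("no cells")
    if (is.null(names(l))) return("labels must be named by cell")
    u <- sort(unique(l))
    if (!identical(u, seq_along(u)))
        return("labels must be contiguous integers starting at 1")
    TRUE
})

#' SimTruth: ground truth emitted by the read simulator
#'
#' @slot counts integer genes x cells matrix of true molecule counts
#' @slot labels character population label per cell (named)
#' @slot provenance data.frame, one row per emitted read (cell, UMI,
#'   source isoform, start, ambient flag, observed barcode)
#' @slot config the SimConfig the truth was drawn under
#' @export
setClass("SimTruth",
    representation(counts = "matrix", labels = "character",
                   provenance = "data.frame", config = "list"))

setValidity("SimTruth", function(object) {
    if (!is.numeric(object@counts)) return("counts must be numeric")
    if (any(object@counts < 0)) return("negative molecule counts")
    if (length(object@labels) != ncol(object@counts))
        return("one label per cell required")
    TRUE
})
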