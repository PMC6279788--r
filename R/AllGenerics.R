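#' @importFrom BiocGenerics counts
NULL

#' @describeIn CountMatrix-class the underlying sparse matrix
#' @param object a CountMatrix
#' @export
setMethod("counts", "CountMatrix", function(object) object@counts)

#' Accessors for dropquant containers
#'
#' @param object a dropquant S4 object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("countLevel", function(object) standardGeneric("countLevel"))
#' @rdname accessors
#' @export
setMethod("countLevel", "CountMatrix", function(object) object@level)

#' @rdname accessors
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setMethod("featureIds", "CountMatrix", function(object) rownames(object@counts))

#' @rdname accessors
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setMethod("cellIds", "CountMatrix", function(object) colnames(object@counts))

#' @rdname accessors
#' @export
setGeneric("txIds", function(object) standardGeneric("txIds"))
#' @rdname accessors
#' @export
setMethod("txIds", "TranscriptGeneMap", function(object) object@isoform)

#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setMethod("geneIds", "TranscriptGeneMap", function(object) object@gene)

#' @rdname accessors
#' @export
setGeneric("representativeIsoform",
           function(object) standardGeneric("representativeIsoform"))
#' @rdname accessors
#' @export
setMethod("representativeIsoform", "TranscriptGeneMap",
          function(object) object@representative)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("mergeHistory", function(object) standardGeneric("mergeHistory"))
#' @rdname accessors
#' @export
setMethod("mergeHistory", "ClusterAssignment",
          function(object) object@mergeHistory)

#' @rdname accessors
#' @export
setGeneric("trueCounts", function(object) standardGeneric("trueCounts"))
#' @rdname accessors
#' @export
setMethod("trueCounts", "SimTruth", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("trueLabels", function(object) standardGeneric("trueLabels"))
#' @rdname accessors
#' @export
setMethod("trueLabels", "SimTruth", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("readProvenance", function(object) standardGeneric("readProvenance"))
#' @rdname accessors
#' @export
setMethod("readProvenance", "SimTruth", function(object) object@provenance)

#' @rdname accessors
#' @export
setGeneric("whitelistEntries",
           function(object) standardGeneric("whitelistEntries"))
#' @rdname accessors
#' @export
setMethod("whitelistEntries", "BarcodeWhitelist", function(object) object@entries)

#' @rdname accessors
#' @export
setGeneric("barcodeWidth", function(object) standardGeneric("barcodeWidth"))
#' @rdname accessors
#' @export
setMethod("barcodeWidth", "BarcodeWhitelist", function(object) object@width)

setMethod("dim", "CountMatrix", function(x) dim(x@counts))

setMethod("show", "CountMatrix", function(object) {
    cat(sprintf("CountMatrix (%s level): %d features x %d cells, %d nonzero\n",
                object@level, nrow(object@counts), ncol(object@counts),
                length(object@counts@x)))
})

setMethod("show", "ClusterAssignment", function(object) {
    k <- length(unique(object@labels))
    cat(sprintf("ClusterAssignment: %d cells in %d clusters (resolution %.2f, %d merges)\n",
                length(object@labels), k, object@resolution,
                nrow(object@mergeHistory)))
})

setMethod("show", "TranscriptGeneMap", function(object) {
    cat(sprintf("TranscriptGeneMap: %d isoforms, %d genes (%d representatives set)\n",
                length(object@isoform), length(unique(object@gene)),
                sum(!is.na(object@representative))))
})

setMethod("show", "BarcodeWhitelist", function(object) {
    cat(sprintf("BarcodeWhitelist: %d entries of width %d\n",
                length(object@entries), object@width))
})

setMethod("show", "SimTruth", function(object) {
    cat(sprintf("SimTruth: %d genes x %d cells, %d populations, %d reads emitted\n",
                nrow(object@counts), ncol(object@counts),
                length(unique(object@labels)), nrow(object@provenance)))
})
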