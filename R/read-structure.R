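#' @importFrom Biostrings DNAStringSet BStringSet readDNAStringSet
#'   writeXStringSet
#' @importFrom S4Vectors mcols
#' @importFrom stats setNames
NULL

#' Construct a read layout
#'
#' @param bio,cb1,cb2,umi,lib each \code{list(stream, start, end)} with
#'   stream one of \code{"r1","r2","i1","i2"} and a 0-based half-open slice.
#' @return a \linkS4class{ReadLayout}
#' @export
readLayout <- function(bio, cb1, cb2, umi, lib) {
    new("ReadLayout", bio = bio, cb1 = cb1, cb2 = cb2, umi = umi, lib = lib)
}

#' The default inDrops V3 layout
#'
#' Run geometry 61 + 14 + 8 + 8: the biological sequence is the 61-cycle
#' read 1; the 14-cycle read 2 carries the second cell-barcode half
#' (cycles 0-8) followed by the 6-nt UMI (cycles 8-14); index 2 carries
#' the first barcode half and index 1 the library (sample) index. The
#' sequencing run states only the cycle counts; the field assignment is
#' the inDrops V3 convention and every slice is configurable through
#' [readLayout()].
#'
#' @return a \linkS4class{ReadLayout}
#' @export
indropsV3Layout <- function() {
    readLayout(bio = list(stream = "r1", start = 0L, end = 61L),
               cb1 = list(stream = "i2", start = 0L, end = 8L),
               cb2 = list(stream = "r2", start = 0L, end = 8L),
               umi = list(stream = "r2", start = 8L, end = 14L),
               lib = list(stream = "i1", start = 0L, end = 8L))
}

.layoutParts <- function(layout)
    list(bio = layout@bio, cb1 = layout@cb1, cb2 = layout@cb2,
         umi = layout@umi, lib = layout@lib)

## minimum stream lengths the layout requires
.requiredLengths <- function(layout) {
    req <- c(r1 = 0L, r2 = 0L, i1 = 0L, i2 = 0L)
    for (s in .layoutParts(layout)) req[s$stream] <- max(req[s$stream], s$end)
    req
}

.slice <- function(seqs, s) substr(seqs, s$start + 1L, s$end)

## ---- FASTQ I/O (Biostrings-backed) -----------------------------------------

.readFastq <- function(path, with.qual = FALSE) {
    x <- readDNAStringSet(path, format = "fastq", with.qualities = with.qual)
    ids <- sub("[ \t].*$", "", names(x))
    out <- data.frame(id = ids, seq = as.character(x))
    if (with.qual) out$qual <- as.character(mcols(x)$qualities)
    out
}

.writeFastq <- function(id, seq, qual, path) {
    x <- DNAStringSet(seq)
    names(x) <- id
    writeXStringSet(x, path, format = "fastq",
                    qualities = BStringSet(qual),
                    compress = grepl("\\.gz$", path))
    invisible(path)
}

## ---- quartet parsing -------------------------------------------------------

#' Parse raw FASTQ quartets into uncorrected annotated reads
#'
#' Slices the four parallel streams of each read according to the layout.
#' No barcode correction happens here; the returned barcode halves are
#' verbatim. A quartet is rejected (with a reason code) when a stream is
#' shorter than the layout requires (\code{short_read}) or the UMI slice
#' contains an N (\code{N_in_umi}).
#'
#' @param quartets data.frame with columns \code{read_id}, \code{r1_seq},
#'   \code{r1_qual}, \code{r2_seq}, \code{r2_qual}, \code{i1_seq},
#'   \code{i2_seq}
#' @param layout a \linkS4class{ReadLayout}
#' @return list with \code{accepted} (data.frame: read_id, cb1, cb2,
#'   cell_barcode, umi, lib_index, bio_seq, bio_qual) and \code{rejected}
#'   (data.frame: read_id, reason)
#' @export
parseQuartets <- function(quartets, layout = indropsV3Layout()) {
    stopifnot(is(layout, "ReadLayout"))
    req <- .requiredLengths(layout)
    n <- nrow(quartets)
    if (n == 0L) {
        return(list(
            accepted = data.frame(read_id = character(), cb1 = character(),
                                  cb2 = character(), cell_barcode = character(),
                                  umi = character(), lib_index = character(),
                                  bio_seq = character(), bio_qual = character()),
            rejected = data.frame(read_id = character(), reason = character())))
    }
    lens <- cbind(r1 = nchar(quartets$r1_seq), r2 = nchar(quartets$r2_seq),
                  i1 = nchar(quartets$i1_seq), i2 = nchar(quartets$i2_seq))
    short <- (lens[, "r1"] < req["r1"]) | (lens[, "r2"] < req["r2"]) |
             (lens[, "i1"] < req["i1"]) | (lens[, "i2"] < req["i2"])
    p <- .layoutParts(layout)
    streamSeq <- function(st) quartets[[paste0(st, "_seq")]]
    umi <- .slice(streamSeq(p$umi$stream), p$umi)
    nInUmi <- !short & grepl("N", umi, fixed = TRUE)
    keep <- !short & !nInUmi
    cb1 <- .slice(streamSeq(p$cb1$stream), p$cb1)[keep]
    cb2 <- .slice(streamSeq(p$cb2$stream), p$cb2)[keep]
    bioq <- quartets[[paste0(p$bio$stream, "_qual")]]
    if (is.null(bioq)) bioq <- strrep("I", nchar(streamSeq(p$bio$stream)))
    accepted <- data.frame(
        read_id = quartets$read_id[keep],
        cb1 = cb1, cb2 = cb2,
        cell_barcode = paste0(cb1, cb2),
        umi = umi[keep],
        lib_index = .slice(streamSeq(p$lib$stream), p$lib)[keep],
        bio_seq = .slice(streamSeq(p$bio$stream), p$bio)[keep],
        bio_qual = .slice(bioq, p$bio)[keep])
    rejected <- data.frame(
        read_id = quartets$read_id[!keep],
        reason = ifelse(short[!keep], "short_read", "N_in_umi"))
    list(accepted = accepted, rejected = rejected)
}

#' Parse a single raw quartet
#'
#' Scalar convenience over [parseQuartets()].
#'
#' @param quartet a one-row data.frame or named list with the quartet fields
#' @inheritParams parseQuartets
#' @return on acceptance, a named list of the sliced fields with
#'   \code{$accepted = TRUE}; on rejection, \code{list(accepted = FALSE,
#'   reason = <code>)}
#' @export
parseQuartet <- function(quartet, layout = indropsV3Layout()) {
    res <- parseQuartets(as.data.frame(as.list(quartet)), layout)
    if (nrow(res$accepted)) c(list(accepted = TRUE), as.list(res$accepted[1L, ]))
    else list(accepted = FALSE, reason = res$rejected$reason[1L])
}

## ---- barcode whitelists and correction -------------------------------------

#' Construct / read a barcode whitelist
#'
#' @param entries character vector of equal-length barcodes over ACGT
#' @return a \linkS4class{BarcodeWhitelist}
#' @export
barcodeWhitelist <- function(entries) {
    new("BarcodeWhitelist", entries = unique(entries),
        width = nchar(entries[1L]))
}

#' @rdname barcodeWhitelist
#' @param path plain-text file, one barcode per line
#' @export
readBarcodeWhitelist <- function(path) {
    barcodeWhitelist(readLines(path, warn = FALSE))
}

#' @rdname barcodeWhitelist
#' @param object a BarcodeWhitelist
#' @export
writeBarcodeWhitelist <- function(object, path) {
    writeLines(object@entries, path)
    invisible(path)
}

## pairwise Hamming distances between query strings and whitelist entries;
## N (or any non-ACGT symbol) counts as a mismatch at its position.
.hammingToWhitelist <- function(queries, entries, width) {
    qm <- matrix(unlist(strsplit(queries, "", fixed = TRUE), use.names = FALSE),
                 ncol = width, byrow = TRUE)
    wm <- matrix(unlist(strsplit(entries, "", fixed = TRUE), use.names = FALSE),
                 ncol = width, byrow = TRUE)
    d <- matrix(0L, nrow = length(queries), ncol = length(entries))
    for (j in seq_len(width))
        d <- d + outer(qm[, j], wm[, j], "!=")
    d
}

#' Correct observed barcodes against a whitelist
#'
#' An observed barcode is replaced by the unique whitelist entry within
#' Hamming distance \code{max_hamming} (N counts as a mismatch). If no
#' entry is in range the read is rejected with \code{no_match}; if two or
#' more entries tie at the minimal in-range distance, with
#' \code{ambiguous}. Substitutions only - indels are out of scope.
#'
#' @param observed character vector of observed barcodes (whitelist width)
#' @param whitelist a \linkS4class{BarcodeWhitelist}
#' @param max_hamming maximum correctable distance (default 1)
#' @return list with \code{barcode} (corrected, NA where rejected) and
#'   \code{reason} (NA, "no_match" or "ambiguous")
#' @export
correctBarcodes <- function(observed, whitelist, max_hamming = 1L) {
    stopifnot(is(whitelist, "BarcodeWhitelist"))
    w <- whitelist@width
    if (length(observed) && any(nchar(observed) != w))
        stop("observed barcodes must match the whitelist width")
    out <- character(length(observed))
    reason <- rep(NA_character_, length(observed))
    exact <- match(observed, whitelist@entries)
    hit <- !is.na(exact)
    out[hit] <- whitelist@entries[exact[hit]]
    todo <- which(!hit)
    if (length(todo)) {
        uq <- unique(observed[todo])
        d <- .hammingToWhitelist(uq, whitelist@entries, w)
        best <- apply(d, 1L, min)
        nbest <- rowSums(d == best)
        corr <- rep(NA_character_, length(uq))
        rs <- rep(NA_character_, length(uq))
        inRange <- best <= max_hamming
        amb <- inRange & nbest > 1L
        uniq <- inRange & nbest == 1L
        corr[uniq] <- whitelist@entries[apply(d[uniq, , drop = FALSE], 1L,
                                              which.min)]
        rs[!inRange] <- "no_match"
        rs[amb] <- "ambiguous"
        m <- match(observed[todo], uq)
        out[todo] <- corr[m]
        reason[todo] <- rs[m]
    }
    out[is.na(reason) & out == ""] <- NA_character_
    list(barcode = ifelse(is.na(reason), out, NA_character_), reason = reason)
}

#' @rdname correctBarcodes
#' @details `correctBarcode()` is the scalar form: it returns the corrected
#'   barcode, or `NA` with a `"reason"` attribute on rejection.
#' @export
correctBarcode <- function(observed, whitelist, max_hamming = 1L) {
    res <- correctBarcodes(observed[1L], whitelist, max_hamming)
    if (is.na(res$barcode)) structure(NA_character_, reason = res$reason)
    else res$barcode
}

## ---- sample sheet ----------------------------------------------------------

#' Read a sample sheet (library index -> sample name)
#'
#' @param path TSV with two columns: index sequence, sample name (no header)
#' @return named character vector, names = index sequences
#' @export
readSampleSheet <- function(path) {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("index", "sample"),
                           colClasses = "character")
    setNames(x$sample, x$index)
}

## ---- annotated FASTQ -------------------------------------------------------

.HEADER_SEP <- ":"

#' Encode annotated reads into a single FASTQ
#'
#' One record per corrected read. The header grammar is
#' \code{@library:cell_barcode:umi:read_id}; the sequence and quality lines
#' are the biological read. \code{:} is forbidden inside fields.
#'
#' @param reads data.frame with columns \code{library_id},
#'   \code{cell_barcode}, \code{umi}, \code{read_id}, \code{bio_seq},
#'   \code{bio_qual}
#' @param path output FASTQ (gz-transparent by extension)
#' @export
encodeAnnotatedFastq <- function(reads, path) {
    fields <- c("library_id", "cell_barcode", "umi", "read_id")
    for (f in fields)
        if (any(grepl(.HEADER_SEP, reads[[f]], fixed = TRUE)))
            stop("malformed_field: '", .HEADER_SEP, "' inside ", f)
    if (nrow(reads) == 0L) {
        file.create(path)
        return(invisible(path))
    }
    hdr <- paste(reads$library_id, reads$cell_barcode, reads$umi,
                 reads$read_id, sep = .HEADER_SEP)
    .writeFastq(hdr, reads$bio_seq, reads$bio_qual, path)
}

#' Decode an annotated FASTQ back into reads
#'
#' Inverse of [encodeAnnotatedFastq()]; \code{decode(encode(x))} recovers
#' \code{x} exactly.
#'
#' @param path annotated FASTQ
#' @return data.frame with library_id, cell_barcode, umi, read_id,
#'   bio_seq, bio_qual
#' @export
decodeAnnotatedFastq <- function(path) {
    empty <- data.frame(library_id = character(), cell_barcode = character(),
                        umi = character(), read_id = character(),
                        bio_seq = character(), bio_qual = character())
    if (file.size(path) == 0) return(empty)
    x <- .readFastq(path, with.qual = TRUE)
    if (nrow(x) == 0L) return(empty)
    parts <- strsplit(x$id, .HEADER_SEP, fixed = TRUE)
    bad <- which(lengths(parts) != 4L)
    if (length(bad))
        stop("malformed_header at record ", bad[1L], ": ", x$id[bad[1L]])
    m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
    data.frame(library_id = m[, 1L], cell_barcode = m[, 2L], umi = m[, 3L],
               read_id = m[, 4L], bio_seq = x$seq, bio_qual = x$qual)
}

## ---- end-to-end extraction -------------------------------------------------

#' Extract annotated reads from four parallel FASTQ streams
#'
#' Runs the full read-structure stage: parse each quartet under the
#' layout, correct both cell-barcode halves against their whitelists,
#' match the library index exactly against the sample sheet, and
#' (optionally) write the surviving reads as a single annotated FASTQ.
#' Quality strings are carried through but never used for filtering.
#'
#' @param r1,r2,i1,i2 paths to the four FASTQ streams (gz-transparent)
#' @param layout a \linkS4class{ReadLayout}
#' @param whitelist1,whitelist2 \linkS4class{BarcodeWhitelist}s for the two
#'   barcode halves
#' @param sample_sheet named character vector (index sequence -> sample
#'   name), e.g. from [readSampleSheet()]
#' @param max_hamming maximum barcode correction distance (default 1)
#' @param output optional path for the single annotated FASTQ
#' @return list with \code{reads} (data.frame of accepted annotated reads)
#'   and \code{tallies} (named integer: input, accepted and per-reason
#'   rejection counts; accepted + rejections = input)
#' @export
extractReads <- function(r1, r2, i1, i2, layout = indropsV3Layout(),
                         whitelist1, whitelist2, sample_sheet,
                         max_hamming = 1L, output = NULL) {
    f1 <- .readFastq(r1, with.qual = TRUE)
    f2 <- .readFastq(r2)
    fi1 <- .readFastq(i1)
    fi2 <- .readFastq(i2)
    n <- nrow(f1)
    if (nrow(f2) != n || nrow(fi1) != n || nrow(fi2) != n)
        stop("the four FASTQ streams have different record counts")
    if (n && !(all(f1$id == f2$id) && all(f1$id == fi1$id) &&
               all(f1$id == fi2$id)))
        stop("read identifiers disagree across streams")
    quartets <- data.frame(read_id = f1$id,
                           r1_seq = f1$seq, r1_qual = f1$qual,
                           r2_seq = f2$seq, r2_qual = strrep("I", nchar(f2$seq)),
                           i1_seq = fi1$seq, i2_seq = fi2$seq)
    parsed <- parseQuartets(quartets, layout)
    acc <- parsed$accepted
    tallies <- c(input = n,
                 short_read = sum(parsed$rejected$reason == "short_read"),
                 N_in_umi = sum(parsed$rejected$reason == "N_in_umi"))

    c1 <- correctBarcodes(acc$cb1, whitelist1, max_hamming)
    c2 <- correctBarcodes(acc$cb2, whitelist2, max_hamming)
    bcOk <- is.na(c1$reason) & is.na(c2$reason)
    reasons <- ifelse(!is.na(c1$reason), c1$reason, c2$reason)
    tallies["barcode_no_match"] <- sum(reasons[!bcOk] == "no_match")
    tallies["barcode_ambiguous"] <- sum(reasons[!bcOk] == "ambiguous")

    lib <- unname(sample_sheet[acc$lib_index])
    libOk <- !is.na(lib)
    tallies["library_unknown"] <- sum(bcOk & !libOk)

    keep <- bcOk & libOk
    reads <- data.frame(library_id = lib[keep],
                        cell_barcode = paste0(c1$barcode[keep], c2$barcode[keep]),
                        umi = acc$umi[keep],
                        read_id = acc$read_id[keep],
                        bio_seq = acc$bio_seq[keep],
                        bio_qual = acc$bio_qual[keep])
    tallies["accepted"] <- nrow(reads)
    if (!is.null(output)) encodeAnnotatedFastq(reads, output)
    list(reads = reads, tallies = tallies)
}
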