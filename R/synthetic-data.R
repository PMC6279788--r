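#' @import data.table
#' @importFrom stats rgamma rnbinom rgeom runif rnorm
NULL

utils::globalVariables(c(
    "cell", "gene", "isoform", "start", "is_ambient", "cb_true",
    "cb_observed", "population", "block_len", "block_group", "n_copies"))

#' Simulation configuration
#'
#' Defines the study conditions the simulator emulates: a multi-isoform
#' toy transcriptome whose shared sequence blocks induce exact, known
#' multi-mapping; planted cell populations with distinct expression
#' programs (gamma-distributed gene means, population-specific genes
#' shifted by a log2 fold change, negative-binomial molecule counts);
#' and inDrops-style raw reads with UMI duplication, cell-barcode
#' sequencing errors and an ambient-molecule background.
#'
#' @param seed RNG seed (mandatory; all stages derive sub-seeds from it)
#' @param n_genes number of genes (default 100)
#' @param isoforms_per_gene isoforms per gene (default 2)
#' @param isoform_length isoform length in nt (default 500)
#' @param shared_block_fraction fraction of each isoform shared between a
#'   gene's isoforms (and across paralog pairs), inducing multi-mapping
#'   (default 0.2)
#' @param n_paralog_pairs gene pairs sharing their block across genes
#'   (default 5)
#' @param n_populations planted cell populations (default 3)
#' @param cells_per_population cells per population (default 70)
#' @param de_genes_per_population population-specific genes (default 20)
#' @param de_log2fc log2 fold change of population-specific genes
#'   (default 2)
#' @param gene_mean_shape,gene_mean_scale gamma parameters for baseline
#'   gene mean weights (default shape 2, scale 1)
#' @param nb_dispersion negative-binomial size parameter of molecule
#'   counts; smaller = more overdispersed (default 2)
#' @param molecules_per_cell expected true molecules per cell (default
#'   1000; with the default duplication rate this yields about 2000
#'   reads per cell)
#' @param read_length biological read length (default 61)
#' @param umi_length UMI length in nt (default 6)
#' @param umi_duplication_rate geometric extra-read probability per
#'   molecule; 0.5 gives on average 2 reads per molecule (default 0.5)
#' @param barcode_error_rate probability a read's 16-nt cell barcode
#'   carries one substitution (default 0.01)
#' @param ambient_fraction fraction of emitted reads drawn from the pooled
#'   expression profile and assigned to a random cell (default 0.02)
#' @param barcode_half_length length of each barcode half (default 8)
#' @param whitelist_size entries per half whitelist (default 48)
#' @param library_index the 8-nt sample index on the i1 stream
#' @return a list of class \code{SimConfig}
#' @export
simConfig <- function(seed,
                      n_genes = 100L, isoforms_per_gene = 2L,
                      isoform_length = 500L, shared_block_fraction = 0.2,
                      n_paralog_pairs = 5L,
                      n_populations = 3L, cells_per_population = 70L,
                      de_genes_per_population = 20L, de_log2fc = 2,
                      gene_mean_shape = 2, gene_mean_scale = 1,
                      nb_dispersion = 2, molecules_per_cell = 1000L,
                      read_length = 61L, umi_length = 6L,
                      umi_duplication_rate = 0.5, barcode_error_rate = 0.01,
                      ambient_fraction = 0.02, barcode_half_length = 8L,
                      whitelist_size = 48L, library_index = "ACGTACGT") {
    if (missing(seed)) stop("seed is mandatory")
    rates <- c(shared_block_fraction, umi_duplication_rate,
               barcode_error_rate, ambient_fraction)
    stopifnot(all(rates >= 0), all(rates <= 1), umi_duplication_rate < 1,
              ambient_fraction < 1, n_genes >= 1,
              isoform_length >= read_length,
              n_populations * de_genes_per_population <= n_genes,
               nchar(library_index) == 8L)
    structure(as.list(environment()), class = "SimConfig")
}

## integer 0 .. 4^len - 1  ->  nucleotide string
.intToKmer <- function(idx, len) {
    bases <- c("A", "C", "G", "T")
    out <- matrix("", nrow = length(idx), ncol = len)
    for (p in seq_len(len))
        out[, p] <- bases[(idx %/% 4^(len - p)) %% 4 + 1]
    do.call(paste0, as.data.frame(out, stringsAsFactors = FALSE))
}

.randomSeq <- function(n, len)
    vapply(seq_len(n),
           function(i) paste(sample(c("A", "C", "G", "T"), len,
                                    replace = TRUE), collapse = ""),
           character(1L))

#' Generate a random barcode whitelist
#'
#' Barcodes are drawn uniformly and kept only at pairwise Hamming distance
#' at least \code{min_dist}, so single-substitution errors are always
#' unambiguously correctable.
#'
#' @param n entries
#' @param width barcode length (default 8)
#' @param min_dist minimum pairwise Hamming distance (default 3)
#' @param seed RNG seed
#' @return a \linkS4class{BarcodeWhitelist}
#' @export
makeBarcodeWhitelist <- function(n, width = 8L, min_dist = 3L, seed = 0L) {
    set.seed(seed)
    kept <- character(0L)
    tries <- 0L
    while (length(kept) < n) {
        cand <- .randomSeq(1L, width)
        tries <- tries + 1L
        if (tries > 10000L * n) stop("cannot place ", n, " barcodes at distance ",
                                     min_dist)
        if (length(kept)) {
            d <- .hammingToWhitelist(cand, kept, width)
            if (min(d) < min_dist) next
        }
        kept <- c(kept, cand)
    }
    barcodeWhitelist(kept)
}

#' Build the toy multi-isoform transcriptome
#'
#' Each gene's isoforms share an identical leading block of
#' \code{shared_block_fraction * isoform_length} nt and are random beyond
#' it; designated paralog gene pairs additionally share one block across
#' genes. Reads falling entirely inside a block therefore multi-map to
#' every isoform carrying it - exactly and knowably. Deterministic for a
#' given config seed.
#'
#' @param config a [simConfig()]
#' @return list of class \code{SimTranscriptome}: \code{sequences}
#'   (DNAStringSet), \code{map} (\linkS4class{TranscriptGeneMap}),
#'   \code{iso_info} (data.frame: isoform, gene, block_group, block_len,
#'   length)
#' @export
makeTranscriptome <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    if (config$n_genes < 1L) stop("degenerate config: 0 genes")
    set.seed(config$seed + 1L)
    L <- config$isoform_length
    B <- round(config$shared_block_fraction * L)
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    ## paralog pairs share a block group (and its prefix sequence)
    group <- genes
    npp <- min(config$n_paralog_pairs, config$n_genes %/% 2L)
    if (npp > 0L && B > 0L) {
        for (p in seq_len(npp))
            group[2L * p] <- group[2L * p - 1L]
    }
    prefixes <- setNames(.randomSeq(length(unique(group)), max(B, 1L)),
                         unique(group))
    iso <- character(0L); isoGene <- character(0L)
    seqs <- character(0L)
    for (gi in seq_along(genes)) {
        g <- genes[gi]
        for (j in seq_len(config$isoforms_per_gene)) {
            body <- .randomSeq(1L, L - B)
            s <- if (B > 0L) paste0(substr(prefixes[[group[gi]]], 1L, B), body)
                 else body
            iso <- c(iso, paste0(g, ".i", j))
            isoGene <- c(isoGene, g)
            seqs <- c(seqs, s)
        }
    }
    info <- data.frame(isoform = iso, gene = isoGene,
                       block_group = group[match(isoGene, genes)],
                       block_len = if (B > 0L) B else 0L,
                       length = nchar(seqs))
    sequences <- Biostrings::DNAStringSet(setNames(seqs, iso))
    list(sequences = sequences,
         map = transcriptGeneMap(iso, isoGene),
         iso_info = info) |>
        structure(class = "SimTranscriptome")
}

#' @rdname makeTranscriptome
#' @param txome a SimTranscriptome
#' @param fasta,map_tsv output paths (FASTA and isoform TAB gene TSV)
#' @export
writeTranscriptome <- function(txome, fasta, map_tsv) {
    Biostrings::writeXStringSet(txome$sequences, fasta)
    writeTranscriptGeneMap(txome$map, map_tsv)
    invisible(c(fasta, map_tsv))
}

#' Draw true expression: population programs and molecule counts
#'
#' Baseline gene mean weights are gamma draws shared by all populations;
#' each population's specific genes (disjoint blocks of
#' \code{de_genes_per_population}) are up-shifted by \code{de_log2fc}.
#' Per-cell molecule counts are negative binomial (gamma-mixed Poisson,
#' the standard droplet overdispersion assumption) with mean
#' \code{molecules_per_cell} times the population's normalized gene
#' weight.
#'
#' @param config a [simConfig()]
#' @return a \linkS4class{SimTruth} (provenance empty until [emitReads()])
#' @export
drawExpression <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + 2L)
    G <- config$n_genes
    P <- config$n_populations
    genes <- sprintf("G%04d", seq_len(G))
    base <- rgamma(G, shape = config$gene_mean_shape,
                   scale = config$gene_mean_scale)
    base <- pmax(base, 1e-6)
    de <- config$de_genes_per_population
    if (de > 0L) {
        ## population-program genes must be detectably expressed for the
        ## configured fold change to mean anything: floor their baseline
        ## at the median of the mean distribution
        idxAll <- seq_len(P * de)
        base[idxAll] <- pmax(base[idxAll],
                             stats::qgamma(0.5, shape = config$gene_mean_shape,
                                           scale = config$gene_mean_scale))
    }
    nCells <- P * config$cells_per_population
    counts <- matrix(0L, nrow = G, ncol = nCells,
                     dimnames = list(genes, sprintf("C%04d", seq_len(nCells))))
    labels <- character(nCells)
    ci <- 0L
    for (p in seq_len(P)) {
        w <- base
        if (de > 0L) {
            idx <- ((p - 1L) * de + 1L):(p * de)
            w[idx] <- w[idx] * 2^config$de_log2fc
        }
        mu <- config$molecules_per_cell * w / sum(w)
        for (cc in seq_len(config$cells_per_population)) {
            ci <- ci + 1L
            counts[, ci] <- rnbinom(G, size = config$nb_dispersion, mu = mu)
            labels[ci] <- paste0("pop", p)
        }
    }
    new("SimTruth", counts = counts,
        labels = setNames(labels, colnames(counts)),
        provenance = data.frame(), config = unclass(config))
}

## deterministic cell barcode assignment from the two half whitelists
.cellBarcodes <- function(nCells, wl1, wl2) {
    n1 <- length(wl1@entries); n2 <- length(wl2@entries)
    if (nCells > n1 * n2) stop("whitelist exhausted: ", nCells,
                               " cells > ", n1 * n2, " barcode combinations")
    i <- seq_len(nCells) - 1L
    data.frame(cb1 = wl1@entries[i %/% n2 + 1L],
               cb2 = wl2@entries[i %% n2 + 1L])
}

#' Emit raw inDrops-style reads for a drawn truth
#'
#' Every true molecule receives a UMI (drawn without replacement within
#' its cell while the 4^umi_length space allows, so molecules and UMI
#' groups coincide at the default UMI length; shorter UMIs saturate and
#' collide, visibly biasing the estimator). \code{umi_duplication_rate}
#' adds geometric extra reads per molecule; \code{barcode_error_rate}
#' substitutes one position of the 16-nt barcode; ambient reads are drawn
#' from the pooled profile and assigned to random cells. Biological
#' sequences are error-free substrings of the source isoform. Writes the
#' four FASTQ streams plus truth tables.
#'
#' @param truth a \linkS4class{SimTruth} from [drawExpression()]
#' @param txome a SimTranscriptome from [makeTranscriptome()]
#' @param dir output directory
#' @param config a [simConfig()] (defaults to the truth's)
#' @return list: \code{truth} (with provenance filled), \code{files}
#'   (named paths r1/r2/i1/i2, whitelist1/2, sample_sheet, truth tables),
#'   \code{whitelist1}, \code{whitelist2}, \code{sample_sheet}
#' @export
emitReads <- function(truth, txome, dir, config = NULL) {
    if (is.null(config)) config <- structure(truth@config, class = "SimConfig")
    set.seed(config$seed + 3L)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wl1 <- makeBarcodeWhitelist(config$whitelist_size,
                                width = config$barcode_half_length,
                                seed = config$seed + 5L)
    wl2 <- makeBarcodeWhitelist(config$whitelist_size,
                                width = config$barcode_half_length,
                                seed = config$seed + 6L)
    cnt <- truth@counts
    nCells <- ncol(cnt)
    cb <- if (nCells) .cellBarcodes(nCells, wl1, wl2) else
        data.frame(cb1 = character(), cb2 = character())
    rl <- config$read_length
    isoLen <- setNames(txome$iso_info$length, txome$iso_info$isoform)
    isoSeq <- setNames(as.character(txome$sequences), names(txome$sequences))
    isoByGene <- split(txome$iso_info$isoform, txome$iso_info$gene)

    ## one row per true molecule
    nz <- which(cnt > 0, arr.ind = TRUE)
    mol <- data.table(gene = rownames(cnt)[nz[, 1L]],
                      cell = colnames(cnt)[nz[, 2L]],
                      n_copies = cnt[nz])
    mol <- mol[rep(seq_len(.N), n_copies)][, n_copies := NULL]
    nMol <- nrow(mol)
    if (nMol) {
        pick <- function(g) {
            iso <- isoByGene[[g]]
            if (length(iso) == 1L) iso else sample(iso, 1L)
        }
        mol[, isoform := vapply(gene, pick, character(1L))]
        mol[, start := floor(runif(.N) * (isoLen[isoform] - rl + 1))]
        ## per-cell UMIs: without replacement while the space allows
        uspace <- 4^config$umi_length
        mol[, umi := {
            idx <- if (.N <= uspace) sample(uspace, .N) - 1L
                   else floor(runif(.N) * uspace)
            .intToKmer(idx, config$umi_length)
        }, by = cell]
    } else {
        mol <- data.table(gene = character(), cell = character(),
                          isoform = character(), start = numeric(),
                          umi = character())
    }

    ## duplication: geometric extra reads per molecule (same UMI and start)
    copies <- if (nMol) 1L + rgeom(nMol, prob = 1 - config$umi_duplication_rate)
              else integer(0L)
    reads <- mol[rep(seq_len(nMol), copies)]
    reads[, is_ambient := FALSE]

    ## ambient background from the pooled profile
    if (config$ambient_fraction > 0 && nMol) {
        f <- config$ambient_fraction
        nAmb <- round(f / (1 - f) * nrow(reads))
        if (nAmb > 0L) {
            pool <- rowSums(cnt)
            g <- sample(rownames(cnt), nAmb, replace = TRUE,
                        prob = pool / sum(pool))
            iso <- vapply(g, function(gg) {
                is <- isoByGene[[gg]]
                if (length(is) == 1L) is else sample(is, 1L)
            }, character(1L))
            amb <- data.table(
                gene = g,
                cell = sample(colnames(cnt), nAmb, replace = TRUE),
                isoform = iso,
                start = floor(runif(nAmb) * (isoLen[iso] - rl + 1)),
                umi = .intToKmer(floor(runif(nAmb) * 4^config$umi_length),
                                 config$umi_length),
                is_ambient = TRUE)
            reads <- rbind(reads, amb)
        }
    }
    nReads <- nrow(reads)
    if (nReads) {
        reads[, read_id := sprintf("r%07d", seq_len(.N))]
        ci <- match(reads$cell, colnames(cnt))
        reads[, cb_true := paste0(cb$cb1[ci], cb$cb2[ci])]
        ## barcode sequencing errors: one substitution per hit read
        obs <- reads$cb_true
        hit <- which(runif(nReads) < config$barcode_error_rate)
        if (length(hit)) {
            pos <- sample.int(2L * config$barcode_half_length, length(hit),
                              replace = TRUE)
            old <- substr(obs[hit], pos, pos)
            alt <- vapply(old, function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                          b), 1L),
                          character(1L))
            substr(obs[hit], pos, pos) <- alt
        }
        reads[, cb_observed := obs]
    } else {
        reads <- data.table(gene = character(), cell = character(),
                            isoform = character(), start = numeric(),
                            umi = character(), is_ambient = logical(),
                            read_id = character(), cb_true = character(),
                            cb_observed = character())
    }

    files <- list(r1 = file.path(dir, "sim_R1.fastq.gz"),
                  r2 = file.path(dir, "sim_R2.fastq.gz"),
                  i1 = file.path(dir, "sim_I1.fastq.gz"),
                  i2 = file.path(dir, "sim_I2.fastq.gz"),
                  whitelist1 = file.path(dir, "whitelist1.txt"),
                  whitelist2 = file.path(dir, "whitelist2.txt"),
                  sample_sheet = file.path(dir, "sample_sheet.tsv"),
                  truth_counts = file.path(dir, "truth_counts.tsv"),
                  truth_labels = file.path(dir, "truth_labels.tsv"),
                  provenance = file.path(dir, "provenance.tsv"))
    if (nReads) {
        hw <- config$barcode_half_length
        bio <- substr(isoSeq[reads$isoform], reads$start + 1, reads$start + rl)
        r2 <- paste0(substr(reads$cb_observed, hw + 1L, 2L * hw), reads$umi)
        .writeFastq(reads$read_id, bio, strrep("I", rep(rl, nReads)), files$r1)
        .writeFastq(reads$read_id, r2, strrep("I", nchar(r2)), files$r2)
        .writeFastq(reads$read_id, rep(config$library_index, nReads),
                    strrep("I", rep(8L, nReads)), files$i1)
        .writeFastq(reads$read_id, substr(reads$cb_observed, 1L, hw),
                    strrep("I", rep(hw, nReads)), files$i2)
    } else {
        for (f in files[c("r1", "r2", "i1", "i2")]) file.create(f)
    }
    writeBarcodeWhitelist(wl1, files$whitelist1)
    writeBarcodeWhitelist(wl2, files$whitelist2)
    sheet <- setNames("S1", config$library_index)
    utils::write.table(data.frame(names(sheet), sheet), files$sample_sheet,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(as.data.frame(as.matrix(cnt)), files$truth_counts,
                       sep = "\t", quote = FALSE)
    utils::write.table(data.frame(cell = names(truth@labels),
                                  population = truth@labels),
                       files$truth_labels, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    data.table::fwrite(reads, files$provenance, sep = "\t")
    truth@provenance <- as.data.frame(reads)
    list(truth = truth, files = files, whitelist1 = wl1, whitelist2 = wl2,
         sample_sheet = sheet)
}

#' Emit SAM alignments with exact, known multi-mapping
#'
#' Bypasses any external aligner: every emitted read aligns to its source
#' isoform and, when its window lies entirely inside a shared block, to
#' every isoform carrying that block. By construction the target sets are
#' exactly what a perfect aligner reporting all best-stratum hits would
#' find.
#'
#' @param truth a \linkS4class{SimTruth} with provenance (after
#'   [emitReads()])
#' @param txome the SimTranscriptome the reads were drawn from
#' @param path output SAM file
#' @param reads optional annotated reads (from [extractReads()]): restricts
#'   the SAM to reads that survived extraction and stamps their corrected
#'   barcodes and library into the query names
#' @param library_id library field when \code{reads} is not given
#' @return invisibly, the path; attribute \code{n_alignments}
#' @export
emitSam <- function(truth, txome, path, reads = NULL, library_id = "S1") {
    prov <- data.table::as.data.table(truth@provenance)
    if (!nrow(prov) && is.null(reads))
        prov <- data.table(read_id = character(), cell = character(),
                           umi = character(), isoform = character(),
                           start = numeric(), cb_true = character())
    rl <- truth@config$read_length
    info <- txome$iso_info
    if (!is.null(reads)) {
        keep <- data.table(read_id = reads$read_id, lib = reads$library_id,
                           cb = reads$cell_barcode, umi_x = reads$umi)
        prov <- merge(prov, keep, by = "read_id", sort = FALSE)
        prov[, `:=`(qlib = lib, qcb = cb)]
    } else if (nrow(prov)) {
        prov[, `:=`(qlib = library_id, qcb = cb_true)]
    }
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", info$isoform, info$length))
    if (!nrow(prov)) {
        writeLines(hdr, path)
        return(invisible(structure(path, n_alignments = 0L)))
    }
    ## target set: all isoforms of the source's block group when the read
    ## window sits inside the shared block, else the source isoform alone
    bg <- setNames(info$block_group, info$isoform)
    bl <- setNames(info$block_len, info$isoform)
    groupMembers <- split(info$isoform, info$block_group)
    inBlock <- prov$start + rl <= bl[prov$isoform]
    tlist <- vector("list", nrow(prov))
    tlist[!inBlock] <- as.list(prov$isoform[!inBlock])
    if (any(inBlock))
        tlist[inBlock] <- groupMembers[bg[prov$isoform[inBlock]]]
    k <- lengths(tlist)
    qname <- paste(prov$qlib, prov$qcb, prov$umi, prov$read_id, sep = ":")
    lines <- data.table(
        qname = rep(qname, k),
        flag = unlist(lapply(k, function(kk) c(0L, rep(256L, kk - 1L))),
                      use.names = FALSE),
        rname = unlist(tlist, use.names = FALSE),
        pos = rep(prov$start + 1L, k))
    body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                    lines$qname, lines$flag, lines$rname, lines$pos, rl)
    writeLines(c(hdr, body), path)
    invisible(structure(path, n_alignments = nrow(lines)))
}
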