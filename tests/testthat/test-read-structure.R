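test_that("V3 quartets slice into 16-nt barcode, 6-nt UMI, 61-nt bio read", {
    set.seed(42)
    bases <- c("A", "C", "G", "T")
    mk <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
    q <- data.frame(read_id = "q1",
                    r1_seq = mk(61), r1_qual = strrep("I", 61),
                    r2_seq = mk(14), r2_qual = strrep("I", 14),
                    i1_seq = mk(8), i2_seq = mk(8))
    r <- parseQuartet(q)
    expect_true(r$accepted)
    expect_equal(nchar(r$cell_barcode), 16L)
    expect_equal(nchar(r$umi), 6L)
    expect_equal(nchar(r$bio_seq), 61L)
    expect_identical(r$bio_seq, q$r1_seq)
    expect_identical(r$cell_barcode, paste0(q$i2_seq, substr(q$r2_seq, 1, 8)))
    expect_identical(r$umi, substr(q$r2_seq, 9, 14))
    expect_identical(r$lib_index, q$i1_seq)

    short <- q; short$r2_seq <- substr(short$r2_seq, 1, 10)
    expect_identical(parseQuartet(short)$reason, "short_read")

    nq <- q; substr(nq$r2_seq, 12, 12) <- "N"
    expect_identical(parseQuartet(nq)$reason, "N_in_umi")
    ## N outside the UMI slice is tolerated
    nq2 <- q; substr(nq2$r1_seq, 5, 5) <- "N"
    expect_true(parseQuartet(nq2)$accepted)
})

test_that("parsing partitions every quartet into accepted or one reason", {
    set.seed(7)
    bases <- c("A", "C", "G", "T", "N")
    n <- 200L
    mk <- function(len, i) paste(sample(bases, len, replace = TRUE,
                                        prob = c(rep(0.23, 4), 0.08)),
                                 collapse = "")
    q <- data.frame(read_id = sprintf("q%03d", 1:n),
                    r1_seq = vapply(1:n, function(i) mk(61, i), ""),
                    r1_qual = strrep("I", 61),
                    r2_seq = vapply(1:n, function(i)
                        mk(sample(c(10L, 14L), 1, prob = c(.1, .9)), i), ""),
                    r2_qual = "x", i1_seq = vapply(1:n, function(i) mk(8, i), ""),
                    i2_seq = vapply(1:n, function(i) mk(8, i), ""))
    res <- parseQuartets(q)
    expect_equal(nrow(res$accepted) + nrow(res$rejected), n)
    expect_true(all(res$rejected$reason %in% c("short_read", "N_in_umi")))
    ## pure per-record function: permuting input permutes output identically
    perm <- sample(n)
    res2 <- parseQuartets(q[perm, ])
    expect_setequal(res2$accepted$read_id, res$accepted$read_id)
    expect_setequal(res2$rejected$read_id, res$rejected$read_id)
})

test_that("barcode correction returns unique in-range entries only", {
    wl <- barcodeWhitelist(c("AAAAAAAA", "AAAATAAA"))
    expect_identical(correctBarcode("AAAAAAAA", wl), "AAAAAAAA")
    expect_identical(correctBarcode("AAAATAAT", wl), "AAAATAAA")
    wl1 <- barcodeWhitelist("AAAAAAAA")
    expect_identical(correctBarcode("AAAAAAAT", wl1), "AAAAAAAA")
    ## N counts as a mismatch
    expect_identical(correctBarcode("AAAAAAAN", wl1), "AAAAAAAA")
    ## two entries at the same minimal distance: ambiguous
    wl2 <- barcodeWhitelist(c("AAAAAAAA", "AAAAAATT"))
    amb <- correctBarcode("AAAAAAAT", wl2)
    expect_true(is.na(amb))
    expect_identical(attr(amb, "reason"), "ambiguous")
    ## nothing within range: no_match
    nm <- correctBarcode("TTTTTTTT", wl1)
    expect_true(is.na(nm))
    expect_identical(attr(nm, "reason"), "no_match")
})

test_that("corrections never exceed max_hamming and match an enumeration oracle", {
    set.seed(11)
    wl <- makeBarcodeWhitelist(24, width = 8, seed = 3)
    entries <- whitelistEntries(wl)
    bases <- c("A", "C", "G", "T", "N")
    obs <- vapply(1:300, function(i)
        paste(sample(bases, 8, replace = TRUE), collapse = ""), "")
    ## seed in some single-error corruptions of real entries
    obs[1:100] <- vapply(1:100, function(i) {
        b <- sample(entries, 1); p <- sample(8, 1)
        substr(b, p, p) <- sample(setdiff(bases, substr(b, p, p)), 1)
        b
    }, "")
    res <- correctBarcodes(obs, wl, max_hamming = 1)
    for (i in seq_along(obs)) {
        d <- vapply(entries, function(e) strHamming(obs[i], e), 0)
        if (!is.na(res$barcode[i])) {
            expect_lte(strHamming(obs[i], res$barcode[i]), 1)
            expect_equal(sum(d <= 1), 1L)   # oracle: unique in-range entry
            expect_identical(res$barcode[i], entries[which.min(d)])
        } else if (res$reason[i] == "no_match") {
            expect_equal(sum(d <= 1), 0L)
        } else {
            expect_gte(sum(d == min(d)), 2L)
        }
    }
})

test_that("annotated FASTQ encoding round-trips exactly", {
    reads <- randomAnnotatedReads(1000, seed = 5)
    f <- tempfile(fileext = ".fastq.gz")
    encodeAnnotatedFastq(reads, f)
    back <- decodeAnnotatedFastq(f)
    expect_identical(back, reads)
    ## per-record library identity is preserved across interleaving
    expect_identical(back$library_id, reads$library_id)
    expect_gt(length(unique(reads$library_id)), 1L)

    ## empty stream -> empty FASTQ
    f0 <- tempfile(fileext = ".fastq")
    encodeAnnotatedFastq(reads[0, ], f0)
    expect_equal(nrow(decodeAnnotatedFastq(f0)), 0L)

    ## delimiter inside a field is refused
    bad <- reads[1, ]; bad$read_id <- "a:b"
    expect_error(encodeAnnotatedFastq(bad, tempfile()), "malformed_field")

    ## plain non-annotated header is refused with the record index
    fbad <- tempfile(fileext = ".fastq")
    writeLines(c("@SRR001.1", "ACGT", "+", "IIII"), fbad)
    expect_error(decodeAnnotatedFastq(fbad), "malformed_header at record 1")
})

test_that("extraction tallies account for every input quartet", {
    cfg <- simConfig(seed = 21, n_genes = 20, n_populations = 1,
                     cells_per_population = 15, molecules_per_cell = 60,
                     de_genes_per_population = 0, whitelist_size = 8,
                     barcode_error_rate = 0.2, ambient_fraction = 0)
    tx <- makeTranscriptome(cfg)
    sim <- emitReads(drawExpression(cfg), tx, tempfile("sim"), cfg)
    out <- tempfile(fileext = ".fastq.gz")
    ex <- extractReads(sim$files$r1, sim$files$r2, sim$files$i1, sim$files$i2,
                       whitelist1 = sim$whitelist1,
                       whitelist2 = sim$whitelist2,
                       sample_sheet = sim$sample_sheet, output = out)
    t <- ex$tallies
    expect_equal(t[["accepted"]] + t[["short_read"]] + t[["N_in_umi"]] +
                 t[["barcode_no_match"]] + t[["barcode_ambiguous"]] +
                 t[["library_unknown"]], t[["input"]])
    ## whitelist halves are >= 3 apart, so every single-substitution
    ## barcode error is corrected back to the emitting cell
    expect_equal(t[["accepted"]], t[["input"]])
    prov <- readProvenance(sim$truth)
    m <- match(ex$reads$read_id, prov$read_id)
    expect_identical(ex$reads$cell_barcode, prov$cb_true[m])
    ## the annotated FASTQ round-trips the extraction output
    expect_identical(decodeAnnotatedFastq(out), ex$reads)
})
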