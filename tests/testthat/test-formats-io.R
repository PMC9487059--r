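# File-format readers and writers: Bismark CX cytosine report, CGmap,
# genePred/BED12 annotation, BED, bedGraph, chrom.sizes.

test_that("cytosine report lines map to calls field by field", {
    f <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("chr1\t105\t+\t3\t1\tCG\tCGG",
                 "chr1\t200\t-\t0\t0\tCHH\tCTT"), f)
    cs <- readCytosineReport(f)
    gr <- calls(cs)
    expect_length(gr, 2L)
    # 1-based file position 105 stays 105 in the 1-based container
    expect_equal(start(gr), c(105L, 200L))
    expect_equal(as.character(strand(gr)), c("+", "-"))
    expect_equal(gr$context, c("CpG", "CHH"))
    expect_equal(gr$n_meth, c(3L, 0L))
    expect_equal(gr$n_unmeth, c(1L, 0L))
    expect_equal(gr$trinucleotide, c("CGG", "CTT"))
    # zero-coverage row retained, and written back verbatim
    out <- withr::local_tempfile(fileext = ".txt")
    writeCytosineReport(cs, out)
    expect_identical(readLines(out),
                     c("chr1\t105\t+\t3\t1\tCG\tCGG",
                       "chr1\t200\t-\t0\t0\tCHH\tCTT"))
})

test_that("cytosine report round-trips, sorts unsorted input, handles gzip", {
    set.seed(42)
    n <- 200L
    cs <- makeCalls(sample(c("chr1", "chr2"), n, TRUE),
                    sample.int(100000L, n), sample(c("+", "-"), n, TRUE),
                    sample(c("CpG", "CHG", "CHH"), n, TRUE),
                    rpois(n, 5), rpois(n, 5),
                    tri = rep("NNN", n))
    f <- withr::local_tempfile(fileext = ".txt")
    writeCytosineReport(cs, f)
    back <- readCytosineReport(f)
    expect_identical(calls(back), calls(cs))
    # write(read(f)) is byte-identical
    f2 <- withr::local_tempfile(fileext = ".txt")
    writeCytosineReport(back, f2)
    expect_identical(readLines(f2), readLines(f))
    # unsorted input is sorted silently
    f3 <- withr::local_tempfile(fileext = ".txt")
    writeLines(rev(readLines(f)), f3)
    expect_identical(calls(readCytosineReport(f3)), calls(cs))
    # gzip detected by magic bytes even without .gz extension
    fgz <- withr::local_tempfile(fileext = ".dat")
    con <- gzfile(fgz, "wb"); writeLines(readLines(f), con); close(con)
    expect_identical(calls(readCytosineReport(fgz)), calls(cs))
})

test_that("malformed cytosine reports fail with the offending line number", {
    f <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("chr1\t105\t+\t3\t1\tCG\tCGG",
                 "chr1\t110\t+\t3\t1"), f)
    expect_error(readCytosineReport(f), "line 2")
    writeLines(c("chr1\t105\t*\t3\t1\tCG\tCGG"), f)
    expect_error(readCytosineReport(f), "strand")
    writeLines(c("chr1\t105\t+\tx\t1\tCG\tCGG"), f)
    expect_error(readCytosineReport(f), "line 1")
    writeLines(c("chr1\t105\t+\t3\t1\tCGX\tCGG"), f)
    expect_error(readCytosineReport(f), "context")
})

test_that("CGmap conversion maps strand, counts and context", {
    f <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("chr1\tG\t3541\tCHH\tCC\t0.0\t0\t2",
                 "chr1\tC\t100\tCG\tCG\t1.0\t5\t5"), f)
    cs <- convertCgmapToCalls(f)
    gr <- calls(cs)
    expect_equal(start(gr), c(100L, 3541L))
    expect_equal(as.character(strand(gr)), c("+", "-"))
    expect_equal(gr$context, c("CpG", "CHH"))
    expect_equal(gr$n_meth, c(5L, 0L))
    expect_equal(gr$n_unmeth, c(0L, 2L))
    # conversion then report round-trip is lossless on shared fields
    out <- withr::local_tempfile(fileext = ".txt")
    writeCytosineReport(cs, out)
    back <- calls(readCytosineReport(out))
    expect_identical(granges(back), granges(gr))
    expect_identical(back$n_meth, gr$n_meth)
    expect_identical(back$context, gr$context)
})

test_that("CGmap conversion conserves total counts and rejects bad rows", {
    set.seed(7)
    n <- 50L
    tot <- rpois(n, 10)
    nm <- rbinom(n, tot, 0.5)
    lines <- sprintf("chr1\t%s\t%d\tCG\tCG\t%.2f\t%d\t%d",
                     sample(c("C", "G"), n, TRUE), seq_len(n) * 10L,
                     ifelse(tot > 0, nm / pmax(tot, 1), 0), nm, tot)
    f <- withr::local_tempfile(fileext = ".txt")
    writeLines(lines, f)
    cs <- convertCgmapToCalls(f)
    expect_equal(sum(calls(cs)$n_meth) + sum(calls(cs)$n_unmeth),
                 sum(tot))
    writeLines("chr1\tC\t10\tCG\tCG\t1.0\t5\t3", f)
    expect_error(convertCgmapToCalls(f), "total count")
    writeLines("chr1\tA\t10\tCG\tCG\t1.0\t1\t3", f)
    expect_error(convertCgmapToCalls(f), "nucleotide")
})

test_that("genePred and BED12 readers agree on equivalent records", {
    gp <- withr::local_tempfile(fileext = ".genePred")
    # 0-based: tx [2000,5000), exons [2000,2200) and [4700,5000)
    writeLines(paste("tx1", "chr1", "+", 2000, 5000, 2000, 5000, 2,
                     "2000,4700,", "2200,5000,", sep = "\t"), gp)
    b12 <- withr::local_tempfile(fileext = ".bed")
    writeLines(paste("chr1", 2000, 5000, "tx1", 0, "+", 2000, 5000,
                     "0", 2, "200,300,", "0,2700,", sep = "\t"), b12)
    g1 <- readGeneAnnotation(gp, "genePred")
    g2 <- readGeneAnnotation(b12, "BED12")
    expect_equal(start(g1), 2001L)
    expect_equal(end(g1), 5000L)
    expect_identical(start(g1$exons[[1L]]), start(g2$exons[[1L]]))
    expect_identical(end(g1$exons[[1L]]), end(g2$exons[[1L]]))
    expect_equal(start(g1$exons[[1L]]), c(2001L, 4701L))
    expect_equal(end(g1$exons[[1L]]), c(2200L, 5000L))
    expect_identical(granges(g1), granges(g2))
})

test_that("single-exon transcripts yield no introns downstream", {
    gp <- withr::local_tempfile(fileext = ".genePred")
    writeLines(paste("tx1", "chr1", "+", 2000, 5000, 2000, 5000, 1,
                     "2000,", "5000,", sep = "\t"), gp)
    genes <- readGeneAnnotation(gp, "genePred")
    ctx <- deriveGenomicContexts(genes, c(chr1 = 10000L))
    expect_length(ctx@introns, 0L)
    expect_equal(start(ctx@mergedExons), 2001L)
    expect_equal(end(ctx@mergedExons), 5000L)
})

test_that("exons outside the transcript span are rejected", {
    gp <- withr::local_tempfile(fileext = ".genePred")
    writeLines(paste("tx1", "chr1", "+", 2000, 5000, 2000, 5000, 1,
                     "1500,", "5000,", sep = "\t"), gp)
    expect_error(readGeneAnnotation(gp, "genePred"),
                 "exon outside transcript")
})

test_that("BED output is 0-based half-open and re-parseable", {
    gr <- GRanges("chr1", IRanges(1001L, 2000L), strand = "+",
                  name = "UMR", score = 980L)
    f <- withr::local_tempfile(fileext = ".bed")
    writeBed(gr, f)
    expect_identical(readLines(f), "chr1\t1000\t2000\tUMR\t980\t+")
    back <- rtracklayer::import(f, format = "BED")
    expect_equal(start(back), 1001L)
    expect_equal(end(back), 2000L)
    expect_equal(back$name, "UMR")
    # empty collection -> empty file
    writeBed(GRanges(), f)
    expect_identical(readLines(f), character(0))
    expect_error(writeBed(GRanges("chr1", IRanges(5, 4)), f))
    bad <- GRanges("chr1", IRanges(1, 10), score = 2000L)
    expect_error(writeBed(bad, f), "score")
})

test_that("bedGraph omits missing bins and rejects overlaps", {
    gr <- GRanges("chr1", IRanges(c(1L, 100001L), c(100000L, 200000L)))
    f <- withr::local_tempfile(fileext = ".bedGraph")
    writeBedGraph(gr, c(0.73, NA), f)
    expect_identical(readLines(f), "chr1\t0\t100000\t0.73")
    ov <- GRanges("chr1", IRanges(c(1L, 50L), c(100L, 150L)))
    expect_error(writeBedGraph(ov, c(1, 2), f), "overlap")
    writeBedGraph(gr, c(0.5, 0.5), f)
    vals <- vapply(strsplit(readLines(f), "\t"), `[`, "", 4L)
    expect_true(all(vals == "0.5"))
})

test_that("chrom.sizes round-trips", {
    sizes <- c(chr1 = 250000L, chr2 = 100000L)
    f <- withr::local_tempfile(fileext = ".sizes")
    writeChromSizes(sizes, f)
    expect_identical(readChromSizes(f), sizes)
})
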