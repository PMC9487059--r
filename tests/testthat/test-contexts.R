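# Genomic-context derivation, per-class methylation and TSS
# metaprofiles.

test_that("promoters are strand-aware 1-kb upstream intervals", {
    gp <- GRanges("chr1", IRanges(2001L, 5000L), strand = "+",
                  gene_id = "gp")
    gp$exons <- IRangesList(IRanges(2001L, 5000L))
    gm <- GRanges("chr1", IRanges(2001L, 5000L), strand = "-",
                  gene_id = "gm")
    gm$exons <- IRangesList(IRanges(2001L, 5000L))
    gc <- GRanges("chr1", IRanges(301L, 900L), strand = "+",
                  gene_id = "gc")
    gc$exons <- IRangesList(IRanges(301L, 900L))
    ctx <- deriveGenomicContexts(suppressWarnings(c(gp, gm, gc)),
                                 c(chr1 = 10000L))
    pr <- ctx@promoters
    # '+' gene [2001,5000]: promoter [1001,2000] (0-based [1000,2000))
    expect_equal(start(pr[pr$gene_id == "gp"]), 1001L)
    expect_equal(end(pr[pr$gene_id == "gp"]), 2000L)
    # '-' gene: mirrored downstream in coordinates, [5001,6000]
    expect_equal(start(pr[pr$gene_id == "gm"]), 5001L)
    expect_equal(end(pr[pr$gene_id == "gm"]), 6000L)
    # clamped at the chromosome start: [1,300]
    expect_equal(start(pr[pr$gene_id == "gc"]), 1L)
    expect_equal(end(pr[pr$gene_id == "gc"]), 300L)
    expect_error(deriveGenomicContexts(gp, c(chrX = 1000L)),
                 "absent from chromSizes")
})

test_that("context partition invariants hold on random annotations", {
    set.seed(101)
    for (rep in 1:100) {
        ann <- randomAnnotation(nGenes = sample(2:5, 1L))
        ctx <- deriveGenomicContexts(ann$genes, ann$chromSizes)
        for (g in ctx@geneBodies$gene_id) {
            gb <- ctx@geneBodies[ctx@geneBodies$gene_id == g]
            ex <- ctx@mergedExons[ctx@mergedExons$gene_id == g]
            intr <- ctx@introns[ctx@introns$gene_id == g]
            both <- reduce(c(granges(ex), granges(intr)))
            expect_identical(ranges(both), ranges(gb))
            expect_length(findOverlaps(ex, intr), 0L)
        }
        # intergenic disjoint from transcripts, and full coverage
        expect_length(findOverlaps(ctx@intergenic, ann$genes,
                                   ignore.strand = TRUE), 0L)
        cover <- reduce(c(granges(ctx@intergenic),
                          granges(ann$genes)), ignore.strand = TRUE)
        expect_equal(sum(width(cover)), sum(ann$chromSizes))
    }
})

test_that("per-class means respect nesting and intergenic exclusivity", {
    g <- GRanges("chr1", IRanges(2001L, 5000L), strand = "+",
                 gene_id = "g1")
    g$exons <- IRangesList(IRanges(c(2001L, 4001L), c(2500L, 5000L)))
    ctx <- deriveGenomicContexts(g, c(chr1 = 10000L))
    # sites: promoter, exon, intron, intergenic
    tr <- makeTrack("chr1", c(1500L, 2200L, 3000L, 8000L), "+", "CpG",
                    c(1L, 1L, 1L, 1L), c(1L, 1L, 1L, 1L))
    sm <- contextLevelSummary(tr, ctx, "CpG")
    expect_equal(sm$mean_level, rep(0.5, 5L))  # constant track
    expect_equal(sm$n_sites[sm$region_class == "promoter"], 1L)
    # the exon site also counts in the gene-body class
    expect_equal(sm$n_sites[sm$region_class == "gene"], 2L)
    expect_equal(sm$n_sites[sm$region_class == "exon"], 1L)
    expect_equal(sm$n_sites[sm$region_class == "intron"], 1L)
    # intergenic = genome minus transcripts, so the promoter site is
    # intergenic too; the gene-body sites are not
    expect_equal(sm$n_sites[sm$region_class == "intergenic"], 2L)
    expect_equal(sum(sm$n_sites[sm$region_class != "intergenic"]), 5L)
    # gene-linked sites never count as intergenic
    body_sites <- GRanges("chr1", IRanges(c(2200L, 3000L), width = 1L))
    expect_false(any(overlapsAny(body_sites, ctx@intergenic)))
})

test_that("TSS metaprofile has 26 windows and reproduces constants", {
    g <- GRanges("chr1", IRanges(5001L, 8000L), strand = "+",
                 gene_id = "g1")
    g$exons <- IRangesList(IRanges(5001L, 8000L))
    ctx <- deriveGenomicContexts(g, c(chr1 = 20000L))
    pos <- seq(3001L, 7000L, by = 10L)
    tr <- makeTrack("chr1", pos, "+", "CpG", 7L, 3L)
    mp <- tssMetaprofile(tr, ctx)
    expect_equal(nrow(mp@windows), 26L)
    expect_equal((2L * 1500L - 500L) %/% 100L + 1L, 26L)
    expect_true(all(abs(mp@aggregate - 0.7) < 1e-12))
})

test_that("minus-strand profiles equal the mirrored plus computation", {
    L <- 40000L
    tss_p <- 10000L
    tss_m <- 30000L
    gp <- GRanges("chr1", IRanges(tss_p, tss_p + 2999L), strand = "+",
                  gene_id = "gp")
    gp$exons <- IRangesList(IRanges(tss_p, tss_p + 2999L))
    gm <- GRanges("chr1", IRanges(tss_m - 2999L, tss_m), strand = "-",
                  gene_id = "gm")
    gm$exons <- IRangesList(IRanges(tss_m - 2999L, tss_m))
    ctx <- deriveGenomicContexts(suppressWarnings(c(gp, gm)),
                                 c(chr1 = L))
    # site pattern around the '+' TSS, mirrored around the '-' TSS
    off <- seq(-1600L, 1600L, by = 7L)
    lev <- round(seq(0, 1, length.out = length(off)) * 20) / 20
    pos_p <- tss_p + off
    pos_m <- tss_m - off
    nm <- as.integer(lev * 20L)
    tr <- buildTrack(mergeReplicates(list(
        makeCalls("chr1", pos_p, "+", "CpG", nm, 20L - nm),
        makeCalls("chr1", pos_m, "+", "CpG", nm, 20L - nm))))
    mp <- tssMetaprofile(tr, ctx)
    expect_equal(mp@geneLevels["gp", ], mp@geneLevels["gm", ],
                 tolerance = 1e-12)
})

test_that("a linear methylation gradient gives window-midpoint means", {
    # covered CpG sites at every position, level = pos / 40000
    L <- 40000L
    tss <- 20000L
    g <- GRanges("chr1", IRanges(tss, tss + 999L), strand = "+",
                 gene_id = "g1")
    g$exons <- IRangesList(IRanges(tss, tss + 999L))
    ctx <- deriveGenomicContexts(g, c(chr1 = L))
    pos <- seq(tss - 1600L, tss + 1600L)
    denom <- 40000L
    nm <- pos  # level = pos/denom with coverage denom
    tr <- makeTrack("chr1", pos, "+", "CpG", nm, denom - nm)
    mp <- tssMetaprofile(tr, ctx)
    # midpoint of window i in genomic coordinates (1-based positions)
    mid <- tss + mp@windows$rel_start + (500 - 1) / 2
    expect_equal(unname(mp@geneLevels["g1", ]), mid / denom,
                 tolerance = 1e-12)
})

test_that("windows past the chromosome edge are missing for that gene", {
    g <- GRanges("chr1", IRanges(1001L, 3000L), strand = "+",
                 gene_id = "g1")
    g$exons <- IRangesList(IRanges(1001L, 3000L))
    ctx <- deriveGenomicContexts(g, c(chr1 = 10000L))
    tr <- makeTrack("chr1", seq(1L, 5000L, 10L), "+", "CpG", 1L, 1L)
    mp <- tssMetaprofile(tr, ctx)
    # TSS at 1001: windows starting before position 1 are missing
    expect_true(all(is.na(mp@geneLevels["g1", 1:5])))
    expect_true(all(!is.na(mp@geneLevels["g1", 7:26])))
})
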