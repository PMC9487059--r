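# Per-site exact testing, FDR adjustment, DMC filtering, DMR clustering
# and gene association.

# Independent oracle: full enumeration of the hypergeometric null for a
# 2x2 table with fixed margins, summing tables no more likely than the
# observed one (probabilities via exact binomial coefficients).
enumOracle <- function(a, b, c, d) {
    m <- a + b; n2 <- c + d; k <- a + c
    xs <- max(0, k - n2):min(k, m)
    pr <- choose(m, xs) * choose(n2, k - xs) / choose(m + n2, k)
    pobs <- choose(m, a) * choose(n2, k - a) / choose(m + n2, k)
    sum(pr[pr <= pobs * (1 + 1e-7)])
}

twoTracks <- function(pos, cm, cu, km, ku) {
    list(case = makeTrack("chr1", pos, "+", "CpG", cm, cu),
         control = makeTrack("chr1", pos, "+", "CpG", km, ku))
}

test_that("exact test matches enumeration and fisher.test", {
    tt <- twoTracks(100L, 10L, 0L, 0L, 10L)
    res <- testDmc(tt$case, tt$control)
    expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
    expect_equal(res$p_value, enumOracle(10, 0, 0, 10),
                 tolerance = 1e-12)
    expect_equal(res$diff_pp, 100)
    # symmetric table: p = 1, no difference
    tt <- twoTracks(100L, 5L, 5L, 5L, 5L)
    res <- testDmc(tt$case, tt$control)
    expect_equal(res$p_value, 1.0)
    expect_equal(res$diff_pp, 0)
    # random tables agree with both the enumeration oracle and
    # stats::fisher.test (the standard implementation, used here only
    # as a cross-check)
    set.seed(88)
    for (i in 1:50) {
        tab <- matrix(rpois(4, 8) + c(5L, 0L, 0L, 5L), 2L)
        tt <- twoTracks(100L, tab[1, 1], tab[1, 2], tab[2, 1],
                        tab[2, 2])
        p <- testDmc(tt$case, tt$control)$p_value
        expect_equal(p, enumOracle(tab[1, 1], tab[1, 2], tab[2, 1],
                                   tab[2, 2]), tolerance = 1e-12)
        expect_equal(p, stats::fisher.test(tab)$p.value,
                     tolerance = 1e-9)
    }
})

test_that("sites below the coverage floor are not tested", {
    case <- makeTrack("chr1", c(100L, 200L), "+", "CpG",
                      c(3L, 10L), c(1L, 2L))     # coverage 4 and 12
    control <- makeTrack("chr1", c(100L, 200L), "+", "CpG",
                         c(5L, 1L), c(5L, 11L))
    res <- testDmc(case, control)  # minCoverage 5
    expect_equal(start(res), 200L)
    # no qualifying shared site -> empty with a warning
    lone <- makeTrack("chr1", 900L, "+", "CpG", 10L, 10L)
    expect_warning(res0 <- testDmc(case, lone), "no shared sites")
    expect_length(res0, 0L)
})

test_that("BH adjustment matches the step-up formula", {
    expect_equal(adjustFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(adjustFdr(0.2), 0.2)
    expect_equal(adjustFdr(rep(1, 5)), rep(1, 5))
    expect_error(adjustFdr(c(0.5, 1.2)), "\\[0, 1\\]")
    # order invariance and monotonicity in p-rank
    set.seed(9)
    p <- runif(100)
    perm <- sample.int(100)
    expect_equal(adjustFdr(p)[perm], adjustFdr(p[perm]))
    q <- adjustFdr(p)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("DMC filtering applies both thresholds and sets direction", {
    gr <- GRanges("chr1", IRanges(c(10L, 20L, 30L), width = 1L),
                  strand = "+", context = "CpG",
                  case_meth = 1L, case_unmeth = 1L, control_meth = 1L,
                  control_unmeth = 1L,
                  diff_pp = c(30, -30, 30),
                  p_value = c(0.01, 0.01, 0.01),
                  q_value = c(0.4, 0.4, 0.6))
    dm <- filterDmcs(gr, analysisParams())   # qCutoff 0.5, minDiff 25
    got <- dmcs(dm)
    expect_equal(start(got), c(10L, 20L))
    expect_equal(got$direction, c("hyper", "hypo"))
    # |diff| below the floor is dropped even when significant
    gr$diff_pp <- c(10, -30, 30)
    expect_equal(start(dmcs(filterDmcs(gr, analysisParams()))),
                 c(20L, 30L)[1L])
})

makeDmcSet <- function(chrom, pos, direction, diff = 40) {
    gr <- GRanges(chrom, IRanges(pos, width = 1L), strand = "+",
                  context = "CpG", case_meth = 10L, case_unmeth = 10L,
                  control_meth = 10L, control_unmeth = 10L,
                  diff_pp = ifelse(direction == "hypo", -diff, diff),
                  p_value = 1e-6, q_value = 1e-4,
                  direction = direction)
    new("DmcSet", sites = sort(gr), params = analysisParams())
}

test_that("gap clustering follows the inclusive 500-bp rule", {
    dm <- makeDmcSet("chr1", c(100L, 550L, 1200L), rep("hypo", 3L))
    got <- dmrs(clusterDmrs(dm))
    expect_length(got, 1L)
    expect_equal(start(got), 100L)
    expect_equal(end(got), 550L)
    expect_equal(got$n_dmcs, 2L)
    expect_equal(as.integer(got$dmc_pos[[1L]]), c(100L, 550L))
    # gap of exactly 500 clusters
    dm <- makeDmcSet("chr1", c(100L, 600L), rep("hypo", 2L))
    expect_length(dmrs(clusterDmrs(dm)), 1L)
    # opposite directions never share a region
    dm <- makeDmcSet("chr1", c(100L, 300L), c("hyper", "hypo"))
    expect_length(dmrs(clusterDmrs(dm)), 0L)
})

test_that("gap clustering equals the brute-force chaining oracle", {
    set.seed(33)
    for (rep in 1:100) {
        n <- sample(2:80, 1L)
        pos <- sort(sample.int(100000L, n))
        dirn <- sample(c("hypo", "hyper"), n, TRUE)
        dm <- makeDmcSet("chr1", pos, dirn)
        got <- dmrs(clusterDmrs(dm))
        want <- chainOracle("chr1", pos, dirn)
        expect_equal(length(got), nrow(want))
        if (nrow(want)) {
            o <- order(start(got), got$direction)
            expect_equal(start(got)[o], want$start)
            expect_equal(end(got)[o], want$end)
            expect_equal(got$n_dmcs[o], want$n)
            expect_equal(got$direction[o], want$direction)
        }
    }
})

test_that("the smoothing-style rule enforces all four thresholds", {
    params <- analysisParams()
    cpg_pos <- seq(1000L, 4000L, by = 25L)   # 121 CpGs available
    track <- makeCpgTrack(cpg_pos, rep(0.8, length(cpg_pos)))
    mk <- function(pos) {
        dm <- makeDmcSet("chr1", pos, rep("hypo", length(pos)),
                         diff = 12)
        clusterDmrs(dm, analysisParams(dmrMaxGap = 2000L))
    }
    # 3 DMCs, mean |diff| 12, >=70 CpGs in span, >=1 kb: retained
    good <- filterDmrsSmoothLike(mk(c(1000L, 2000L, 3000L)), track,
                                 params)
    expect_length(dmrs(good), 1L)
    expect_equal(dmrs(good)$n_cpgs_in_span, 81L)
    # span of 900 bp fails the length test (and the CpG count)
    short <- filterDmrsSmoothLike(mk(c(1000L, 1500L, 1900L)), track,
                                  params)
    expect_length(dmrs(short), 0L)
    # only 2 DMCs fails the count test even when long enough
    few <- filterDmrsSmoothLike(mk(c(1000L, 3000L)), track, params)
    expect_length(dmrs(few), 0L)
})

test_that("DMC summaries report distances and orientation", {
    g <- GRanges("chr1", IRanges(2001L, 5000L), strand = "+",
                 gene_id = "g1")
    g$exons <- IRangesList(IRanges(2001L, 5000L))
    ctx <- deriveGenomicContexts(g, c(chr1 = 10000L))
    dm <- makeDmcSet("chr1", c(100L, 550L, 1501L),
                     c("hypo", "hypo", "hyper"))
    sm <- summarizeDmcs(dm, ctx)
    expect_equal(sm$counts$n_total, c(2L, 1L))
    # the site at 1501 sits inside the promoter [1001, 2000]
    expect_equal(sm$counts$n_in_promoter[sm$counts$direction ==
                                         "hyper"], 1L)
    expect_equal(sort(sm$adjacent_distances$distance), c(450L, 951L))
    # '+' TSS at 2001: DMC at 1501 is 500 bp upstream -> -500
    tssd <- sm$tss_distances
    expect_equal(tssd$distance[tssd$pos == 1501L], -500L)
})

test_that("equidistant TSSs break ties to the lower coordinate", {
    g1 <- GRanges("chr1", IRanges(1001L, 2000L), strand = "+",
                  gene_id = "a")
    g1$exons <- IRangesList(IRanges(1001L, 2000L))
    g2 <- GRanges("chr1", IRanges(2001L, 3000L), strand = "+",
                  gene_id = "b")
    g2$exons <- IRangesList(IRanges(2001L, 3000L))
    ctx <- deriveGenomicContexts(suppressWarnings(c(g1, g2)),
                                 c(chr1 = 10000L))
    dm <- makeDmcSet("chr1", 1501L, "hypo")  # 500 bp from both TSSs
    sm <- summarizeDmcs(dm, ctx)
    expect_equal(sm$tss_distances$gene_id, "a")
})

test_that("gene association is promoter-based and unique", {
    g <- GRanges("chr1", IRanges(2001L, 5000L), strand = "+",
                 gene_id = "g1")
    g$exons <- IRangesList(IRanges(2001L, 5000L))
    ctx <- deriveGenomicContexts(g, c(chr1 = 10000L))
    # two DMCs in the promoter, one in the gene body
    dm <- makeDmcSet("chr1", c(1200L, 1500L, 3000L), rep("hypo", 3L))
    expect_identical(associateGenes(dm, ctx), "g1")
    # gene-body-only DMCs do not associate
    dm2 <- makeDmcSet("chr1", 3000L, "hypo")
    expect_identical(associateGenes(dm2, ctx), character(0))
    # DMRs associate by >= 1 bp promoter overlap
    dmr <- clusterDmrs(makeDmcSet("chr1", c(1900L, 2300L),
                                  rep("hypo", 2L)))
    expect_identical(associateGenes(dmr, ctx), "g1")
})
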