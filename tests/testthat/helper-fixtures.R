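# Shared fixture builders. Everything is generated in code; coordinates
# below are 1-based closed (the GRanges convention).

library(GenomicRanges)
library(IRanges)

# Build a CytosineCalls object from parallel vectors.
makeCalls <- function(chrom, pos, strand, context, n_meth, n_unmeth,
                      tri = NULL, label = "test") {
    gr <- GRanges(chrom, IRanges(pos, width = 1L), strand = strand,
                  context = context, n_meth = as.integer(n_meth),
                  n_unmeth = as.integer(n_unmeth))
    if (!is.null(tri)) gr$trinucleotide <- tri
    CytosineCalls(gr, label)
}

makeTrack <- function(...) buildTrack(makeCalls(...))

# A track of destranded CpG units at given positions/levels with fixed
# coverage (level must be representable as meth/coverage).
makeCpgTrack <- function(pos, level, coverage = 50L, chrom = "chr1",
                         label = "cpg") {
    nm <- as.integer(round(level * coverage))
    makeTrack(chrom, pos, "+", "CpG", nm, coverage - nm, label = label)
}

# Random small transcript annotation (multiple transcripts per gene
# possible) plus chrom sizes; used by context-derivation property tests.
randomAnnotation <- function(nGenes = 4L, nChroms = 2L,
                             chromLen = 50000L) {
    sizes <- stats::setNames(rep(chromLen, nChroms),
                             paste0("c", seq_len(nChroms)))
    recs <- list()
    occupied <- GRanges()
    gi <- 0L
    while (gi < nGenes) {
        chr <- sample(names(sizes), 1L)
        glen <- sample(500:3000, 1L)
        gstart <- sample(seq_len(chromLen - glen - 1L), 1L)
        cand <- GRanges(chr, IRanges(gstart, gstart + glen - 1L))
        if (length(occupied) &&
            any(suppressWarnings(overlapsAny(cand + 100L, occupied))))
            next
        occupied <- suppressWarnings(c(occupied, cand))
        gi <- gi + 1L
        std <- sample(c("+", "-"), 1L)
        ntx <- sample(1:2, 1L)
        for (t in seq_len(ntx)) {
            nex <- sample(1:3, 1L)
            cuts <- sort(sample(seq(gstart + 10L,
                                    gstart + glen - 11L, by = 4L),
                                2L * nex - 2L))
            bounds <- c(gstart, cuts, gstart + glen - 1L)
            ex <- IRanges(bounds[seq(1L, 2L * nex, 2L)],
                          bounds[seq(2L, 2L * nex, 2L)])
            g <- GRanges(chr, IRanges(gstart, gstart + glen - 1L),
                         strand = std,
                         gene_id = sprintf("g%02d", gi))
            g$exons <- IRangesList(ex)
            recs[[length(recs) + 1L]] <- g
        }
    }
    genes <- suppressWarnings(do.call(c, recs))
    list(genes = genes, chromSizes = sizes)
}

# Independent O(n^2) chaining oracle for DMR gap-clustering: maximal
# same-direction chains with adjacent gaps <= maxGap and >= minDmcs
# members, per chromosome.
chainOracle <- function(chrom, pos, direction, maxGap = 500L,
                        minDmcs = 2L) {
    out <- list()
    for (chr in unique(chrom)) for (d in unique(direction)) {
        p <- sort(pos[chrom == chr & direction == d])
        n <- length(p)
        i <- 1L
        while (i <= n) {
            j <- i
            while (j < n && p[j + 1L] - p[j] <= maxGap) j <- j + 1L
            if (j - i + 1L >= minDmcs)
                out[[length(out) + 1L]] <-
                    data.frame(chrom = chr, start = p[i], end = p[j],
                               direction = d, n = j - i + 1L)
            i <- j + 1L
        }
    }
    if (!length(out))
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), direction = character(),
                          n = integer()))
    df <- do.call(rbind, out)
    df[order(df$chrom, df$start, df$direction), , drop = FALSE]
}

# Fraction of planted intervals recovered by called intervals at >= 50%
# reciprocal overlap with matching direction.
reciprocalRecovery <- function(planted, called) {
    if (!length(planted)) return(NA_real_)
    hitcnt <- 0L
    for (i in seq_along(planted)) {
        ok <- FALSE
        for (j in seq_along(called)) {
            if (as.character(seqnames(planted))[i] !=
                as.character(seqnames(called))[j]) next
            ov <- width(pintersect(ranges(planted[i]),
                                   ranges(called[j]),
                                   resolve.empty = "max.start"))
            if (ov >= 0.5 * width(planted)[i] &&
                ov >= 0.5 * width(called)[j] &&
                identical(planted$direction[i],
                          called$direction[j])) {
                ok <- TRUE
                break
            }
        }
        if (ok) hitcnt <- hitcnt + 1L
    }
    hitcnt / length(planted)
}
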