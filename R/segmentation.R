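# Hypomethylated region (UMR/LMR) segmentation on the destranded CpG
# track.

# Centered running mean over k consecutive values; windows are truncated
# at the ends (mean of the available neighbours).
.runMean <- function(x, k) {
    h <- k %/% 2L
    n <- length(x)
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Segment unmethylated and low-methylated regions
#'
#' Identifies hypomethylated regions — contiguous stretches of CpGs with
#' lower methylation than their surroundings — from a destranded CpG
#' track, and classifies them as UMRs (mean raw level below
#' \code{umrMaxLevel}, the CpG-island-like near-zero class) or LMRs
#' (otherwise; the low-methylated class around 30%). The procedure: (i)
#' only CpGs with coverage of at least \code{minCoverage} enter; (ii)
#' each CpG's level is smoothed with a centered running mean over
#' \code{segSmoothK} consecutive CpGs per chromosome; (iii) CpGs with a
#' smoothed level below \code{lmrMaxLevel} are marked; (iv) maximal runs
#' of at least \code{segMinCpgs} marked CpGs become segments spanning
#' the first to the last CpG; (v) each segment is classified by its mean
#' raw level. Chromosomes with fewer covered CpGs than
#' \code{segSmoothK} are skipped with a warning.
#'
#' @param track a destranded, CpG-only (or mixed; only CpG records are
#'   used) \linkS4class{MethylationTrack}.
#' @param params an \linkS4class{AnalysisParams}.
#' @return a \linkS4class{SegmentSet}; segments never overlap.
#' @export
segmentHmrs <- function(track, params = analysisParams()) {
    stopifnot(is(track, "MethylationTrack"))
    all_sites <- track@sites
    chroms_with_cpg <- as.character(unique(
        seqnames(all_sites[all_sites$context == "CpG"])))
    gr <- all_sites[all_sites$context == "CpG" &
             (all_sites$n_meth + all_sites$n_unmeth) >=
                 params@minCoverage &
             !is.na(all_sites$level)]
    segs <- GRanges(kind = character(), n_cpg = integer(),
                    mean_level = numeric())
    for (chr in chroms_with_cpg) {
        g <- gr[seqnames(gr) == chr]
        g <- g[order(start(g))]
        n <- length(g)
        if (n < params@segSmoothK) {
            warning("chromosome ", chr, " has fewer than ",
                    params@segSmoothK,
                    " covered CpGs; skipped in segmentation",
                    call. = FALSE)
            next
        }
        sm <- .runMean(g$level, params@segSmoothK)
        marked <- sm < params@lmrMaxLevel
        r <- rle(marked)
        ends_i <- cumsum(r$lengths)
        starts_i <- ends_i - r$lengths + 1L
        keep <- r$values & r$lengths >= params@segMinCpgs
        if (!any(keep)) next
        si <- starts_i[keep]; ei <- ends_i[keep]
        mlev <- vapply(seq_along(si), function(j)
            mean(g$level[si[j]:ei[j]]), 0)
        kind <- ifelse(mlev < params@umrMaxLevel, "UMR", "LMR")
        segs <- .cGr(list(segs, GRanges(chr,
                                IRanges(start(g)[si], start(g)[ei]),
                                kind = kind,
                                n_cpg = ei - si + 1L,
                                mean_level = mlev)))
    }
    segs <- segs[order(as.integer(seqnames(segs)), start(segs))]
    new("SegmentSet", segments = segs, params = params)
}

#' Report UMRs overlapping promoters
#'
#' Lists the UMRs having at least 1 bp overlap with any promoter,
#' annotated with the overlapping gene id(s), plus the total count.
#' Adjacency without overlap does not count.
#'
#' @param segset a \linkS4class{SegmentSet}.
#' @param contexts a \linkS4class{GenomicContexts} on the same assembly.
#' @return a list with \code{overlaps} (GRanges of qualifying UMRs with
#'   a comma-separated \code{gene_ids} column) and \code{count}.
#' @seealso \code{\link{writeBed}} to export the overlaps.
#' @export
overlapUmrsPromoters <- function(segset, contexts) {
    stopifnot(is(segset, "SegmentSet"), is(contexts, "GenomicContexts"))
    umrs <- segset@segments[segset@segments$kind == "UMR"]
    hits <- findOverlaps(umrs, contexts@promoters, ignore.strand = TRUE)
    idx <- unique(queryHits(hits))
    out <- umrs[idx]
    gids <- vapply(idx, function(i) paste(unique(
        contexts@promoters$gene_id[subjectHits(hits)[queryHits(hits) == i]]),
        collapse = ","), "")
    out$gene_ids <- gids
    list(overlaps = out, count = length(out))
}

#' Summarize a segment set
#'
#' @param segset a \linkS4class{SegmentSet}.
#' @return a data.frame with per-kind counts, mean lengths and mean CpG
#'   counts.
#' @export
summarizeSegments <- function(segset) {
    gr <- segset@segments
    do.call(rbind, lapply(c("UMR", "LMR"), function(k) {
        g <- gr[gr$kind == k]
        data.frame(kind = k, n = length(g),
                   mean_length = if (length(g)) mean(width(g)) else
                       NA_real_,
                   mean_n_cpg = if (length(g)) mean(g$n_cpg) else
                       NA_real_,
                   mean_level = if (length(g)) mean(g$mean_level) else
                       NA_real_)
    }))
}

#' Export segments as BED
#'
#' Name column is the segment kind; score is
#' \code{round(1000 * (1 - mean_level))}, so fully unmethylated segments
#' score 1000.
#'
#' @param segset a \linkS4class{SegmentSet}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSegmentsBed <- function(segset, path) {
    gr <- segset@segments
    gr$name <- gr$kind
    gr$score <- as.integer(round(1000 * (1 - gr$mean_level)))
    writeBed(gr, path)
}
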