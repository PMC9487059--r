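# Differential methylation: per-site exact tests, BH adjustment, DMC
# filtering, DMR clustering under two rule sets, summaries and
# promoter-based gene association.

# Two-sided exact test on a 2x2 table [[a, b], [c, d]] under the
# hypergeometric null: sum of the probabilities of all tables (with the
# same margins) no more likely than the observed one. The relative
# tolerance on the probability comparison mirrors the conventional
# guard against floating-point ties.
.exactTest2x2 <- function(a, b, c, d) {
    m <- a + b; n2 <- c + d; k <- a + c
    support <- max(0L, k - n2):min(k, m)
    probs <- dhyper(support, m, n2, k)
    pobs <- dhyper(a, m, n2, k)
    min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

#' Per-site exact test of differential methylation
#'
#' Compares two replicate-merged methylation tracks site by site. Only
#' sites present in both tracks with coverage of at least
#' \code{minCoverage} in each are tested. At each such site a two-sided
#' exact test is performed on the 2x2 table of (methylated,
#' unmethylated) counts in case and control under the hypergeometric
#' null, and the level difference is reported in percentage points
#' (case minus control).
#'
#' @param case,control \linkS4class{MethylationTrack}s (typically
#'   destranded CpG tracks so DMC coordinates match segmentation).
#' @param params an \linkS4class{AnalysisParams} (coverage cutoff).
#' @param context restrict testing to one CX context (default
#'   \code{"CpG"}); use \code{NULL} to test all contexts.
#' @return a width-1 GRanges of tested sites with metadata columns
#'   \code{context}, \code{case_meth}, \code{case_unmeth},
#'   \code{control_meth}, \code{control_unmeth}, \code{diff_pp},
#'   \code{p_value}. Empty (with a warning) when no site qualifies.
#' @export
testDmc <- function(case, control, params = analysisParams(),
                    context = "CpG") {
    stopifnot(is(case, "MethylationTrack"),
              is(control, "MethylationTrack"))
    a <- case@sites; b <- control@sites
    if (!is.null(context)) {
        a <- a[a$context == context]
        b <- b[b$context == context]
    }
    a <- a[(a$n_meth + a$n_unmeth) >= params@minCoverage]
    b <- b[(b$n_meth + b$n_unmeth) >= params@minCoverage]
    ka <- paste(as.character(seqnames(a)), start(a),
                as.character(strand(a)))
    kb <- paste(as.character(seqnames(b)), start(b),
                as.character(strand(b)))
    hit <- match(ka, kb)
    ia <- which(!is.na(hit)); ib <- hit[ia]
    if (!length(ia)) {
        warning("no shared sites passing the coverage filter",
                call. = FALSE)
        out <- GRanges(context = character(), case_meth = integer(),
                       case_unmeth = integer(),
                       control_meth = integer(),
                       control_unmeth = integer(), diff_pp = numeric(),
                       p_value = numeric())
        return(out)
    }
    out <- granges(a[ia])
    cm <- a$n_meth[ia]; cu <- a$n_unmeth[ia]
    km <- b$n_meth[ib]; ku <- b$n_unmeth[ib]
    out$context <- a$context[ia]
    out$case_meth <- cm; out$case_unmeth <- cu
    out$control_meth <- km; out$control_unmeth <- ku
    out$diff_pp <- 100 * (cm / (cm + cu) - km / (km + ku))
    out$p_value <- mapply(.exactTest2x2, cm, cu, km, ku)
    out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment of per-site p-values; the
#' result is monotone in p-rank, lies in [0, 1] and is invariant to the
#' input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
adjustFdr <- function(p) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    p.adjust(p, method = "BH")
}

#' Filter tested sites into a DMC set
#'
#' Retains sites with \code{q_value <= qCutoff} and
#' \code{|diff_pp| >= minDiffPp}, and assigns the direction: hypo when
#' the case level is below the control level, hyper otherwise. If the
#' input lacks a \code{q_value} column it is computed with
#' \code{\link{adjustFdr}} over all tested sites.
#'
#' @param tested GRanges from \code{\link{testDmc}} (optionally already
#'   carrying \code{q_value}).
#' @param params an \linkS4class{AnalysisParams}.
#' @return a \linkS4class{DmcSet}.
#' @export
filterDmcs <- function(tested, params = analysisParams()) {
    if (is.null(tested$q_value))
        tested$q_value <- adjustFdr(tested$p_value)
    keep <- tested$q_value <= params@qCutoff &
        abs(tested$diff_pp) >= params@minDiffPp
    gr <- tested[keep]
    gr$direction <- ifelse(gr$diff_pp < 0, "hypo", "hyper")
    new("DmcSet", sites = gr, params = params)
}

#' Call DMCs between two tracks
#'
#' Convenience wrapper: \code{\link{testDmc}}, then
#' \code{\link{adjustFdr}}, then \code{\link{filterDmcs}}.
#'
#' @inheritParams testDmc
#' @return a \linkS4class{DmcSet}.
#' @export
callDmcs <- function(case, control, params = analysisParams(),
                     context = "CpG") {
    tested <- testDmc(case, control, params, context)
    if (length(tested))
        tested$q_value <- adjustFdr(tested$p_value)
    else tested$q_value <- numeric()
    filterDmcs(tested, params)
}

#' Cluster DMCs into DMRs (gap rule)
#'
#' Per chromosome and per direction (hypo and hyper DMCs never share a
#' region), maximal chains of DMCs whose consecutive positions differ by
#' at most \code{dmrMaxGap} bp (inclusive: a gap of exactly 500 bp
#' clusters at the default) become DMRs when they contain at least
#' \code{dmrMinDmcs} DMCs. A DMR spans its first to its last member DMC.
#'
#' @param dmcset a \linkS4class{DmcSet}.
#' @param params an \linkS4class{AnalysisParams}.
#' @return a \linkS4class{DmrSet} with \code{rule = "gap_cluster"};
#'   \code{n_cpgs_in_span} is \code{NA} until
#'   \code{\link{filterDmrsSmoothLike}} supplies a CpG track.
#' @export
clusterDmrs <- function(dmcset, params = analysisParams()) {
    stopifnot(is(dmcset, "DmcSet"))
    gr <- dmcset@sites
    out <- GRanges(direction = character(), n_dmcs = integer(),
                   mean_abs_diff_pp = numeric(),
                   n_cpgs_in_span = integer())
    out$dmc_pos <- IntegerList()
    chroms <- as.character(unique(seqnames(gr)))
    for (chr in chroms) for (dir in c("hypo", "hyper")) {
        g <- gr[seqnames(gr) == chr & gr$direction == dir]
        if (length(g) < params@dmrMinDmcs) next
        pos <- sort(start(g))
        brk <- which(diff(pos) > params@dmrMaxGap)
        starts_i <- c(1L, brk + 1L)
        ends_i <- c(brk, length(pos))
        sizes <- ends_i - starts_i + 1L
        keep <- sizes >= params@dmrMinDmcs
        if (!any(keep)) next
        si <- starts_i[keep]; ei <- ends_i[keep]
        diffs <- abs(g$diff_pp[order(start(g))])
        mdiff <- vapply(seq_along(si), function(j)
            mean(diffs[si[j]:ei[j]]), 0)
        members <- IntegerList(lapply(seq_along(si), function(j)
            pos[si[j]:ei[j]]))
        add <- GRanges(chr, IRanges(pos[si], pos[ei]),
                       direction = dir,
                       n_dmcs = ei - si + 1L,
                       mean_abs_diff_pp = mdiff,
                       n_cpgs_in_span = NA_integer_)
        add$dmc_pos <- members
        out <- .cGr(list(out, add))
    }
    out <- out[order(as.integer(seqnames(out)), start(out),
                     out$direction)]
    new("DmrSet", regions = out, rule = "gap_cluster", params = params)
}

#' Filter candidate DMRs under the smoothing-style rule
#'
#' Retains gap-clustered candidates that additionally have at least
#' \code{smoothMinDmcs} DMCs, a mean absolute difference of at least
#' \code{smoothMinDiffPp} percentage points, span at least
#' \code{smoothMinCpgs} destranded CpG units (all units in the track,
#' covered or not), and are at least \code{smoothMinLen} bp long.
#'
#' @param dmrset a gap-clustered \linkS4class{DmrSet}.
#' @param cpgTrack the destranded CpG \linkS4class{MethylationTrack}
#'   used to count CpG units in each span.
#' @param params an \linkS4class{AnalysisParams}.
#' @return a \linkS4class{DmrSet} with \code{rule = "smooth_like"} and
#'   \code{n_cpgs_in_span} filled in.
#' @export
filterDmrsSmoothLike <- function(dmrset, cpgTrack,
                                 params = analysisParams()) {
    stopifnot(is(dmrset, "DmrSet"), is(cpgTrack, "MethylationTrack"))
    gr <- dmrset@regions
    cp <- cpgTrack@sites
    cp <- cp[cp$context == "CpG"]
    gr$n_cpgs_in_span <- countOverlaps(gr, cp, ignore.strand = TRUE)
    keep <- gr$n_dmcs >= params@smoothMinDmcs &
        gr$mean_abs_diff_pp >= params@smoothMinDiffPp &
        gr$n_cpgs_in_span >= params@smoothMinCpgs &
        width(gr) >= params@smoothMinLen
    new("DmrSet", regions = gr[keep], rule = "smooth_like",
        params = params)
}

#' Summarize a DMC set
#'
#' Per-direction DMC counts overall and within promoters, distances
#' between consecutive DMCs per chromosome, and each DMC's signed
#' distance to the nearest TSS in gene orientation (negative = upstream
#' of the TSS). Equidistant TSSs tie-break to the lower coordinate.
#'
#' @param dmcset a \linkS4class{DmcSet}.
#' @param contexts a \linkS4class{GenomicContexts}.
#' @return a list with \code{counts} (data.frame: direction, n_total,
#'   n_in_promoter), \code{adjacent_distances} (data.frame: chrom,
#'   distance) and \code{tss_distances} (data.frame: chrom, pos,
#'   direction, gene_id, distance).
#' @export
summarizeDmcs <- function(dmcset, contexts) {
    stopifnot(is(dmcset, "DmcSet"), is(contexts, "GenomicContexts"))
    gr <- dmcset@sites
    in_prom <- overlapsAny(gr, contexts@promoters, ignore.strand = TRUE)
    counts <- do.call(rbind, lapply(c("hypo", "hyper"), function(d) {
        sel <- gr$direction == d
        data.frame(direction = d, n_total = sum(sel),
                   n_in_promoter = sum(sel & in_prom))
    }))
    dists <- do.call(rbind, lapply(
        as.character(unique(seqnames(gr))), function(chr) {
            pos <- sort(start(gr[seqnames(gr) == chr]))
            if (length(pos) < 2L) return(NULL)
            data.frame(chrom = chr, distance = diff(pos))
        }))
    if (is.null(dists))
        dists <- data.frame(chrom = character(), distance = integer())
    tssd <- NULL
    tss <- contexts@tss
    if (length(gr) && length(tss)) {
        rows <- lapply(seq_along(gr), function(i) {
            chr <- as.character(seqnames(gr))[i]
            cand <- which(as.character(seqnames(tss)) == chr)
            if (!length(cand)) return(NULL)
            pos <- start(gr)[i]
            tp <- start(tss)[cand]
            ad <- abs(pos - tp)
            best <- cand[order(ad, tp)[1L]]
            signed <- if (as.character(strand(tss))[best] == "+")
                pos - start(tss)[best] else start(tss)[best] - pos
            data.frame(chrom = chr, pos = pos,
                       direction = gr$direction[i],
                       gene_id = tss$gene_id[best],
                       distance = signed)
        })
        tssd <- do.call(rbind, rows)
    }
    if (is.null(tssd))
        tssd <- data.frame(chrom = character(), pos = integer(),
                           direction = character(),
                           gene_id = character(), distance = integer())
    list(counts = counts, adjacent_distances = dists,
         tss_distances = tssd)
}

#' Genes whose promoter carries a DMC or overlaps a DMR
#'
#' Collects the unique gene ids whose promoter contains at least one
#' DMC position (for a \linkS4class{DmcSet}) or overlaps a DMR by at
#' least 1 bp (for a \linkS4class{DmrSet}). The resulting list is the
#' hand-off point for functional-enrichment tools.
#'
#' @param features a \linkS4class{DmcSet} or \linkS4class{DmrSet}.
#' @param contexts a \linkS4class{GenomicContexts}.
#' @return a sorted character vector of unique gene ids.
#' @export
associateGenes <- function(features, contexts) {
    stopifnot(is(contexts, "GenomicContexts"))
    gr <- if (is(features, "DmcSet")) features@sites
          else if (is(features, "DmrSet")) features@regions
          else stop("features must be a DmcSet or DmrSet",
                    call. = FALSE)
    hits <- findOverlaps(contexts@promoters, gr, ignore.strand = TRUE)
    sort(unique(contexts@promoters$gene_id[queryHits(hits)]))
}

#' Export a DMC set as TSV
#'
#' Positions are written 1-based for display; columns are chrom, pos,
#' strand, case/control counts, diff_pp, p_value, q_value, direction.
#'
#' @param dmcset a \linkS4class{DmcSet}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeDmcTsv <- function(dmcset, path) {
    gr <- dmcset@sites
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     pos = start(gr),
                     strand = as.character(strand(gr)),
                     case_meth = gr$case_meth,
                     case_unmeth = gr$case_unmeth,
                     control_meth = gr$control_meth,
                     control_unmeth = gr$control_unmeth,
                     diff_pp = sprintf("%.4f", gr$diff_pp),
                     p_value = format(gr$p_value, digits = 6L),
                     q_value = format(gr$q_value, digits = 6L),
                     direction = gr$direction)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export a DMR set as BED
#'
#' Name is \code{direction:rule}; score is
#' \code{round(10 * mean |diff_pp|)}.
#'
#' @param dmrset a \linkS4class{DmrSet}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeDmrBed <- function(dmrset, path) {
    gr <- dmrset@regions
    gr$name <- if (length(gr))
        paste(gr$direction, dmrset@rule, sep = ":") else character()
    gr$score <- pmin(1000L,
                     as.integer(round(10 * gr$mean_abs_diff_pp)))
    gr$dmc_pos <- NULL
    writeBed(gr, path)
}

#' Export a gene list, one id per line
#'
#' @param genes character vector of gene ids.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGeneList <- function(genes, path) {
    writeLines(genes, path)
    invisible(path)
}
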