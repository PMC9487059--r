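# Sample-level methylation tracks and per-sample profiles.

# Combine GRanges that may carry disjoint seqlevel sets (e.g. built per
# chromosome); the seqinfo merge warning is expected and meaningless
# here because no seqlengths are attached.
.cGr <- function(grl) suppressWarnings(do.call(c, grl))

# Sum `values` within integer groups 1..nbins (absent groups -> 0).
.sumBy <- function(values, index, nbins) {
    out <- numeric(nbins)
    if (length(values)) {
        rs <- rowsum(as.numeric(values), index)
        out[as.integer(rownames(rs))] <- rs[, 1L]
    }
    out
}

#' Merge replicate call sets
#'
#' Combines the methyl-C calls of all replicates of one sample: at each
#' (chrom, position, strand) the methylated and unmethylated counts are
#' summed across replicates. The context (and trinucleotide) must agree
#' across replicates at a shared position; sites present in only some
#' replicates are kept with the counts observed.
#'
#' @param replicates a list of \linkS4class{CytosineCalls} on one
#'   coordinate system.
#' @param sampleLabel label for the merged sample.
#' @return a \linkS4class{CytosineCalls} with one record per site.
#' @export
mergeReplicates <- function(replicates, sampleLabel = "merged") {
    stopifnot(length(replicates) >= 1L,
              all(vapply(replicates, is, TRUE, "CytosineCalls")))
    if (length(replicates) == 1L) {
        x <- replicates[[1L]]
        return(CytosineCalls(x@calls, sampleLabel))
    }
    gr <- do.call(c, lapply(replicates, calls))
    gr <- .sortCalls(gr)
    n <- length(gr)
    if (n == 0L) return(CytosineCalls(gr, sampleLabel))
    new_grp <- c(TRUE,
                 as.character(seqnames(gr))[-1L] !=
                     as.character(seqnames(gr))[-n] |
                 start(gr)[-1L] != start(gr)[-n] |
                 as.character(strand(gr))[-1L] !=
                     as.character(strand(gr))[-n])
    grp <- cumsum(new_grp)
    first <- which(new_grp)
    if (any(gr$context != gr$context[first][grp])) {
        bad <- which(gr$context != gr$context[first][grp])[1L]
        stop(sprintf(
            "context disagreement across replicates at %s:%d(%s)",
            as.character(seqnames(gr))[bad], start(gr)[bad],
            as.character(strand(gr))[bad]), call. = FALSE)
    }
    nG <- length(first)
    out <- gr[first]
    out$n_meth <- as.integer(.sumBy(gr$n_meth, grp, nG))
    out$n_unmeth <- as.integer(.sumBy(gr$n_unmeth, grp, nG))
    CytosineCalls(out, sampleLabel)
}

#' Build a methylation-level track
#'
#' Computes the methylation level of every site as the ratio of
#' methylated calls to total (methylated plus unmethylated) calls;
#' zero-coverage sites get \code{NA} (missing), never an imputed value.
#'
#' @param x a \linkS4class{CytosineCalls} object.
#' @return a \linkS4class{MethylationTrack}.
#' @export
buildTrack <- function(x) {
    stopifnot(is(x, "CytosineCalls"))
    gr <- x@calls
    cov <- gr$n_meth + gr$n_unmeth
    gr$level <- ifelse(cov > 0L, gr$n_meth / cov, NA_real_)
    new("MethylationTrack", sites = gr, sampleLabel = x@sampleLabel)
}

.destrandGr <- function(gr) {
    is_cpg <- gr$context == "CpG"
    plus <- which(is_cpg & strand(gr) == "+")
    minus <- which(is_cpg & strand(gr) == "-")
    if (!length(plus) || !length(minus)) return(gr)
    kp <- paste(as.character(seqnames(gr))[plus], start(gr)[plus])
    km <- paste(as.character(seqnames(gr))[minus], start(gr)[minus] - 1L)
    hit <- match(km, kp)
    paired_m <- which(!is.na(hit))
    if (!length(paired_m)) return(gr)
    pi <- plus[hit[paired_m]]
    mi <- minus[paired_m]
    gr$n_meth[pi] <- gr$n_meth[pi] + gr$n_meth[mi]
    gr$n_unmeth[pi] <- gr$n_unmeth[pi] + gr$n_unmeth[mi]
    gr[-mi]
}

#' @rdname destrandCpg
#' @export
setMethod("destrandCpg", "CytosineCalls", function(x) {
    CytosineCalls(.destrandGr(x@calls), x@sampleLabel)
})

#' @rdname destrandCpg
#' @export
setMethod("destrandCpg", "MethylationTrack", function(x) {
    gr <- .destrandGr(x@sites)
    cov <- gr$n_meth + gr$n_unmeth
    gr$level <- ifelse(cov > 0L, gr$n_meth / cov, NA_real_)
    new("MethylationTrack", sites = .sortCalls(gr),
        sampleLabel = x@sampleLabel)
})

#' Per-context methylation summary
#'
#' For each CX context (CpG, CHG, CHH): the mean level over covered
#' sites, the covered-site count, and a histogram of levels in ten fixed
#' bins of width 10% — left-closed, right-open, except the last bin
#' which is closed at 1.0 (a fully methylated site counts in bin 10).
#'
#' @param track a \linkS4class{MethylationTrack}.
#' @param params an \linkS4class{AnalysisParams} (histogram bin width).
#' @return a list with elements \code{means} (data.frame: context,
#'   mean_level, n_covered) and \code{histogram} (data.frame: context,
#'   bin, lower, upper, count). Histogram counts per context sum to that
#'   context's covered-site count.
#' @export
summarizeContexts <- function(track, params = analysisParams()) {
    stopifnot(is(track, "MethylationTrack"))
    gr <- track@sites
    nb <- as.integer(round(1 / params@histBin))
    lower <- (seq_len(nb) - 1L) / nb
    upper <- seq_len(nb) / nb
    means <- data.frame(context = .CONTEXTS, mean_level = NA_real_,
                        n_covered = 0L)
    hist <- do.call(rbind, lapply(.CONTEXTS, function(cx)
        data.frame(context = cx, bin = seq_len(nb), lower = lower,
                   upper = upper, count = 0L)))
    for (cx in .CONTEXTS) {
        lv <- gr$level[gr$context == cx]
        lv <- lv[!is.na(lv)]
        i <- match(cx, .CONTEXTS)
        means$n_covered[i] <- length(lv)
        if (length(lv)) {
            means$mean_level[i] <- mean(lv)
            b <- pmin(floor(lv * nb) + 1L, nb)
            hist$count[hist$context == cx] <- tabulate(b, nb)
        }
    }
    list(means = means, histogram = hist)
}

#' Bin the genome and average methylation per bin
#'
#' Tiles every chromosome with consecutive fixed-size bins (default
#' 100 kb, last bin truncated at the chromosome end) and reports the
#' mean level over covered sites of the chosen context per bin; bins
#' with no covered site are flagged missing (\code{NA}).
#'
#' @param track a \linkS4class{MethylationTrack}.
#' @param context the CX context to average (\code{"CpG"}, \code{"CHG"}
#'   or \code{"CHH"}).
#' @param params an \linkS4class{AnalysisParams} (bin size).
#' @param chromSizes named integer vector covering every chromosome in
#'   the track.
#' @return a GRanges of bins with metadata columns \code{mean_level}
#'   (NA where empty) and \code{n_covered}.
#' @export
binGenome <- function(track, context = "CpG", params = analysisParams(),
                      chromSizes) {
    stopifnot(is(track, "MethylationTrack"), context %in% .CONTEXTS)
    gr <- track@sites
    used <- as.character(unique(seqnames(gr)))
    miss <- setdiff(used, names(chromSizes))
    if (length(miss))
        stop("chromosome(s) missing from chromSizes: ",
             paste(miss, collapse = ", "), call. = FALSE)
    over <- end(gr) > chromSizes[as.character(seqnames(gr))]
    if (any(over))
        stop("site beyond chromosome end at ",
             as.character(seqnames(gr))[which(over)[1L]], ":",
             start(gr)[which(over)[1L]], call. = FALSE)
    bins <- .cGr(lapply(names(chromSizes), function(chr) {
        L <- as.integer(chromSizes[[chr]])
        s <- seq(1L, L, by = params@binSize)
        GRanges(chr, IRanges(s, pmin(s + params@binSize - 1L, L)))
    }))
    sel <- gr[gr$context == context & !is.na(gr$level)]
    hits <- findOverlaps(sel, bins, ignore.strand = TRUE)
    nb <- length(bins)
    sums <- .sumBy(sel$level[queryHits(hits)], subjectHits(hits), nb)
    cnt <- tabulate(subjectHits(hits), nb)
    bins$mean_level <- ifelse(cnt > 0L, sums / cnt, NA_real_)
    bins$n_covered <- cnt
    bins
}
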