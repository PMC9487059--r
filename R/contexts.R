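# Genomic-context derivation and context-resolved methylation profiles.
# The per-gene interval arithmetic is done on plain integer vectors
# (merge / complement of 1-based closed intervals) and wrapped into
# GRanges at the end; with many small annotations the S4 overhead of
# range ops would otherwise dominate.

# Merge possibly overlapping or adjacent closed intervals.
.mergeIvl <- function(s, e) {
    if (!length(s)) return(list(start = integer(), end = integer()))
    o <- order(s, e)
    s <- s[o]; e <- e[o]
    cm <- cummax(e)
    n <- length(s)
    new_grp <- c(TRUE, s[-1L] > cm[-n] + 1L)
    gend <- c(which(new_grp)[-1L] - 1L, n)
    list(start = s[new_grp], end = cm[gend])
}

# Complement of merged intervals within [lo, hi].
.complementIvl <- function(s, e, lo, hi) {
    if (!length(s)) return(list(start = lo, end = hi))
    gs <- c(lo, e + 1L)
    ge <- c(s - 1L, hi)
    keep <- gs <= ge
    list(start = gs[keep], end = ge[keep])
}

#' Derive genomic context regions from gene models
#'
#' Defines the five region classes used for context-resolved
#' methylation. A promoter is the \code{promoterLen} (default 1 kb)
#' region immediately upstream of a gene's TSS, strand-aware and clamped
#' at chromosome edges. The gene body is the min-to-max span of all
#' transcripts sharing a gene id (which must share chromosome and
#' strand); merged exons are the per-gene union of all transcripts'
#' exons; introns are the gene span minus the merged exons; intergenic
#' regions are the genome minus the union of all transcript spans.
#' Classes other than intergenic may overlap across genes.
#'
#' @param genes transcript GRanges as returned by
#'   \code{\link{readGeneAnnotation}} (metadata: \code{gene_id},
#'   \code{exons}).
#' @param chromSizes named integer vector covering every gene's
#'   chromosome.
#' @param params an \linkS4class{AnalysisParams} (promoter length).
#' @return a \linkS4class{GenomicContexts} object.
#' @export
deriveGenomicContexts <- function(genes, chromSizes,
                                  params = analysisParams()) {
    chromSizes <- stats::setNames(as.integer(chromSizes),
                                  names(chromSizes))
    used <- as.character(unique(seqnames(genes)))
    missChr <- setdiff(used, names(chromSizes))
    if (length(missChr))
        stop("gene(s) on chromosome(s) absent from chromSizes: ",
             paste(missChr, collapse = ", "), call. = FALSE)
    genomeGr <- GRanges(names(chromSizes),
                        IRanges(1L, unname(chromSizes)))
    empty <- GRanges(gene_id = character())
    if (length(genes) == 0L)
        return(new("GenomicContexts", chromSizes = chromSizes,
                   promoters = empty, geneBodies = empty,
                   mergedExons = empty, introns = empty,
                   intergenic = genomeGr, tss = empty))

    chrom <- as.character(seqnames(genes))
    std <- as.character(strand(genes))
    gid <- genes$gene_id
    txs <- start(genes)
    txe <- end(genes)
    first <- match(gid, gid)
    bad <- chrom != chrom[first] | std != std[first]
    if (any(bad))
        stop("transcripts of one gene_id must share chromosome and strand: ",
             paste(unique(gid[bad]), collapse = ", "), call. = FALSE)

    glev <- unique(gid)
    gidx <- match(gid, glev)
    nG <- length(glev)
    g_chr <- chrom[first][!duplicated(gidx)]
    g_std <- std[first][!duplicated(gidx)]
    sp <- split(seq_along(gid), gidx)
    g_start <- vapply(sp, function(i) min(txs[i]), 0L)
    g_end <- vapply(sp, function(i) max(txe[i]), 0L)

    gb <- GRanges(g_chr, IRanges(g_start, g_end), strand = g_std,
                  gene_id = glev)

    on_plus <- g_std == "+"
    chrlen <- unname(chromSizes[g_chr])
    tss_pos <- ifelse(on_plus, g_start, g_end)
    tss <- GRanges(g_chr, IRanges(tss_pos, width = 1L),
                   strand = g_std, gene_id = glev)

    pL <- params@promoterLen
    pstart <- ifelse(on_plus, pmax(1L, tss_pos - pL), tss_pos + 1L)
    pend <- ifelse(on_plus, tss_pos - 1L, pmin(chrlen, tss_pos + pL))
    keep <- pstart <= pend
    promoters <- GRanges(g_chr[keep], IRanges(pstart[keep],
                                              pend[keep]),
                         strand = g_std[keep], gene_id = glev[keep])

    # merged exons and introns per gene, on integer intervals
    exn <- genes$exons
    nex <- lengths(exn)
    es <- unlist(lapply(exn, start), use.names = FALSE)
    ee <- unlist(lapply(exn, end), use.names = FALSE)
    egene <- rep(gidx, nex)
    esp <- split(seq_along(es), factor(egene, levels = seq_len(nG)))
    mex_s <- mex_e <- intr_s <- intr_e <- vector("list", nG)
    for (g in seq_len(nG)) {
        m <- .mergeIvl(es[esp[[g]]], ee[esp[[g]]])
        mex_s[[g]] <- m$start; mex_e[[g]] <- m$end
        cmpl <- .complementIvl(m$start, m$end, g_start[g], g_end[g])
        intr_s[[g]] <- cmpl$start; intr_e[[g]] <- cmpl$end
    }
    nmex <- lengths(mex_s)
    mergedExons <- GRanges(rep(g_chr, nmex),
                           IRanges(unlist(mex_s, use.names = FALSE),
                                   unlist(mex_e, use.names = FALSE)),
                           strand = rep(g_std, nmex),
                           gene_id = rep(glev, nmex))
    nintr <- lengths(intr_s)
    introns <- GRanges(rep(g_chr, nintr),
                       IRanges(unlist(intr_s, use.names = FALSE),
                               unlist(intr_e, use.names = FALSE)),
                       strand = rep(g_std, nintr),
                       gene_id = rep(glev, nintr))

    # intergenic: per-chromosome complement of merged transcript spans
    ig_chr <- ig_s <- ig_e <- list()
    for (chr in names(chromSizes)) {
        on <- chrom == chr
        m <- .mergeIvl(txs[on], txe[on])
        cmpl <- .complementIvl(m$start, m$end, 1L,
                               unname(chromSizes[[chr]]))
        ig_chr[[chr]] <- rep(chr, length(cmpl$start))
        ig_s[[chr]] <- cmpl$start
        ig_e[[chr]] <- cmpl$end
    }
    intergenic <- GRanges(unlist(ig_chr, use.names = FALSE),
                          IRanges(unlist(ig_s, use.names = FALSE),
                                  unlist(ig_e, use.names = FALSE)))

    new("GenomicContexts", chromSizes = chromSizes,
        promoters = promoters, geneBodies = gb,
        mergedExons = mergedExons, introns = introns,
        intergenic = intergenic, tss = tss)
}

#' Mean methylation per genomic region class
#'
#' For each of the five region classes (promoter, gene, exon, intron,
#' intergenic), the mean level over covered sites of the chosen CX
#' context falling in that class. Classes are non-exclusive except
#' intergenic: a site inside an exon also counts in the gene-body mean,
#' but an intergenic site never counts in any gene-linked class.
#'
#' @param track a \linkS4class{MethylationTrack}.
#' @param contexts a \linkS4class{GenomicContexts}.
#' @param context CX context to summarize (default \code{"CpG"}).
#' @return a data.frame with columns \code{region_class},
#'   \code{mean_level} (NA when no covered site falls in the class) and
#'   \code{n_sites}.
#' @export
contextLevelSummary <- function(track, contexts, context = "CpG") {
    stopifnot(is(track, "MethylationTrack"),
              is(contexts, "GenomicContexts"), context %in% .CONTEXTS)
    gr <- track@sites
    sel <- gr[gr$context == context & !is.na(gr$level)]
    classes <- list(promoter = contexts@promoters,
                    gene = contexts@geneBodies,
                    exon = contexts@mergedExons,
                    intron = contexts@introns,
                    intergenic = contexts@intergenic)
    res <- lapply(names(classes), function(nm) {
        inside <- overlapsAny(sel, classes[[nm]], ignore.strand = TRUE)
        data.frame(region_class = nm,
                   mean_level = if (any(inside))
                       mean(sel$level[inside]) else NA_real_,
                   n_sites = sum(inside))
    })
    do.call(rbind, res)
}

#' TSS metaprofile
#'
#' Mean methylation in sliding windows around every gene's TSS: windows
#' of \code{window} bp advancing by \code{step} bp across
#' \code{tssFlank} bp on each side (26 windows at the defaults). Windows
#' are oriented by strand — window 1 is the most upstream window for
#' both '+' and '-' genes, so a '-' gene's profile equals the
#' coordinate-mirrored '+' computation. Windows that run past a
#' chromosome edge are marked missing for that gene, as are windows with
#' no covered site; the across-gene mean per window ignores missing
#' genes.
#'
#' @param track a \linkS4class{MethylationTrack}.
#' @param contexts a \linkS4class{GenomicContexts} (TSS positions and
#'   chromosome sizes).
#' @param params an \linkS4class{AnalysisParams} (flank, window, step).
#' @param context CX context of the profiled sites (default
#'   \code{"CpG"}, the biologically standard choice for TSS profiles).
#' @return a \linkS4class{MetaProfile}.
#' @export
tssMetaprofile <- function(track, contexts, params = analysisParams(),
                           context = "CpG") {
    stopifnot(is(track, "MethylationTrack"),
              is(contexts, "GenomicContexts"))
    flank <- params@tssFlank; win <- params@window; step <- params@step
    nW <- (2L * flank - win) %/% step + 1L
    rel_start <- -flank + (seq_len(nW) - 1L) * step
    windows <- data.frame(rel_start = rel_start,
                          rel_end = rel_start + win,
                          center = rel_start + win / 2)
    tssgr <- contexts@tss
    nG <- length(tssgr)
    mat <- matrix(NA_real_, nrow = nG, ncol = nW,
                  dimnames = list(tssgr$gene_id, NULL))
    if (nG > 0L) {
        chr <- as.character(seqnames(tssgr))
        t1 <- start(tssgr)
        plus <- as.character(strand(tssgr)) == "+"
        gidx <- rep(seq_len(nG), each = nW)
        widx <- rep(seq_len(nW), times = nG)
        a <- rel_start[widx]
        s1 <- ifelse(plus[gidx], t1[gidx] + a,
                     t1[gidx] - a - win + 1L)
        e1 <- s1 + win - 1L
        inb <- s1 >= 1L &
            e1 <= contexts@chromSizes[chr[gidx]]
        if (any(inb)) {
            wgr <- GRanges(chr[gidx][inb], IRanges(s1[inb], e1[inb]))
            gr <- track@sites
            sel <- gr[gr$context == context & !is.na(gr$level)]
            hits <- findOverlaps(sel, wgr, ignore.strand = TRUE)
            nwin <- length(wgr)
            sums <- .sumBy(sel$level[queryHits(hits)],
                           subjectHits(hits), nwin)
            cnt <- tabulate(subjectHits(hits), nwin)
            vals <- ifelse(cnt > 0L, sums / cnt, NA_real_)
            mat[cbind(gidx[inb], widx[inb])] <- vals
        }
    }
    agg <- colMeans(mat, na.rm = TRUE)
    agg[is.nan(agg)] <- NA_real_
    new("MetaProfile", windows = windows, geneLevels = mat,
        aggregate = agg)
}
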