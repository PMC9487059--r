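# S4 classes. All ranges are width-1 (per-cytosine) or interval GRanges in
# 1-based closed coordinates; strand is '+' or '-' for cytosines.

.CONTEXTS <- c("CpG", "CHG", "CHH")

#' Analysis parameters
#'
#' One object holding every numeric constant of the toolkit: profiling
#' geometry, coverage and significance cutoffs, DMR clustering rules and
#' hypomethylation segmentation thresholds. Defaults follow the conventions
#' of the underlying methods: 1-kb promoters, 100-kb genome bins, 10%
#' histogram bins, a 500-bp window sliding by 100 bp across +/-1500 bp of
#' the TSS, minimum coverage 5, q-value cutoff 0.5, minimum DMC difference
#' 25 percentage points, DMR gap 500 bp with at least 2 DMCs
#' (gap-clustering rule) and at least 3 DMCs / 10 pp mean difference /
#' 70 CpGs / 1 kb (smoothing-style rule), and UMR/LMR level bounds 0.10
#' and 0.50 with runs of at least 4 CpGs smoothed over 3 neighbours.
#'
#' @slot promoterLen promoter length upstream of the TSS, bp.
#' @slot binSize genome bin size, bp.
#' @slot histBin methylation-level histogram bin width (fraction).
#' @slot tssFlank flank on each side of the TSS for metaprofiles, bp.
#' @slot window metaprofile sliding-window size, bp.
#' @slot step metaprofile step size, bp.
#' @slot minCoverage minimum combined read coverage for a site to enter
#'   differential testing or segmentation.
#' @slot qCutoff maximum q-value for a site to be retained as a DMC.
#' @slot minDiffPp minimum absolute methylation difference (percentage
#'   points) for a DMC.
#' @slot dmrMaxGap maximum distance between adjacent DMCs in one DMR, bp.
#' @slot dmrMinDmcs minimum DMCs per DMR (gap-clustering rule).
#' @slot smoothMinDmcs minimum DMCs per DMR (smoothing-style rule).
#' @slot smoothMinDiffPp minimum mean |difference| per DMR, pp
#'   (smoothing-style rule).
#' @slot smoothMinCpgs minimum destranded CpGs spanned per DMR
#'   (smoothing-style rule).
#' @slot smoothMinLen minimum DMR length, bp (smoothing-style rule).
#' @slot umrMaxLevel mean raw level below which a segment is a UMR.
#' @slot lmrMaxLevel smoothed level below which a CpG is hypomethylated;
#'   also the upper bound of the LMR class.
#' @slot segMinCpgs minimum CpGs per hypomethylated segment.
#' @slot segSmoothK running-mean width (CpGs) for segmentation smoothing.
#' @export
setClass("AnalysisParams", slots = c(
    promoterLen = "integer", binSize = "integer", histBin = "numeric",
    tssFlank = "integer", window = "integer", step = "integer",
    minCoverage = "integer", qCutoff = "numeric", minDiffPp = "numeric",
    dmrMaxGap = "integer", dmrMinDmcs = "integer",
    smoothMinDmcs = "integer", smoothMinDiffPp = "numeric",
    smoothMinCpgs = "integer", smoothMinLen = "integer",
    umrMaxLevel = "numeric", lmrMaxLevel = "numeric",
    segMinCpgs = "integer", segSmoothK = "integer"))

setValidity("AnalysisParams", function(object) {
    lens <- c(promoterLen = object@promoterLen, binSize = object@binSize,
              tssFlank = object@tssFlank, window = object@window,
              step = object@step, dmrMaxGap = object@dmrMaxGap,
              smoothMinLen = object@smoothMinLen)
    if (any(lens <= 0L)) return("all lengths must be positive")
    levs <- c(object@histBin, object@qCutoff, object@umrMaxLevel,
              object@lmrMaxLevel)
    if (any(levs < 0) || any(levs > 1))
        return("level thresholds must lie in [0, 1]")
    if (object@minCoverage < 0L) return("minCoverage must be >= 0")
    if (object@segSmoothK < 1L || object@segMinCpgs < 1L)
        return("segSmoothK and segMinCpgs must be >= 1")
    TRUE
})

#' Per-cytosine methylation calls
#'
#' A sorted set of per-cytosine methylated/unmethylated call counts, the
#' universal currency of the toolkit. Backed by a width-1
#' \link[GenomicRanges]{GRanges} with metadata columns \code{context}
#' (\code{"CpG"}, \code{"CHG"} or \code{"CHH"}), \code{n_meth},
#' \code{n_unmeth} (non-negative integer counts) and \code{trinucleotide}
#' (3 letters over A/C/G/T/N). Zero-coverage cytosines are retained;
#' coverage filters are applied later, at analysis time.
#'
#' @slot calls width-1 GRanges with the metadata columns above, sorted by
#'   (seqnames, position, strand) with at most one record per
#'   (seqnames, position, strand).
#' @slot sampleLabel free-text sample/replicate label.
#' @export
setClass("CytosineCalls",
         slots = c(calls = "GRanges", sampleLabel = "character"))

.checkCallMcols <- function(gr, need_level = FALSE) {
    want <- c("context", "n_meth", "n_unmeth")
    if (need_level) want <- c(want, "level")
    miss <- setdiff(want, colnames(mcols(gr)))
    if (length(miss))
        return(paste("missing metadata column(s):",
                     paste(miss, collapse = ", ")))
    if (!all(gr$context %in% .CONTEXTS))
        return("context must be one of CpG, CHG, CHH")
    if (any(gr$n_meth < 0L) || any(gr$n_unmeth < 0L))
        return("call counts must be non-negative")
    if (length(gr) && !all(width(gr) == 1L))
        return("cytosine records must have width 1")
    if (length(gr) && !all(strand(gr) %in% c("+", "-")))
        return("strand must be '+' or '-'")
    if (is.unsorted(order(as.integer(seqnames(gr)), start(gr),
                          as.integer(strand(gr)))))
        return("records must be sorted by (chrom, pos, strand)")
    key <- paste(as.character(seqnames(gr)), start(gr),
                 as.character(strand(gr)))
    if (anyDuplicated(key))
        return("at most one record per (chrom, pos, strand)")
    TRUE
}

setValidity("CytosineCalls", function(object) {
    if (length(object@sampleLabel) != 1L)
        return("sampleLabel must be a single string")
    ok <- .checkCallMcols(object@calls)
    if (!isTRUE(ok)) return(ok)
    tri <- object@calls$trinucleotide
    if (!is.null(tri) && length(tri)) {
        if (!all(grepl("^[ACGTN]{3}$", tri)))
            return("trinucleotide must be 3 letters over A/C/G/T/N")
        noN <- !grepl("N", tri, fixed = TRUE)
        expect <- ifelse(substr(tri, 2L, 2L) == "G", "CpG",
                  ifelse(substr(tri, 3L, 3L) == "G", "CHG", "CHH"))
        if (any(noN & expect != object@calls$context))
            return("context inconsistent with trinucleotide")
    }
    TRUE
})

#' Per-site methylation-level track
#'
#' A \linkS4class{CytosineCalls}-derived track with the methylation level
#' at each site: \code{level = n_meth / (n_meth + n_unmeth)}, or \code{NA}
#' where coverage is zero. Built with \code{\link{buildTrack}}.
#'
#' @slot sites width-1 GRanges with metadata columns \code{context},
#'   \code{n_meth}, \code{n_unmeth}, \code{level}.
#' @slot sampleLabel sample label carried over from the calls.
#' @export
setClass("MethylationTrack",
         slots = c(sites = "GRanges", sampleLabel = "character"))

setValidity("MethylationTrack", function(object) {
    ok <- .checkCallMcols(object@sites, need_level = TRUE)
    if (!isTRUE(ok)) return(ok)
    gr <- object@sites
    cov <- gr$n_meth + gr$n_unmeth
    lv <- gr$level
    if (any(is.na(lv) != (cov == 0L)))
        return("level must be NA exactly where coverage is 0")
    def <- !is.na(lv)
    if (any(lv[def] < 0) || any(lv[def] > 1))
        return("level must lie in [0, 1]")
    TRUE
})

#' Derived genomic context annotation
#'
#' The five region classes used for context-resolved methylation
#' (promoter, gene body, merged exon, intron, intergenic) plus per-gene
#' TSS positions and the chromosome sizes they were derived against.
#' Built with \code{\link{deriveGenomicContexts}}. Classes other than
#' intergenic may overlap each other; intergenic is disjoint from every
#' transcript.
#'
#' @slot chromSizes named integer vector of chromosome lengths.
#' @slot promoters strand-aware 1-kb (by default) upstream intervals,
#'   with \code{gene_id}.
#' @slot geneBodies per-gene union span, with \code{gene_id}.
#' @slot mergedExons per-gene merged exons, with \code{gene_id}.
#' @slot introns gene span minus merged exons, with \code{gene_id}.
#' @slot intergenic genome minus all transcript spans (unstranded).
#' @slot tss width-1 GRanges of per-gene TSS positions, with
#'   \code{gene_id}.
#' @export
setClass("GenomicContexts", slots = c(
    chromSizes = "integer", promoters = "GRanges", geneBodies = "GRanges",
    mergedExons = "GRanges", introns = "GRanges", intergenic = "GRanges",
    tss = "GRanges"))

setValidity("GenomicContexts", function(object) {
    if (length(object@chromSizes) && is.null(names(object@chromSizes)))
        return("chromSizes must be named")
    grs <- list(object@promoters, object@geneBodies, object@mergedExons,
                object@introns, object@intergenic, object@tss)
    used <- unique(unlist(lapply(grs, function(g)
        as.character(unique(seqnames(g))))))
    if (length(used) && !all(used %in% names(object@chromSizes)))
        return("all region chromosomes must appear in chromSizes")
    TRUE
})

#' TSS metaprofile
#'
#' Mean methylation in sliding windows positioned relative to each gene's
#' transcription start site, oriented so that window 1 is the most
#' upstream window on either strand. At the defaults (flank 1500 bp,
#' window 500 bp, step 100 bp) there are 26 windows per gene.
#'
#' @slot windows data.frame with one row per window: \code{rel_start},
#'   \code{rel_end} (TSS-relative, 0 = the TSS base, half-open) and
#'   \code{center}.
#' @slot geneLevels numeric matrix (genes x windows) of per-gene window
#'   means; \code{NA} where a gene has no covered site in a window or the
#'   window runs off the chromosome.
#' @slot aggregate numeric vector of across-gene means per window,
#'   ignoring \code{NA} genes.
#' @export
setClass("MetaProfile", slots = c(
    windows = "data.frame", geneLevels = "matrix", aggregate = "numeric"))

setValidity("MetaProfile", function(object) {
    if (ncol(object@geneLevels) != nrow(object@windows))
        return("geneLevels columns must match windows rows")
    if (length(object@aggregate) != nrow(object@windows))
        return("aggregate length must match windows rows")
    TRUE
})

#' Hypomethylated segments (UMRs and LMRs)
#'
#' Non-overlapping segments of contiguous hypomethylated CpGs, classified
#' as UMR (mean raw level below \code{umrMaxLevel}) or LMR (otherwise,
#' below \code{lmrMaxLevel}). Built with \code{\link{segmentHmrs}}.
#'
#' @slot segments GRanges with metadata columns \code{kind} ("UMR"/"LMR"),
#'   \code{n_cpg} and \code{mean_level}, sorted by (chrom, start).
#' @slot params the \linkS4class{AnalysisParams} used.
#' @export
setClass("SegmentSet",
         slots = c(segments = "GRanges", params = "AnalysisParams"))

setValidity("SegmentSet", function(object) {
    gr <- object@segments
    need <- c("kind", "n_cpg", "mean_level")
    if (!all(need %in% colnames(mcols(gr))))
        return("segments need kind, n_cpg, mean_level columns")
    if (length(gr)) {
        if (!all(gr$kind %in% c("UMR", "LMR")))
            return("kind must be UMR or LMR")
        if (any(countOverlaps(gr, gr, ignore.strand = TRUE) > 1L))
            return("segments must not overlap")
    }
    TRUE
})

#' Differentially methylated cytosines
#'
#' Per-site differential methylation calls between a case and a control
#' sample: counts in both samples, the level difference in percentage
#' points (case minus control), exact-test p-value, BH q-value and the
#' direction (\code{"hypo"} if the case is lower, \code{"hyper"}
#' otherwise). Built with \code{\link{filterDmcs}} (or the
#' \code{\link{callDmcs}} convenience wrapper).
#'
#' @slot sites width-1 GRanges with metadata columns \code{context},
#'   \code{case_meth}, \code{case_unmeth}, \code{control_meth},
#'   \code{control_unmeth}, \code{diff_pp}, \code{p_value},
#'   \code{q_value}, \code{direction}.
#' @slot params the \linkS4class{AnalysisParams} used for filtering.
#' @export
setClass("DmcSet", slots = c(sites = "GRanges", params = "AnalysisParams"))

setValidity("DmcSet", function(object) {
    gr <- object@sites
    need <- c("context", "case_meth", "case_unmeth", "control_meth",
              "control_unmeth", "diff_pp", "p_value", "q_value",
              "direction")
    miss <- setdiff(need, colnames(mcols(gr)))
    if (length(miss))
        return(paste("missing column(s):", paste(miss, collapse = ", ")))
    if (length(gr)) {
        if (!all(gr$direction %in% c("hypo", "hyper")))
            return("direction must be hypo or hyper")
        if (any((gr$diff_pp < 0) != (gr$direction == "hypo")))
            return("direction must be hypo iff diff_pp < 0")
    }
    TRUE
})

#' Differentially methylated regions
#'
#' Clusters of same-direction DMCs, spanning the first to the last member
#' DMC. Two rule sets exist: \code{"gap_cluster"} (at least
#' \code{dmrMinDmcs} DMCs with adjacent gaps of at most \code{dmrMaxGap}
#' bp) and \code{"smooth_like"} (additionally at least
#' \code{smoothMinDmcs} DMCs, mean |difference| of at least
#' \code{smoothMinDiffPp} pp, at least \code{smoothMinCpgs} destranded
#' CpGs in the span, and length at least \code{smoothMinLen} bp).
#'
#' @slot regions GRanges with metadata columns \code{direction},
#'   \code{n_dmcs}, \code{mean_abs_diff_pp}, \code{n_cpgs_in_span}
#'   (\code{NA} until a CpG track is supplied), \code{dmc_pos}
#'   (IntegerList of member positions).
#' @slot rule \code{"gap_cluster"} or \code{"smooth_like"}.
#' @slot params the \linkS4class{AnalysisParams} used.
#' @export
setClass("DmrSet", slots = c(regions = "GRanges", rule = "character",
                             params = "AnalysisParams"))

setValidity("DmrSet", function(object) {
    if (!object@rule %in% c("gap_cluster", "smooth_like"))
        return("rule must be gap_cluster or smooth_like")
    need <- c("direction", "n_dmcs", "mean_abs_diff_pp",
              "n_cpgs_in_span", "dmc_pos")
    miss <- setdiff(need, colnames(mcols(object@regions)))
    if (length(miss))
        return(paste("missing column(s):", paste(miss, collapse = ", ")))
    TRUE
})

#' Simulation configuration
#'
#' Parameters of the synthetic methylome generator. The methylation
#' landscape follows the canonical mammalian picture: a high CpG
#' background (default 0.80, within the commonly cited 70-90% of CpGs
#' methylated in somatic cells), near-zero CHG/CHH methylation (0.01),
#' unmethylated promoter CpG islands (UMR level 0.02), CpG-poor
#' low-methylated regions (LMR level 0.30), and planted DMRs shifting the
#' case condition by \code{dmrDiffPp} percentage points. Coverage is
#' Poisson with mean \code{coverageMean}; methylated counts are binomial
#' at each site's true probability.
#'
#' @slot seed integer master seed; all per-replicate streams derive from
#'   it deterministically.
#' @slot nChroms,chromLen genome geometry.
#' @slot nGenes number of non-overlapping genes to place.
#' @slot cpgBackgroundLevel true CpG methylation probability outside
#'   planted features.
#' @slot chgChhLevel true CHG/CHH methylation probability.
#' @slot umrAtPromoterProb probability that a promoter carries a planted
#'   UMR.
#' @slot umrLevel,lmrLevel,lmrCount planted UMR/LMR true levels and LMR
#'   count.
#' @slot dmrCount,dmrDiffPp,dmrWidthCpgs planted DMR count, case-control
#'   difference (pp) and width in destranded CpG units.
#' @slot coverageMean mean per-site read coverage per replicate.
#' @slot nReplicates replicates per condition.
#' @export
setClass("SimulationConfig", slots = c(
    seed = "integer", nChroms = "integer", chromLen = "integer",
    nGenes = "integer", cpgBackgroundLevel = "numeric",
    chgChhLevel = "numeric", umrAtPromoterProb = "numeric",
    umrLevel = "numeric", lmrCount = "integer", lmrLevel = "numeric",
    dmrCount = "integer", dmrDiffPp = "numeric", dmrWidthCpgs = "integer",
    coverageMean = "numeric", nReplicates = "integer"))

setValidity("SimulationConfig", function(object) {
    levs <- c(object@cpgBackgroundLevel, object@chgChhLevel,
              object@umrAtPromoterProb, object@umrLevel, object@lmrLevel)
    if (any(levs < 0) || any(levs > 1))
        return("all levels/probabilities must lie in [0, 1]")
    cnt <- c(object@nChroms, object@chromLen, object@nGenes,
             object@lmrCount, object@dmrCount, object@dmrWidthCpgs,
             object@nReplicates)
    if (any(cnt < 0L)) return("all counts must be non-negative")
    if (object@coverageMean < 0) return("coverageMean must be >= 0")
    TRUE
})

#' Simulated ground truth
#'
#' The simulator's true methylation landscape: every cytosine site with
#' its true methylation probability in each condition, plus the planted
#' feature intervals (UMR, LMR, DMR with direction). Inside a planted DMR
#' the two conditions differ by exactly \code{dmrDiffPp}/100 at CpG
#' sites; everywhere else they are equal.
#'
#' @slot sites width-1 GRanges with \code{context}, \code{trinucleotide},
#'   \code{prob_control}, \code{prob_case}.
#' @slot features GRanges of planted intervals with \code{kind}
#'   ("UMR"/"LMR"/"DMR") and \code{direction} ("hypo"/"hyper"/NA).
#' @slot config the \linkS4class{SimulationConfig} used.
#' @export
setClass("TrueLandscape", slots = c(
    sites = "GRanges", features = "GRanges", config = "SimulationConfig"))
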