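# Constructors, accessors and show() methods.

#' @describeIn AnalysisParams-class Construct a parameter set; any default
#'   can be overridden by name.
#' @param ... named parameter overrides (see slots).
#' @return an \linkS4class{AnalysisParams} object.
#' @examples
#' p <- analysisParams(minCoverage = 10L)
#' p@minCoverage
#' @export
analysisParams <- function(...) {
    defaults <- list(
        promoterLen = 1000L, binSize = 100000L, histBin = 0.10,
        tssFlank = 1500L, window = 500L, step = 100L,
        minCoverage = 5L, qCutoff = 0.5, minDiffPp = 25,
        dmrMaxGap = 500L, dmrMinDmcs = 2L,
        smoothMinDmcs = 3L, smoothMinDiffPp = 10,
        smoothMinCpgs = 70L, smoothMinLen = 1000L,
        umrMaxLevel = 0.10, lmrMaxLevel = 0.50,
        segMinCpgs = 4L, segSmoothK = 3L)
    over <- list(...)
    bad <- setdiff(names(over), names(defaults))
    if (length(bad))
        stop("unknown parameter(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    defaults[names(over)] <- over
    proto <- getSlots("AnalysisParams")
    for (nm in names(defaults))
        if (proto[[nm]] == "integer")
            defaults[[nm]] <- as.integer(defaults[[nm]])
        else defaults[[nm]] <- as.numeric(defaults[[nm]])
    do.call(new, c("AnalysisParams", defaults))
}

.sortCalls <- function(gr) {
    gr <- GenomeInfoDb::sortSeqlevels(gr)
    gr[order(as.integer(seqnames(gr)), start(gr),
             as.integer(strand(gr)))]
}

#' @describeIn CytosineCalls-class Construct from a width-1 GRanges
#'   carrying \code{context}, \code{n_meth}, \code{n_unmeth} and
#'   optionally \code{trinucleotide} metadata columns (1-based
#'   positions). Records are sorted; duplicates are an error.
#' @param gr a width-1 GRanges with the required metadata columns.
#' @param sampleLabel sample/replicate label.
#' @return a \linkS4class{CytosineCalls} object.
#' @export
CytosineCalls <- function(gr, sampleLabel = "sample") {
    if (is.null(gr$trinucleotide))
        gr$trinucleotide <- rep("NNN", length(gr))
    gr$n_meth <- as.integer(gr$n_meth)
    gr$n_unmeth <- as.integer(gr$n_unmeth)
    gr$context <- as.character(gr$context)
    gr$trinucleotide <- as.character(gr$trinucleotide)
    new("CytosineCalls", calls = .sortCalls(gr),
        sampleLabel = as.character(sampleLabel))
}

#' @rdname CytosineCalls-class
#' @export
setMethod("calls", "CytosineCalls", function(x) x@calls)

#' @rdname CytosineCalls-class
#' @export
setMethod("sampleLabel", "CytosineCalls", function(x) x@sampleLabel)

#' @rdname MethylationTrack-class
#' @export
setMethod("sampleLabel", "MethylationTrack", function(x) x@sampleLabel)

#' @rdname CytosineCalls-class
#' @export
setMethod("length", "CytosineCalls", function(x) length(x@calls))

#' @rdname MethylationTrack-class
#' @export
setMethod("sites", "MethylationTrack", function(x) x@sites)

#' @rdname MethylationTrack-class
#' @export
setMethod("methLevels", "MethylationTrack", function(x) x@sites$level)

#' @rdname MethylationTrack-class
#' @export
setMethod("length", "MethylationTrack", function(x) length(x@sites))

#' @rdname SegmentSet-class
#' @export
setMethod("segments", "SegmentSet", function(x) x@segments)

#' @rdname SegmentSet-class
#' @export
setMethod("length", "SegmentSet", function(x) length(x@segments))

#' @rdname DmcSet-class
#' @export
setMethod("dmcs", "DmcSet", function(x) x@sites)

#' @rdname DmcSet-class
#' @export
setMethod("length", "DmcSet", function(x) length(x@sites))

#' @rdname DmrSet-class
#' @export
setMethod("dmrs", "DmrSet", function(x) x@regions)

#' @rdname DmrSet-class
#' @export
setMethod("dmrRule", "DmrSet", function(x) x@rule)

#' @rdname DmrSet-class
#' @export
setMethod("length", "DmrSet", function(x) length(x@regions))

setMethod("show", "CytosineCalls", function(object) {
    cat("CytosineCalls '", object@sampleLabel, "': ",
        length(object@calls), " cytosines on ",
        length(unique(seqnames(object@calls))), " chromosome(s)\n",
        sep = "")
    tab <- table(object@calls$context)
    cat("  context: ", paste(names(tab), tab, sep = "=",
                             collapse = ", "), "\n", sep = "")
})

setMethod("show", "MethylationTrack", function(object) {
    lv <- object@sites$level
    cat("MethylationTrack '", object@sampleLabel, "': ",
        length(object@sites), " sites, ", sum(!is.na(lv)),
        " covered\n", sep = "")
    if (any(!is.na(lv)))
        cat(sprintf("  mean level (covered): %.4f\n",
                    mean(lv, na.rm = TRUE)))
})

setMethod("show", "GenomicContexts", function(object) {
    cat("GenomicContexts over", length(object@chromSizes),
        "chromosome(s):\n")
    cat(sprintf("  promoters: %d  geneBodies: %d  mergedExons: %d\n",
                length(object@promoters), length(object@geneBodies),
                length(object@mergedExons)))
    cat(sprintf("  introns: %d  intergenic: %d  tss: %d\n",
                length(object@introns), length(object@intergenic),
                length(object@tss)))
})

setMethod("show", "SegmentSet", function(object) {
    tab <- table(factor(object@segments$kind, c("UMR", "LMR")))
    cat("SegmentSet:", length(object@segments), "segments (UMR:",
        tab[["UMR"]], " LMR:", tab[["LMR"]], ")\n")
})

setMethod("show", "DmcSet", function(object) {
    tab <- table(factor(object@sites$direction, c("hypo", "hyper")))
    cat("DmcSet:", length(object@sites), "DMCs (hypo:", tab[["hypo"]],
        " hyper:", tab[["hyper"]], ")\n")
})

setMethod("show", "DmrSet", function(object) {
    cat("DmrSet [", object@rule, "]: ", length(object@regions),
        " regions\n", sep = "")
})

setMethod("show", "MetaProfile", function(object) {
    cat("MetaProfile:", nrow(object@geneLevels), "genes x",
        nrow(object@windows), "windows\n")
})

setMethod("show", "AnalysisParams", function(object) {
    sl <- getSlots("AnalysisParams")
    for (nm in names(sl))
        cat(sprintf("  %-16s %s\n", nm, format(slot(object, nm))))
})

setMethod("show", "TrueLandscape", function(object) {
    cat("TrueLandscape:", length(object@sites), "sites,",
        length(object@features), "planted features\n")
})

#' List the resolved parameter values
#'
#' @param params an \linkS4class{AnalysisParams}.
#' @return a named list of all parameter values.
#' @export
paramsAsList <- function(params) {
    sl <- names(getSlots("AnalysisParams"))
    stats::setNames(lapply(sl, function(nm) slot(params, nm)), sl)
}
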