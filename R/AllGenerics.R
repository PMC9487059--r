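#' @rdname CytosineCalls-class
#' @param x an object with per-cytosine calls.
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname CytosineCalls-class
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))

#' @rdname MethylationTrack-class
#' @param x a \linkS4class{MethylationTrack}.
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @rdname MethylationTrack-class
#' @export
setGeneric("methLevels", function(x) standardGeneric("methLevels"))

#' @rdname SegmentSet-class
#' @param x a \linkS4class{SegmentSet}.
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname DmcSet-class
#' @param x a \linkS4class{DmcSet}.
#' @export
setGeneric("dmcs", function(x) standardGeneric("dmcs"))

#' @rdname DmrSet-class
#' @param x a \linkS4class{DmrSet}.
#' @export
setGeneric("dmrs", function(x) standardGeneric("dmrs"))

#' @rdname DmrSet-class
#' @export
setGeneric("dmrRule", function(x) standardGeneric("dmrRule"))

#' Pool symmetric CpG strand pairs
#'
#' Sums the counts of the two strands of each symmetric CpG dinucleotide
#' ('+' cytosine at position p, '-' cytosine at p+1) into one record
#' anchored at p on the '+' strand. Unpaired CpG sites and non-CpG
#' contexts pass through unchanged; the operation is idempotent and
#' conserves counts exactly.
#'
#' @param x a \linkS4class{MethylationTrack} or
#'   \linkS4class{CytosineCalls}.
#' @return an object of the same class with CpG strand pairs pooled
#'   (levels recomputed for tracks).
#' @export
setGeneric("destrandCpg", function(x) standardGeneric("destrandCpg"))
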