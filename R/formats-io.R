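# On-disk formats: Bismark CX cytosine report (7-column TSV, 1-based),
# BS-Seeker2 CGmap (8-column TSV, 1-based), genePred / BED12 annotation,
# BED / bedGraph output, chrom.sizes.

.isGzip <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readBin(con, "raw", 2L)
    length(magic) == 2L && magic[1L] == as.raw(0x1f) &&
        magic[2L] == as.raw(0x8b)
}

.readLinesAuto <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    con <- if (.isGzip(path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    readLines(con)
}

.splitTsv <- function(lines, ncol, what) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf != ncol)
    if (length(bad))
        stop(sprintf(
            "%s: malformed line %d (expected %d tab-separated fields, found %d)",
            what, bad[1L], ncol, nf[bad[1L]]), call. = FALSE)
    matrix(unlist(fields, use.names = FALSE), ncol = ncol, byrow = TRUE)
}

.asCount <- function(x, what, field) {
    v <- suppressWarnings(as.integer(x))
    bad <- which(is.na(v) | v < 0L)
    if (length(bad))
        stop(sprintf("%s: malformed line %d (%s '%s' is not a non-negative integer)",
                     what, bad[1L], field, x[bad[1L]]), call. = FALSE)
    v
}

.mapContextIn <- function(ctx, what) {
    out <- ifelse(ctx == "CG", "CpG", ctx)
    bad <- which(!out %in% .CONTEXTS)
    if (length(bad))
        stop(sprintf("%s: malformed line %d (context '%s' not one of CG/CHG/CHH)",
                     what, bad[1L], ctx[bad[1L]]), call. = FALSE)
    out
}

#' Read a Bismark-style CX cytosine report
#'
#' Reads a 7-column tab-separated per-cytosine report (chromosome,
#' 1-based position, strand, methylated count, unmethylated count,
#' context CG/CHG/CHH, trinucleotide), optionally gzip-compressed
#' (detected by magic bytes, not extension). Context \code{"CG"} is
#' mapped to \code{"CpG"}; zero-coverage rows are retained; unsorted
#' input is sorted silently.
#'
#' @param path path to the report file.
#' @param sampleLabel label for the resulting call set.
#' @return a \linkS4class{CytosineCalls} object.
#' @seealso \code{\link{writeCytosineReport}} for the inverse.
#' @export
readCytosineReport <- function(path, sampleLabel = basename(path)) {
    lines <- .readLinesAuto(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(CytosineCalls(GRanges(context = character(),
                                     n_meth = integer(),
                                     n_unmeth = integer(),
                                     trinucleotide = character()),
                             sampleLabel))
    what <- "cytosine report"
    m <- .splitTsv(lines, 7L, what)
    pos <- .asCount(m[, 2L], what, "position")
    if (any(pos == 0L))
        stop(sprintf("%s: malformed line %d (position must be 1-based)",
                     what, which(pos == 0L)[1L]), call. = FALSE)
    badstr <- which(!m[, 3L] %in% c("+", "-"))
    if (length(badstr))
        stop(sprintf("%s: malformed line %d (strand '%s' not '+'/'-')",
                     what, badstr[1L], m[badstr[1L], 3L]), call. = FALSE)
    gr <- GRanges(m[, 1L], IRanges(pos, width = 1L), strand = m[, 3L],
                  context = .mapContextIn(m[, 6L], what),
                  n_meth = .asCount(m[, 4L], what, "methylated count"),
                  n_unmeth = .asCount(m[, 5L], what, "unmethylated count"),
                  trinucleotide = m[, 7L])
    CytosineCalls(gr, sampleLabel)
}

#' Write a Bismark-style CX cytosine report
#'
#' Emits the same 7-column dialect \code{\link{readCytosineReport}}
#' consumes: tab-separated, 1-based positions, context written as
#' CG/CHG/CHH, sorted by (chrom, position, strand).
#'
#' @param x a \linkS4class{CytosineCalls} object.
#' @param path output path (\code{.gz} suffix writes gzip).
#' @return invisibly, \code{path}.
#' @export
writeCytosineReport <- function(x, path) {
    stopifnot(is(x, "CytosineCalls"))
    gr <- x@calls
    ctx <- ifelse(gr$context == "CpG", "CG", gr$context)
    lines <- if (length(gr)) {
        paste(as.character(seqnames(gr)), start(gr),
              as.character(strand(gr)), gr$n_meth, gr$n_unmeth,
              ctx, gr$trinucleotide, sep = "\t")
    } else character()
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else
        file(path, "wb")
    ok <- try(writeLines(lines, con, sep = "\n"), silent = TRUE)
    close(con)
    if (inherits(ok, "try-error"))
        stop("cannot write cytosine report to ", path, call. = FALSE)
    invisible(path)
}

#' Convert a BS-Seeker2 CGmap file to cytosine calls
#'
#' CGmap rows are (chromosome, nucleotide, 1-based position, context,
#' dinucleotide, level, methylated count, total count) where the
#' nucleotide is \code{C} for a '+' strand cytosine and \code{G} for a
#' '-' strand one. The unmethylated count is total minus methylated.
#' CGmap carries only a dinucleotide, so the stored trinucleotide is
#' padded with \code{"N"}.
#'
#' @param path path to the CGmap file (optionally gzipped).
#' @param sampleLabel label for the resulting call set.
#' @return a \linkS4class{CytosineCalls} object.
#' @export
convertCgmapToCalls <- function(path, sampleLabel = basename(path)) {
    lines <- .readLinesAuto(path)
    lines <- lines[nzchar(lines)]
    what <- "CGmap"
    if (!length(lines))
        return(CytosineCalls(GRanges(context = character(),
                                     n_meth = integer(),
                                     n_unmeth = integer(),
                                     trinucleotide = character()),
                             sampleLabel))
    m <- .splitTsv(lines, 8L, what)
    badnuc <- which(!m[, 2L] %in% c("C", "G"))
    if (length(badnuc))
        stop(sprintf("%s: malformed line %d (nucleotide '%s' not 'C'/'G')",
                     what, badnuc[1L], m[badnuc[1L], 2L]), call. = FALSE)
    nmeth <- .asCount(m[, 7L], what, "methylated count")
    ntot <- .asCount(m[, 8L], what, "total count")
    short <- which(ntot < nmeth)
    if (length(short))
        stop(sprintf("%s: line %d has total count %d < methylated count %d",
                     what, short[1L], ntot[short[1L]], nmeth[short[1L]]),
             call. = FALSE)
    dinuc <- m[, 5L]
    tri <- ifelse(nchar(dinuc) == 2L, paste0(dinuc, "N"), "NNN")
    gr <- GRanges(m[, 1L],
                  IRanges(.asCount(m[, 3L], what, "position"), width = 1L),
                  strand = ifelse(m[, 2L] == "C", "+", "-"),
                  context = .mapContextIn(m[, 4L], what),
                  n_meth = nmeth, n_unmeth = ntot - nmeth,
                  trinucleotide = tri)
    CytosineCalls(gr, sampleLabel)
}

.parseCommaList <- function(x) {
    lapply(strsplit(sub(",$", "", x), ",", fixed = TRUE),
           function(v) suppressWarnings(as.integer(v)))
}

.validateGeneModels <- function(gr) {
    ex <- gr$exons
    for (i in seq_along(gr)) {
        e <- ex[[i]]
        if (length(e) && (min(start(e)) < start(gr)[i] ||
                          max(end(e)) > end(gr)[i]))
            stop("gene annotation: exon outside transcript span for '",
                 gr$gene_id[i], "'", call. = FALSE)
    }
    gr
}

#' Read gene annotation (genePred or BED12)
#'
#' One record per transcript. genePred columns used are name, chrom,
#' strand, txStart, txEnd, exonCount, exonStarts, exonEnds (0-based
#' half-open, comma-separated lists); BED12 block sizes/starts are
#' expanded to exon intervals. Coordinates are converted to the 1-based
#' closed convention of GRanges on ingest; overlapping exons within a
#' transcript are merged. Duplicate gene ids are allowed (multiple
#' transcripts of one gene).
#'
#' @param path path to the annotation file (optionally gzipped).
#' @param dialect \code{"genePred"} or \code{"BED12"}.
#' @return a GRanges of transcripts with metadata columns \code{gene_id}
#'   and \code{exons} (an \link[IRanges]{IRangesList} of absolute
#'   1-based exon intervals).
#' @export
readGeneAnnotation <- function(path, dialect = c("genePred", "BED12")) {
    dialect <- match.arg(dialect)
    lines <- .readLinesAuto(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) {
        gr <- GRanges(gene_id = character())
        gr$exons <- IRangesList()
        return(gr)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (dialect == "genePred") {
        if (any(nf < 10L))
            stop(sprintf("genePred: malformed line %d (fewer than 10 fields)",
                         which(nf < 10L)[1L]), call. = FALSE)
        name <- vapply(fields, `[`, "", 1L)
        chrom <- vapply(fields, `[`, "", 2L)
        strand <- vapply(fields, `[`, "", 3L)
        txStart <- as.integer(vapply(fields, `[`, "", 4L))
        txEnd <- as.integer(vapply(fields, `[`, "", 5L))
        exStarts <- .parseCommaList(vapply(fields, `[`, "", 9L))
        exEnds <- .parseCommaList(vapply(fields, `[`, "", 10L))
        exons <- IRangesList(mapply(function(s, e)
            reduce(IRanges(s + 1L, e)), exStarts, exEnds,
            SIMPLIFY = FALSE))
        gr <- GRanges(chrom, IRanges(txStart + 1L, txEnd),
                      strand = strand, gene_id = name)
        gr$exons <- exons
    } else {
        if (any(nf < 12L))
            stop(sprintf("BED12: malformed line %d (fewer than 12 fields)",
                         which(nf < 12L)[1L]), call. = FALSE)
        chrom <- vapply(fields, `[`, "", 1L)
        cstart <- as.integer(vapply(fields, `[`, "", 2L))
        cend <- as.integer(vapply(fields, `[`, "", 3L))
        name <- vapply(fields, `[`, "", 4L)
        strand <- vapply(fields, `[`, "", 6L)
        sizes <- .parseCommaList(vapply(fields, `[`, "", 11L))
        starts <- .parseCommaList(vapply(fields, `[`, "", 12L))
        exons <- IRangesList(mapply(function(cs, sz, st)
            reduce(IRanges(cs + st + 1L, cs + st + sz)),
            cstart, sizes, starts, SIMPLIFY = FALSE))
        gr <- GRanges(chrom, IRanges(cstart + 1L, cend),
                      strand = strand, gene_id = name)
        gr$exons <- exons
    }
    .validateGeneModels(gr)
}

#' Write intervals as BED
#'
#' Standard BED with name and score columns, 0-based half-open, sorted by
#' (chrom, start). Scores are clamped to [0, 1000] by validation, not
#' silently.
#'
#' @param gr a GRanges; metadata column \code{name} (or \code{kind}) is
#'   used as the BED name, \code{score} (optional, in [0, 1000]) as the
#'   score.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeBed <- function(gr, path) {
    if (length(gr) && any(width(gr) < 1L))
        stop("BED intervals must satisfy start < end", call. = FALSE)
    nm <- if (!is.null(gr$name)) gr$name else if (!is.null(gr$kind))
        gr$kind else rep(".", length(gr))
    sc <- if (!is.null(gr$score)) gr$score else rep(0L, length(gr))
    if (length(sc) && (any(sc < 0) || any(sc > 1000)))
        stop("BED scores must lie in [0, 1000]", call. = FALSE)
    o <- order(as.integer(seqnames(gr)), start(gr))
    gr <- gr[o]; nm <- nm[o]; sc <- sc[o]
    lines <- if (length(gr)) {
        std <- as.character(strand(gr))
        std[std == "*"] <- "."
        paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
              nm, sc, std, sep = "\t")
    } else character()
    writeLines(lines, path)
    invisible(path)
}

#' Write a per-interval value track as bedGraph
#'
#' 4-column bedGraph, 0-based half-open. Intervals with a missing value
#' (\code{NA}) are omitted — absence of data is represented by absence of
#' a line. Overlapping intervals are rejected.
#'
#' @param gr a GRanges of non-overlapping intervals.
#' @param values one numeric value per interval (NA = no data).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeBedGraph <- function(gr, values, path) {
    stopifnot(length(gr) == length(values))
    if (length(gr) &&
        any(countOverlaps(gr, gr, ignore.strand = TRUE) > 1L))
        stop("bedGraph intervals must not overlap", call. = FALSE)
    keep <- !is.na(values)
    gr <- gr[keep]; values <- values[keep]
    o <- order(as.integer(seqnames(gr)), start(gr))
    gr <- gr[o]; values <- values[o]
    lines <- if (length(gr))
        paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
              format(values, trim = TRUE, scientific = FALSE,
                     digits = 6L), sep = "\t")
    else character()
    writeLines(lines, path)
    invisible(path)
}

#' Read / write chromosome sizes
#'
#' Two-column tab-separated text: chromosome name, length.
#'
#' @param path path to a chrom.sizes file.
#' @return \code{readChromSizes}: a named integer vector.
#' @export
readChromSizes <- function(path) {
    lines <- .readLinesAuto(path)
    lines <- lines[nzchar(lines)]
    m <- .splitTsv(lines, 2L, "chrom.sizes")
    len <- .asCount(m[, 2L], "chrom.sizes", "length")
    stats::setNames(len, m[, 1L])
}

#' @rdname readChromSizes
#' @param sizes named integer vector of chromosome lengths.
#' @return \code{writeChromSizes}: invisibly, \code{path}.
#' @export
writeChromSizes <- function(sizes, path) {
    writeLines(paste(names(sizes), as.integer(sizes), sep = "\t"), path)
    invisible(path)
}
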