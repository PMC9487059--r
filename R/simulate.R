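# Synthetic methylome generator: random genome with CpG-island-like
# promoters, gene models, a true methylation landscape with planted
# UMRs / LMRs / DMRs, and binomially sampled cytosine reports.

#' @describeIn SimulationConfig-class Construct a configuration; any
#'   default can be overridden by name.
#' @param ... named overrides (see slots).
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(...) {
    defaults <- list(
        seed = 1L, nChroms = 2L, chromLen = 200000L, nGenes = 20L,
        cpgBackgroundLevel = 0.80, chgChhLevel = 0.01,
        umrAtPromoterProb = 0.5, umrLevel = 0.02,
        lmrCount = 5L, lmrLevel = 0.30,
        dmrCount = 20L, dmrDiffPp = 40, dmrWidthCpgs = 10L,
        coverageMean = 30, nReplicates = 2L)
    over <- list(...)
    bad <- setdiff(names(over), names(defaults))
    if (length(bad))
        stop("unknown simulation parameter(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
    defaults[names(over)] <- over
    proto <- getSlots("SimulationConfig")
    for (nm in names(defaults))
        defaults[[nm]] <- if (proto[[nm]] == "integer")
            as.integer(defaults[[nm]]) else as.numeric(defaults[[nm]])
    do.call(new, c("SimulationConfig", defaults))
}

.BASE_PROBS <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
.PROMOTER_CPG_RATE <- 0.25  # fraction of promoter dinucleotides set to CG

# All cytosine sites of a genome, both strands, with CX context and
# trinucleotide (N-padded at chromosome edges).
.cytosineSites <- function(genome) {
    parts <- lapply(names(genome), function(chr) {
        v <- strsplit(as.character(genome[[chr]]), "", fixed = TRUE)[[1L]]
        L <- length(v)
        nxt1 <- c(v[-1L], "N")
        nxt2 <- c(v[-c(1L, 2L)], "N", "N")
        prv1 <- c("N", v[-L])
        prv2 <- c("N", "N", v[-c(L - 1L, L)])
        ip <- which(v == "C")
        ctx_p <- ifelse(nxt1[ip] == "G", "CpG",
                 ifelse(nxt2[ip] == "G", "CHG", "CHH"))
        tri_p <- paste0("C", nxt1[ip], nxt2[ip])
        im <- which(v == "G")
        comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
        ctx_m <- ifelse(prv1[im] == "C", "CpG",
                 ifelse(prv2[im] == "C", "CHG", "CHH"))
        tri_m <- paste0("C", comp[prv1[im]], comp[prv2[im]])
        GRanges(chr, IRanges(c(ip, im), width = 1L),
                strand = rep(c("+", "-"), c(length(ip), length(im))),
                context = c(ctx_p, ctx_m),
                trinucleotide = c(tri_p, tri_m))
    })
    .sortCalls(.cGr(parts))
}

#' Simulate a reference genome and annotation
#'
#' Generates a random genome with elevated CpG density at promoter
#' positions (a CpG-island mimic), places \code{nGenes} non-overlapping
#' genes with 2-5 exons each, and optionally writes FASTA, genePred and
#' chrom.sizes files. With a fixed seed the output is byte-identical
#' across runs.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param dir if non-NULL, directory to write \code{genome.fa},
#'   \code{genes.genePred} and \code{chrom.sizes} into.
#' @return a list with \code{genome} (DNAStringSet), \code{genes}
#'   (transcript GRanges with \code{gene_id} and \code{exons}),
#'   \code{chromSizes} and \code{config}.
#' @export
simulateReference <- function(config = simulationConfig(), dir = NULL) {
    stopifnot(is(config, "SimulationConfig"))
    set.seed(config@seed)
    L <- config@chromLen
    chromNames <- sprintf("chrS%d", seq_len(config@nChroms))
    chromSizes <- stats::setNames(rep(L, config@nChroms), chromNames)
    seqs <- lapply(chromNames, function(chr)
        sample(names(.BASE_PROBS), L, replace = TRUE,
               prob = .BASE_PROBS))
    names(seqs) <- chromNames

    pL <- 1000L
    placed <- GRanges()
    genes <- GRanges(gene_id = character())
    genes$exons <- IRangesList()
    if (config@nGenes > 0L) {
        recs <- vector("list", config@nGenes)
        for (i in seq_len(config@nGenes)) {
            ok <- FALSE
            for (try in seq_len(200L)) {
                chr <- sample(chromNames, 1L)
                glen <- sample(2000:6000, 1L)
                if (L < glen + 2L * pL + 200L)
                    stop("chromLen too small to place genes",
                         call. = FALSE)
                gstart <- sample(seq(pL + 100L, L - glen - pL - 100L),
                                 1L)
                std <- sample(c("+", "-"), 1L)
                cand <- GRanges(chr, IRanges(gstart - pL - 100L,
                                             gstart + glen + pL + 100L))
                if (!length(placed) ||
                    !any(suppressWarnings(overlapsAny(cand,
                                                      placed)))) {
                    placed <- .cGr(list(placed, cand))
                    nex <- sample(2:5, 1L)
                    cuts <- sort(sample(seq(gstart + 50L,
                                            gstart + glen - 51L),
                                        2L * nex - 2L))
                    bounds <- c(gstart, cuts, gstart + glen - 1L)
                    exStarts <- bounds[seq(1L, 2L * nex, by = 2L)]
                    exEnds <- bounds[seq(2L, 2L * nex, by = 2L)]
                    g <- GRanges(chr, IRanges(gstart,
                                              gstart + glen - 1L),
                                 strand = std,
                                 gene_id = sprintf("gene%03d", i))
                    g$exons <- IRangesList(IRanges(exStarts, exEnds))
                    recs[[i]] <- g
                    ok <- TRUE
                    break
                }
            }
            if (!ok)
                stop("cannot place ", config@nGenes, " non-overlapping ",
                     "genes at this density; reduce nGenes",
                     call. = FALSE)
        }
        genes <- .sortCalls(.cGr(recs))
        # CpG-enrich promoters
        for (i in seq_along(genes)) {
            std <- as.character(strand(genes))[i]
            chr <- as.character(seqnames(genes))[i]
            prom <- if (std == "+")
                c(start(genes)[i] - pL, start(genes)[i] - 1L)
            else c(end(genes)[i] + 1L, end(genes)[i] + pL)
            idx <- seq(prom[1L], prom[2L])
            ndin <- length(idx) %/% 2L
            din_is_cpg <- runif(ndin) < .PROMOTER_CPG_RATE
            bases <- character(2L * ndin)
            bases[seq(1L, by = 2L, length.out = ndin)] <-
                ifelse(din_is_cpg, "C",
                       sample(names(.BASE_PROBS), ndin, replace = TRUE,
                              prob = .BASE_PROBS))
            bases[seq(2L, by = 2L, length.out = ndin)] <-
                ifelse(din_is_cpg, "G",
                       sample(names(.BASE_PROBS), ndin, replace = TRUE,
                              prob = .BASE_PROBS))
            seqs[[chr]][idx[seq_len(2L * ndin)]] <- bases
        }
    }
    genome <- DNAStringSet(vapply(seqs, paste, "", collapse = ""))
    names(genome) <- chromNames
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        writeXStringSet(genome, file.path(dir, "genome.fa"))
        writeGenePred(genes, file.path(dir, "genes.genePred"))
        writeChromSizes(chromSizes, file.path(dir, "chrom.sizes"))
    }
    list(genome = genome, genes = genes, chromSizes = chromSizes,
         config = config)
}

#' Write transcripts as genePred
#'
#' Standard 10-column genePred (0-based half-open coordinates,
#' comma-terminated exon lists); the CDS columns repeat the transcript
#' span.
#'
#' @param genes transcript GRanges with \code{gene_id} and \code{exons}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGenePred <- function(genes, path) {
    lines <- vapply(seq_along(genes), function(i) {
        ex <- genes$exons[[i]]
        paste(genes$gene_id[i], as.character(seqnames(genes))[i],
              as.character(strand(genes))[i],
              start(genes)[i] - 1L, end(genes)[i],
              start(genes)[i] - 1L, end(genes)[i],
              length(ex),
              paste0(paste(start(ex) - 1L, collapse = ","), ","),
              paste0(paste(end(ex), collapse = ","), ","),
              sep = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Simulate the true methylation landscape
#'
#' Assigns every cytosine site a true methylation probability per
#' condition: CpG sites get the background level, CHG/CHH sites the
#' near-zero non-CpG level; promoters selected with probability
#' \code{umrAtPromoterProb} become planted UMRs (their CpGs set to
#' \code{umrLevel} in both conditions); \code{lmrCount} intervals
#' placed away from genes become planted LMRs (\code{lmrLevel}); and
#' \code{dmrCount} intervals of \code{dmrWidthCpgs} destranded CpG
#' units shift the case condition by exactly \code{dmrDiffPp}/100
#' (direction chosen so the shifted probability stays in [0, 1]; at the
#' defaults all planted DMRs are hypomethylated in the case). Feature
#' placements that would overlap are re-drawn up to a retry cap.
#'
#' @param reference output of \code{\link{simulateReference}}.
#' @param config the same \linkS4class{SimulationConfig}.
#' @param dir if non-NULL, ground-truth BED files (one per feature
#'   class) are written there.
#' @return a \linkS4class{TrueLandscape}.
#' @export
simulateLandscape <- function(reference, config = reference$config,
                              dir = NULL) {
    stopifnot(is(config, "SimulationConfig"))
    set.seed(config@seed + 1L)
    sites <- .cytosineSites(reference$genome)
    is_cpg <- sites$context == "CpG"
    prob <- ifelse(is_cpg, config@cpgBackgroundLevel,
                   config@chgChhLevel)
    feats <- GRanges(kind = character(), direction = character())

    ctx <- deriveGenomicContexts(reference$genes,
                                 reference$chromSizes)
    proms <- ctx@promoters
    if (length(proms)) {
        pick <- runif(length(proms)) < config@umrAtPromoterProb
        if (config@umrAtPromoterProb >= 1) pick <- rep(TRUE,
                                                       length(proms))
        if (any(pick)) {
            u <- granges(proms[pick])
            strand(u) <- "*"
            u$kind <- "UMR"; u$direction <- NA_character_
            feats <- .cGr(list(feats, u))
        }
    }

    avoid <- reduce(c(granges(ctx@geneBodies), granges(proms)),
                    ignore.strand = TRUE)
    chromSizes <- reference$chromSizes
    lmr_w <- 1500L
    for (j in seq_len(config@lmrCount)) {
        done <- FALSE
        for (try in seq_len(200L)) {
            chr <- sample(names(chromSizes), 1L)
            s <- sample(seq_len(chromSizes[[chr]] - lmr_w), 1L)
            cand <- GRanges(chr, IRanges(s, s + lmr_w - 1L))
            if (!suppressWarnings(overlapsAny(cand, avoid,
                                              ignore.strand = TRUE)) &&
                (!length(feats) ||
                 !suppressWarnings(overlapsAny(cand + 2000L, feats,
                                               ignore.strand = TRUE)))) {
                cand$kind <- "LMR"; cand$direction <- NA_character_
                feats <- .cGr(list(feats, cand))
                done <- TRUE
                break
            }
        }
        if (!done)
            stop("could not place LMR ", j,
                 " without overlap; reduce lmrCount", call. = FALSE)
    }

    # DMRs anchored on runs of destranded CpG units with gaps small
    # enough for gap-clustering to see one region.
    units <- sites[is_cpg & strand(sites) == "+"]
    hypo_ok <- config@cpgBackgroundLevel - config@dmrDiffPp / 100 >= 0
    hyper_ok <- config@cpgBackgroundLevel + config@dmrDiffPp / 100 <= 1
    if (config@dmrCount > 0L && !hypo_ok && !hyper_ok)
        stop("dmrDiffPp incompatible with cpgBackgroundLevel",
             call. = FALSE)
    w <- config@dmrWidthCpgs
    for (j in seq_len(config@dmrCount)) {
        done <- FALSE
        for (try in seq_len(500L)) {
            chr <- sample(names(chromSizes), 1L)
            up <- start(units[seqnames(units) == chr])
            if (length(up) < w) next
            i0 <- sample(length(up) - w + 1L, 1L)
            run <- up[i0:(i0 + w - 1L)]
            if (any(diff(run) > 400L)) next
            cand <- GRanges(chr, IRanges(run[1L], run[w] + 1L))
            if (length(feats) &&
                suppressWarnings(overlapsAny(cand + 1000L, feats,
                                             ignore.strand = TRUE))) next
            dir_j <- if (hypo_ok) "hypo" else "hyper"
            cand$kind <- "DMR"; cand$direction <- dir_j
            feats <- .cGr(list(feats, cand))
            done <- TRUE
            break
        }
        if (!done)
            stop("could not place DMR ", j,
                 " without overlap; reduce dmrCount", call. = FALSE)
    }

    for (k in c("UMR", "LMR")) {
        f <- feats[feats$kind == k]
        if (!length(f)) next
        lv <- if (k == "UMR") config@umrLevel else config@lmrLevel
        prob[is_cpg & overlapsAny(sites, f, ignore.strand = TRUE)] <- lv
    }
    prob_case <- prob
    dmrf <- feats[feats$kind == "DMR"]
    if (length(dmrf)) {
        d <- config@dmrDiffPp / 100
        for (i in seq_along(dmrf)) {
            inside <- is_cpg & overlapsAny(sites, dmrf[i],
                                           ignore.strand = TRUE)
            shift <- if (dmrf$direction[i] == "hypo") -d else d
            prob_case[inside] <- prob[inside] + shift
        }
    }
    sites$prob_control <- prob
    sites$prob_case <- prob_case
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        for (k in c("UMR", "LMR", "DMR")) {
            f <- feats[feats$kind == k]
            f$name <- if (k == "DMR")
                paste("DMR", f$direction, sep = ":") else rep(k,
                                                              length(f))
            writeBed(f, file.path(dir,
                                  sprintf("truth_%s.bed", tolower(k))))
        }
    }
    new("TrueLandscape", sites = sites, features = feats,
        config = config)
}

#' Sample a replicate's cytosine calls from the landscape
#'
#' Per site, coverage is drawn from a Poisson with mean
#' \code{coverageMean} and the methylated count binomially at the
#' site's true probability in the given condition. The random stream is
#' derived deterministically from (seed, condition, replicate), so each
#' replicate is reproducible independently.
#'
#' @param landscape a \linkS4class{TrueLandscape}.
#' @param condition \code{"case"} or \code{"control"}.
#' @param replicate replicate index (1-based).
#' @param config the \linkS4class{SimulationConfig} (defaults to the
#'   landscape's).
#' @param path if non-NULL, the calls are also written as a cytosine
#'   report there.
#' @return a \linkS4class{CytosineCalls}.
#' @export
sampleCalls <- function(landscape, condition = c("control", "case"),
                        replicate = 1L, config = landscape@config,
                        path = NULL) {
    stopifnot(is(landscape, "TrueLandscape"))
    condition <- match.arg(condition)
    ci <- if (condition == "case") 2L else 1L
    sub <- (as.double(config@seed) * 100003 + ci * 1009 +
            as.double(replicate)) %% 2147483647
    set.seed(as.integer(sub))
    gr <- landscape@sites
    n <- length(gr)
    prob <- if (condition == "case") gr$prob_case else gr$prob_control
    cov <- rpois(n, config@coverageMean)
    nm <- rbinom(n, cov, prob)
    out <- granges(gr)
    out$context <- gr$context
    out$n_meth <- nm
    out$n_unmeth <- cov - nm
    out$trinucleotide <- gr$trinucleotide
    res <- CytosineCalls(out, sprintf("%s_rep%d", condition,
                                      as.integer(replicate)))
    if (!is.null(path)) writeCytosineReport(res, path)
    res
}

#' Simulate a complete fixture bundle
#'
#' Reference, landscape and one cytosine report per (condition,
#' replicate), written under \code{dir}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param dir output directory (created).
#' @return invisibly, a list with the reference, the landscape and a
#'   data.frame of written report paths.
#' @export
simulateMethylome <- function(config = simulationConfig(), dir) {
    ref <- simulateReference(config, dir)
    land <- simulateLandscape(ref, config, dir)
    tab <- expand.grid(condition = c("control", "case"),
                       replicate = seq_len(config@nReplicates),
                       stringsAsFactors = FALSE)
    tab$path <- file.path(dir, sprintf("%s_rep%d.CX_report.txt",
                                       tab$condition, tab$replicate))
    for (i in seq_len(nrow(tab)))
        sampleCalls(land, tab$condition[i], tab$replicate[i], config,
                    path = tab$path[i])
    invisible(list(reference = ref, landscape = land, reports = tab))
}
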