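# Composable pipeline stages over a declarative run configuration, plus
# the entry point used by the command-line wrapper
# (inst/scripts/methylpost). Stages are independently runnable: profile,
# hmr and dmr each start from the cytosine reports named in the config.

#' Read and validate a run configuration
#'
#' A YAML file declaring the sample table (sample name to a list of
#' cytosine-report replicate paths; \code{.CGmap}/\code{.cgmap} files
#' are converted on ingest), optional pairwise comparisons (each with
#' \code{case} and \code{control} sample names), the annotation file
#' and dialect, the chrom.sizes file, and optional
#' \linkS4class{AnalysisParams} overrides under \code{params}.
#'
#' Relative paths are resolved against the config file's directory, so
#' a simulated fixture bundle is self-contained and relocatable.
#'
#' @param path path to the YAML config.
#' @return a validated list with elements \code{samples},
#'   \code{comparisons}, \code{annotation}, \code{annotation_dialect},
#'   \code{chrom_sizes} and \code{params} (an AnalysisParams).
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path))
        stop("config file not found: ", path, call. = FALSE)
    base <- dirname(normalizePath(path))
    anchor <- function(p) ifelse(startsWith(p, "/"), p,
                                 file.path(base, p))
    raw <- yaml::read_yaml(path)
    if (is.null(raw$samples) || !length(raw$samples))
        stop("config must declare at least one sample", call. = FALSE)
    samples <- lapply(raw$samples, function(x)
        anchor(as.character(unlist(x))))
    if (is.null(names(samples)) || any(!nzchar(names(samples))))
        stop("every sample must be named", call. = FALSE)
    comparisons <- lapply(raw$comparisons, function(cmp) {
        if (is.null(cmp$case) || is.null(cmp$control))
            stop("each comparison needs 'case' and 'control'",
                 call. = FALSE)
        for (s in c(cmp$case, cmp$control))
            if (!s %in% names(samples))
                stop("comparison names unknown sample '", s, "'",
                     call. = FALSE)
        list(case = cmp$case, control = cmp$control)
    })
    params <- do.call(analysisParams,
                      if (is.null(raw$params)) list() else raw$params)
    list(samples = samples, comparisons = comparisons,
         annotation = if (is.null(raw$annotation)) NULL else
             anchor(raw$annotation),
         annotation_dialect = if (is.null(raw$annotation_dialect))
             "genePred" else raw$annotation_dialect,
         chrom_sizes = if (is.null(raw$chrom_sizes)) NULL else
             anchor(raw$chrom_sizes), params = params)
}

.checkInputsExist <- function(paths) {
    miss <- paths[!file.exists(paths)]
    if (length(miss))
        stop("missing input file(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
}

.prepOutDir <- function(out, force) {
    if (dir.exists(out) && length(list.files(out)) && !force)
        stop("output directory ", out,
             " exists and is not empty (use force = TRUE)",
             call. = FALSE)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
}

.loadSample <- function(cfg, name) {
    paths <- cfg$samples[[name]]
    .checkInputsExist(paths)
    reps <- lapply(paths, function(p)
        if (grepl("\\.cgmap(\\.gz)?$", tolower(p)))
            convertCgmapToCalls(p) else readCytosineReport(p))
    mergeReplicates(reps, sampleLabel = name)
}

.loadContexts <- function(cfg) {
    .checkInputsExist(c(cfg$annotation, cfg$chrom_sizes))
    genes <- readGeneAnnotation(cfg$annotation,
                                cfg$annotation_dialect)
    sizes <- readChromSizes(cfg$chrom_sizes)
    deriveGenomicContexts(genes, sizes, cfg$params)
}

.writeTsv <- function(df, path) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x)
        ifelse(is.na(x), "NA", format(x, digits = 6L, trim = TRUE,
                                      scientific = FALSE)))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

.writeRunMeta <- function(out, stage, cfg, extra = list()) {
    log <- file.path(out, paste0(stage, ".log"))
    writeLines(c(
        paste0("stage: ", stage),
        paste0("started: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
        "resolved parameters:",
        vapply(names(paramsAsList(cfg$params)), function(nm)
            sprintf("  %s = %s", nm,
                    format(slot(cfg$params, nm))), "")), log)
    manifest <- c(list(stage = stage,
                       params = paramsAsList(cfg$params),
                       samples = cfg$samples), extra)
    jsonlite::write_json(manifest,
                         file.path(out, paste0(stage,
                                               ".manifest.json")),
                         auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(log)
}

#' Run the profiling stage
#'
#' For every sample: the CX-context summary and 10%-bin histogram
#' (TSV), the binned CpG genome track (bedGraph), per-region-class
#' methylation (TSV) and the TSS metaprofile (per-gene matrix and
#' aggregate row, TSV).
#'
#' @param cfg a run configuration from \code{\link{readRunConfig}}.
#' @param out output directory.
#' @param force overwrite a non-empty output directory.
#' @return invisibly, the output directory.
#' @export
runProfile <- function(cfg, out, force = FALSE) {
    ctx <- .loadContexts(cfg)
    .prepOutDir(out, force)
    for (name in names(cfg$samples)) {
        track <- buildTrack(.loadSample(cfg, name))
        cs <- summarizeContexts(track, cfg$params)
        .writeTsv(cs$means,
                  file.path(out, paste0(name, ".context_means.tsv")))
        .writeTsv(cs$histogram,
                  file.path(out, paste0(name, ".histogram.tsv")))
        bins <- binGenome(track, "CpG", cfg$params, ctx@chromSizes)
        writeBedGraph(bins, bins$mean_level,
                      file.path(out, paste0(name,
                                            ".cpg_100kb.bedGraph")))
        .writeTsv(contextLevelSummary(track, ctx, "CpG"),
                  file.path(out, paste0(name,
                                        ".genomic_context.tsv")))
        mp <- tssMetaprofile(track, ctx, cfg$params)
        agg <- data.frame(gene_id = "(aggregate)",
                          t(mp@aggregate))
        per <- data.frame(gene_id = rownames(mp@geneLevels),
                          mp@geneLevels)
        colnames(agg) <- colnames(per) <-
            c("gene_id", sprintf("w%02d", seq_len(nrow(mp@windows))))
        .writeTsv(rbind(agg, per),
                  file.path(out, paste0(name,
                                        ".tss_metaprofile.tsv")))
    }
    .writeRunMeta(out, "profile", cfg)
    invisible(out)
}

#' Run the hypomethylated-region stage
#'
#' For every sample: UMR/LMR segments (BED and summary TSV) from the
#' destranded CpG track, and the promoter-overlapping UMRs (BED plus
#' count).
#'
#' @inheritParams runProfile
#' @return invisibly, the output directory.
#' @export
runHmr <- function(cfg, out, force = FALSE) {
    ctx <- .loadContexts(cfg)
    .prepOutDir(out, force)
    counts <- list()
    for (name in names(cfg$samples)) {
        track <- destrandCpg(buildTrack(.loadSample(cfg, name)))
        segs <- segmentHmrs(track, cfg$params)
        writeSegmentsBed(segs,
                         file.path(out, paste0(name, ".hmr.bed")))
        .writeTsv(summarizeSegments(segs),
                  file.path(out, paste0(name, ".hmr_summary.tsv")))
        ov <- overlapUmrsPromoters(segs, ctx)
        bed <- ov$overlaps
        bed$name <- ifelse(nzchar(bed$gene_ids),
                           paste0("UMR|", bed$gene_ids), "UMR")
        bed$score <- as.integer(round(1000 * (1 - bed$mean_level)))
        writeBed(bed, file.path(out,
                                paste0(name,
                                       ".umr_promoter_overlap.bed")))
        counts[[name]] <- ov$count
    }
    .writeRunMeta(out, "hmr", cfg,
                  list(umr_promoter_overlap_counts = counts))
    invisible(out)
}

#' Run the differential-methylation stage
#'
#' For every comparison pair: the DMC table (TSV), DMRs under both rule
#' sets (BED), the DMC summaries, and the promoter-associated gene
#' list.
#'
#' @inheritParams runProfile
#' @return invisibly, the output directory.
#' @export
runDmr <- function(cfg, out, force = FALSE) {
    if (!length(cfg$comparisons))
        stop("config declares no comparisons", call. = FALSE)
    ctx <- .loadContexts(cfg)
    .prepOutDir(out, force)
    for (cmp in cfg$comparisons) {
        tag <- paste0(cmp$case, "_vs_", cmp$control)
        case <- destrandCpg(buildTrack(.loadSample(cfg, cmp$case)))
        control <- destrandCpg(buildTrack(.loadSample(cfg,
                                                      cmp$control)))
        dmcset <- callDmcs(case, control, cfg$params)
        writeDmcTsv(dmcset, file.path(out, paste0(tag, ".dmc.tsv")))
        gap <- clusterDmrs(dmcset, cfg$params)
        writeDmrBed(gap, file.path(out,
                                   paste0(tag,
                                          ".dmr_gap_cluster.bed")))
        sm <- filterDmrsSmoothLike(gap, control, cfg$params)
        writeDmrBed(sm, file.path(out,
                                  paste0(tag,
                                         ".dmr_smooth_like.bed")))
        sm_dmc <- summarizeDmcs(dmcset, ctx)
        .writeTsv(sm_dmc$counts,
                  file.path(out, paste0(tag, ".dmc_counts.tsv")))
        .writeTsv(sm_dmc$adjacent_distances,
                  file.path(out, paste0(tag, ".dmc_distances.tsv")))
        .writeTsv(sm_dmc$tss_distances,
                  file.path(out, paste0(tag,
                                        ".dmc_tss_distances.tsv")))
        writeGeneList(associateGenes(dmcset, ctx),
                      file.path(out,
                                paste0(tag, ".promoter_genes.txt")))
    }
    .writeRunMeta(out, "dmr", cfg)
    invisible(out)
}

#' Run the simulation stage
#'
#' Writes a complete fixture bundle (genome, annotation, chrom.sizes,
#' ground-truth BEDs, one cytosine report per condition and replicate)
#' plus a ready-to-use run config (\code{run_config.yaml}) naming the
#' generated files, so \code{profile}/\code{hmr}/\code{dmr} can run on
#' the bundle directly.
#'
#' @param out output directory.
#' @param seed integer seed (overrides the config's).
#' @param config a \linkS4class{SimulationConfig}.
#' @param force overwrite a non-empty output directory.
#' @return invisibly, the output directory.
#' @export
runSimulate <- function(out, seed = NULL,
                        config = simulationConfig(), force = FALSE) {
    if (!is.null(seed)) {
        cfgl <- lapply(slotNames(config), function(s)
            slot(config, s))
        names(cfgl) <- slotNames(config)
        cfgl$seed <- as.integer(seed)
        config <- do.call(simulationConfig, cfgl)
    }
    .prepOutDir(out, force)
    bundle <- simulateMethylome(config, out)
    reports <- bundle$reports
    # paths are written relative to the config file, so the bundle is
    # relocatable and byte-identical across output directories
    samples <- lapply(split(basename(reports$path),
                            reports$condition), as.list)
    yaml::write_yaml(list(
        samples = samples,
        comparisons = list(list(case = "case",
                                control = "control")),
        annotation = "genes.genePred",
        annotation_dialect = "genePred",
        chrom_sizes = "chrom.sizes"),
        file.path(out, "run_config.yaml"))
    invisible(out)
}

#' Dispatch a pipeline subcommand
#'
#' The programmatic equivalent of the command-line wrapper:
#' \code{simulate} writes a fixture bundle; \code{profile}, \code{hmr}
#' and \code{dmr} run the corresponding stage over a run config.
#'
#' @param subcommand one of \code{"profile"}, \code{"hmr"},
#'   \code{"dmr"}, \code{"simulate"}.
#' @param config path to a run-config YAML (ignored by
#'   \code{simulate}).
#' @param out output directory.
#' @param force overwrite a non-empty output directory.
#' @param seed integer seed (used by \code{simulate}).
#' @param minCoverage,qCutoff convenience overrides of the two most
#'   commonly tuned parameters (applied on top of the config's
#'   \code{params}).
#' @return invisibly, the output directory.
#' @export
runPipeline <- function(subcommand = c("profile", "hmr", "dmr",
                                       "simulate"),
                        config = NULL, out, force = FALSE, seed = 1L,
                        minCoverage = NULL, qCutoff = NULL) {
    subcommand <- match.arg(subcommand)
    if (subcommand == "simulate")
        return(runSimulate(out, seed = seed, force = force))
    cfg <- readRunConfig(config)
    over <- list()
    if (!is.null(minCoverage)) over$minCoverage <-
        as.integer(minCoverage)
    if (!is.null(qCutoff)) over$qCutoff <- as.numeric(qCutoff)
    if (length(over)) {
        base <- paramsAsList(cfg$params)
        base[names(over)] <- over
        cfg$params <- do.call(analysisParams, base)
    }
    switch(subcommand,
           profile = runProfile(cfg, out, force),
           hmr = runHmr(cfg, out, force),
           dmr = runDmr(cfg, out, force))
}
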