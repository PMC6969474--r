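#' Assemble a pipeline configuration
#'
#' Collects the file paths and tuning parameters of the full analysis into
#' one validated list, loadable from / writable to JSON.
#'
#' @param counts,sampleMap,geneSets,dePvalues,ctTable input file paths (any
#'   may be NA when the corresponding stage is not run).
#' @param outdir output directory.
#' @param rMin,pMax adjacency thresholds.
#' @param deQ FDR level for DE gene selection.
#' @param minCpm,minSamples low-expression filter settings
#'   (\code{minSamples = NULL} means half the samples).
#' @param nPerm permutations for the preservation test.
#' @param seed integer RNG seed.
#' @param setName gene set used for the network stage (default: first set
#'   of the GMT).
#' @param controlGroup control group label of the qPCR stage.
#' @return a named list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(counts = NA, sampleMap = NA, geneSets = NA,
                           dePvalues = NA, ctTable = NA,
                           outdir = ".", rMin = 0.5, pMax = 0.05,
                           deQ = 0.05, minCpm = 1.0, minSamples = NULL,
                           nPerm = 999L, seed = 1L, setName = NULL,
                           controlGroup = "control") {
    if (rMin < 0 || rMin > 1) stop("rMin must lie in [0, 1]")
    if (pMax <= 0 || pMax > 1) stop("pMax must lie in (0, 1]")
    if (deQ <= 0 || deQ >= 1) stop("deQ must lie in (0, 1)")
    cfg <- list(counts = counts, sampleMap = sampleMap, geneSets = geneSets,
                dePvalues = dePvalues, ctTable = ctTable, outdir = outdir,
                rMin = rMin, pMax = pMax, deQ = deQ, minCpm = minCpm,
                minSamples = minSamples, nPerm = as.integer(nPerm),
                seed = as.integer(seed), setName = setName,
                controlGroup = controlGroup)
    class(cfg) <- "PipelineConfig"
    cfg
}

.requirePath <- function(path, what) {
    if (is.null(path) || is.na(path) || !file.exists(path))
        stop("configuration error: ", what, " file not found: ", path)
    path
}

.ensureOutdir <- function(outdir) {
    if (!dir.exists(outdir))
        dir.create(outdir, recursive = TRUE)
    outdir
}

#' Run the network preservation stage end-to-end
#'
#' Reads counts and gene sets, filters low-expression genes, normalizes to
#' log2-CPM, restricts to the focal gene set, builds one hard-thresholded
#' binary coexpression network per condition, computes node statistics,
#' compares them between conditions and attaches permutation p-values.
#' Writes per-condition edge lists, a node-statistics table, the per-gene
#' preservation table and a JSON summary to \code{outdir}.
#'
#' @param config a [pipelineConfig()] (paths \code{counts},
#'   \code{sampleMap} and \code{geneSets} are required).
#' @return invisibly, the [PreservationReport-class].
#' @export
runNetworkPreservation <- function(config) {
    .requirePath(config$counts, "counts")
    .requirePath(config$sampleMap, "sample map")
    .requirePath(config$geneSets, "gene sets (GMT)")
    outdir <- .ensureOutdir(config$outdir)

    message("[network] reading counts")
    cm <- readCounts(config$counts, config$sampleMap)
    conds <- unique(condition(cm))
    if (length(conds) != 2L)
        stop("network preservation stage needs exactly 2 conditions, got ",
             length(conds))
    message("[network] filter: CPM > ", config$minCpm, " in >= ",
            if (is.null(config$minSamples)) "half the samples"
            else config$minSamples, " samples")
    cm <- filterLowExpression(cm, config$minCpm, config$minSamples)
    expr <- cpmLog2(cm)
    gsc <- readGeneSets(config$geneSets)
    if (length(geneSetNames(gsc)) == 0L)
        stop("configuration error: GMT file contains no gene set")
    setName <- if (is.null(config$setName)) geneSetNames(gsc)[1]
               else config$setName
    message("[network] focal gene set: ", setName)
    expr <- subsetToGeneSet(expr, gsc, setName)
    byCond <- splitByCondition(expr)

    message("[network] thresholds: |r| >= ", config$rMin,
            ", p <= ", config$pMax, "; permutations: ", config$nPerm,
            "; seed: ", config$seed)
    report <- permutationPreservationTest(
        byCond[[1]], byCond[[2]], nPerm = config$nPerm, seed = config$seed,
        rMin = config$rMin, pMax = config$pMax, conditionLabels = conds)

    for (lab in conds) {
        co <- suppressWarnings(pearsonMatrix(byCond[[lab]]))
        net <- thresholdAdjacency(co, config$rMin, config$pMax)
        .writeTsv(edgeList(net, co),
                  file.path(outdir, paste0("edges_", lab, ".tsv")))
    }
    .writeTsv(preservationTable(report),
              file.path(outdir, "node_stats.tsv"))
    summary <- list(conditions = conds,
                    geneSet = setName,
                    nGenes = nrow(preservationTable(report)),
                    means = preservationMeans(report),
                    permutationP = as.list(preservationPvalues(report)),
                    nPermutations = report@nPermutations,
                    parameters = list(rMin = config$rMin, pMax = config$pMax,
                                      minCpm = config$minCpm,
                                      seed = config$seed))
    jsonlite::write_json(summary,
                         file.path(outdir, "preservation_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
}

#' Run the enrichment stage
#'
#' Selects DE genes from the p-value table at FDR \code{deQ} (annotated
#' genes only, when the table carries an \code{annotated} column), then
#' tests every gene set for overrepresentation against the background of
#' all genes in the table. Writes \code{enrichment.tsv}.
#'
#' @param config a [pipelineConfig()] (paths \code{dePvalues} and
#'   \code{geneSets} are required).
#' @return invisibly, the enrichment data.frame (see [fisherEnrichment()]).
#' @export
runEnrichment <- function(config) {
    .requirePath(config$dePvalues, "DE p-value table")
    .requirePath(config$geneSets, "gene sets (GMT)")
    outdir <- .ensureOutdir(config$outdir)
    de <- readDETable(config$dePvalues)
    gsc <- readGeneSets(config$geneSets)
    deGenes <- selectDEGenes(de, q = config$deQ)
    background <- if ("annotated" %in% colnames(de))
        de$gene_id[de$annotated %in% TRUE] else de$gene_id
    message("[enrich] ", length(deGenes), " DE genes at FDR <= ",
            config$deQ, " against a background of ", length(background))
    res <- fisherEnrichment(deGenes, background, gsc)
    .writeTsv(res, file.path(outdir, "enrichment.tsv"))
    invisible(res)
}

#' Run the qPCR validation stage
#'
#' Computes per-sample delta-Ct, 2^-ddCt fold changes relative to the
#' control group, and a likelihood ratio test for a group effect, per gene
#' when the Ct table has a \code{gene} column. Writes \code{qpcr_report.tsv}.
#'
#' @param config a [pipelineConfig()] (path \code{ctTable} required).
#' @return invisibly, the per-gene report data.frame.
#' @export
runQpcr <- function(config) {
    .requirePath(config$ctTable, "Ct table")
    outdir <- .ensureOutdir(config$outdir)
    ct <- readCtTable(config$ctTable)
    if (!"gene" %in% colnames(ct))
        ct$gene <- "target"
    res <- do.call(rbind, lapply(split(ct, ct$gene), function(tab) {
        dct <- deltaCt(tab)
        rel <- relativeExpression(dct, config$controlGroup)
        lrt <- lrtGroupEffect(dct)
        other <- rel$groupMeans[rel$groupMeans$group != config$controlGroup, ]
        data.frame(gene = tab$gene[1],
                   n = nrow(tab),
                   fold_change = other$fold_geomean[1],
                   mean_log2_fold = other$mean_log2_fold[1],
                   lrt_statistic = lrt$statistic,
                   p_value = lrt$p_value)
    }))
    rownames(res) <- NULL
    .writeTsv(res, file.path(outdir, "qpcr_report.tsv"))
    invisible(res)
}

#' Write synthetic study inputs to disk
#'
#' Generates the full synthetic input bundle for the pipeline from one
#' [simulationConfig()]: counts TSV + sample map, a GMT with the focal gene
#' set, a DE p-value table whose true signals fall inside the focal set, a
#' qPCR Ct table, and the ground truth as JSON.
#'
#' @param simConfig a [simulationConfig()].
#' @param outdir output directory.
#' @param nTrueDE number of true DE signals for the p-value table.
#' @param qpcrShift,qpcrNoiseSd parameters forwarded to [simulateQpcr()].
#' @return invisibly, a named list of the written file paths.
#' @export
runSimulation <- function(simConfig, outdir, nTrueDE = 84L,
                          qpcrShift = 1, qpcrNoiseSd = 0.5) {
    if (!inherits(simConfig, "SimulationConfig"))
        simConfig <- do.call(simulationConfig, simConfig)
    outdir <- .ensureOutdir(outdir)
    sim <- simulateExpression(simConfig)
    paths <- list(
        counts = file.path(outdir, "counts.tsv"),
        sampleMap = file.path(outdir, "sample_map.tsv"),
        geneSets = file.path(outdir, "gene_sets.gmt"),
        dePvalues = file.path(outdir, "de_pvalues.tsv"),
        ctTable = file.path(outdir, "ct_table.tsv"),
        truth = file.path(outdir, "ground_truth.json"))
    writeCounts(sim$counts, paths$counts, paths$sampleMap)
    gsc <- makeGeneSetCollection(
        list(SPERMATOGENESIS_LIKE = sim$truth$focalSet),
        c(SPERMATOGENESIS_LIKE = "synthetic focal gene set"))
    writeGeneSets(gsc, paths$geneSets)
    de <- simulateDEPvalues(simConfig$nGenes,
                            min(nTrueDE, simConfig$nGenes),
                            seed = simConfig$seed)
    .writeTsv(de, paths$dePvalues)
    ct <- simulateQpcr(simConfig$samplesPerCondition,
                       deltaCtShift = qpcrShift, noiseSd = qpcrNoiseSd,
                       seed = simConfig$seed,
                       groups = sim$truth$conditionLabels)
    .writeTsv(ct, paths$ctTable)
    jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(paths)
}

#' Run every stage of the pipeline
#'
#' Runs the network preservation, enrichment and qPCR stages from one
#' configuration and writes a run manifest (parameters, seed, package and R
#' versions, MD5 checksums of the inputs) to \code{outdir}.
#'
#' @param config a [pipelineConfig()] with all input paths set.
#' @return invisibly, a list with the three stage results.
#' @export
runPipeline <- function(config) {
    outdir <- .ensureOutdir(config$outdir)
    res <- list(preservation = runNetworkPreservation(config),
                enrichment = runEnrichment(config),
                qpcr = runQpcr(config))
    inputs <- unlist(config[c("counts", "sampleMap", "geneSets",
                              "dePvalues", "ctTable")])
    manifest <- list(
        package = as.character(utils::packageVersion("CoexPreserve")),
        r_version = R.version.string,
        date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
        config = unclass(config),
        input_md5 = as.list(tools::md5sum(inputs[!is.na(inputs)])))
    jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(res)
}
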