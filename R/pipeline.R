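#' Run the full dual-profile pattern analysis
#'
#' Orchestrates the pipeline end-to-end from a single configuration:
#' QC filtering, log-normalization, variable-gene selection, cluster mean
#' profiles, gene partitioning, full and subsample-averaged profile
#' distances, Ward trees with sister-pair extraction (and optional bootstrap
#' support), population-level similarity calls, pattern classification,
#' intersection with the sister analysis, subsampling robustness, per-pair
#' differential expression for every classified pair, and the RBP pattern
#' report (plus target-category proportions when a target table is given).
#' Every source of randomness derives from `config$seed` via per-stage
#' derived seeds, so stages are independently reproducible and the whole run
#' is deterministic given (inputs, config).
#'
#' @param cells a [CellMatrix-class] with raw counts.
#' @param catalog a [GeneCatalog-class] covering the genes.
#' @param config an [analysisConfig()].
#' @param skipQc skip QC filtering (e.g. for pre-filtered or synthetic data).
#' @param useAllCatalogGenes use the catalog's TF/effector sets directly
#'   instead of intersecting with selected variable genes.
#' @param bootstrap run [bootstrapSupport()] on both trees (slower).
#' @param nBoot bootstrap replicates when `bootstrap = TRUE`.
#' @param rbpTargets optional RBP target table (see [readRbpTargets()]).
#' @param outDir optional directory; when given, every stage's output is
#'   written (distances as TSV, trees as newick, assignments as JSON, the
#'   manifest as JSON).
#' @return list with the per-stage outputs (`qcReport`, `cells`, `means`,
#'   `geneSets`, `dist`, `subsampledDist`, `trees`, `sisters`, `calls`,
#'   `patterns` (population/sister/intersected), `robustness`, `de`,
#'   `rbpReport`, `targetProportions`, `bootstrap`) and a `manifest`.
#' @export
runPipeline <- function(cells, catalog, config = analysisConfig(),
                        skipQc = FALSE, useAllCatalogGenes = FALSE,
                        bootstrap = FALSE, nBoot = 1000L, rbpTargets = NULL,
                        outDir = NULL) {
    t0 <- Sys.time()
    stages <- character()
    note <- function(s) stages <<- c(stages, s)

    qcReport <- NULL
    if (!skipQc) {
        qc <- qcFilter(cells, config)
        cells <- qc$cells; qcReport <- qc$report
        note("qc")
    }
    cells <- normalizeCells(cells, config$normalizeScale); note("normalize")

    variable <- if (useAllCatalogGenes) {
        intersect(names(geneCategory(catalog)), rownames(cells))
    } else {
        selectVariableGenes(cells, config$hvg$nBins, config$hvg$xLow,
                            config$hvg$xHigh, config$hvg$yCutoff)
    }
    note("hvg")
    geneSets <- partitionGenes(catalog, variable); note("partition")

    means <- clusterMeans(cells); note("cluster_means")

    dist <- list(
        effector = profileDistance(means, geneSets$effector, "effector"),
        TF = profileDistance(means, geneSets$TF, "TF"))
    subsampledDist <- list(
        effector = subsampledDistance(means, geneSets$effector,
                                      config$subsample$fraction,
                                      config$subsample$reps,
                                      deriveSeed(config$seed, "sub_eff"),
                                      "effector"),
        TF = subsampledDistance(means, geneSets$TF,
                                config$subsample$fraction,
                                config$subsample$reps,
                                deriveSeed(config$seed, "sub_tf"), "TF"))
    note("distances")

    trees <- lapply(dist, wardTree)
    sisters <- lapply(trees, sisterPairs)
    treeCut <- lapply(trees, cutDendrogram, height = config$wardCutHeight)
    discordance <- treeDistance(trees$effector, trees$TF, metric = "cid")
    note("trees")

    boot <- NULL
    if (bootstrap) {
        boot <- list(
            effector = bootstrapSupport(means, geneSets$effector, nBoot,
                                        deriveSeed(config$seed, "boot_eff"),
                                        multiscale = TRUE,
                                        auThreshold = config$auThreshold,
                                        geneSetTag = "effector"),
            TF = bootstrapSupport(means, geneSets$TF, nBoot,
                                  deriveSeed(config$seed, "boot_tf"),
                                  multiscale = TRUE,
                                  auThreshold = config$auThreshold,
                                  geneSetTag = "TF"))
        note("bootstrap")
    }

    calls <- list(
        effector = similarityCalls(dist$effector, config$similarity$qLow,
                                   config$similarity$qHighTop,
                                   config$similarity$mode),
        TF = similarityCalls(dist$TF, config$similarity$qLow,
                             config$similarity$qHighTop,
                             config$similarity$mode))
    population <- classifyPatterns(calls$effector, calls$TF)
    sister <- sisterPatternAnalysis(trees$effector, trees$TF)
    intersected <- intersectPatterns(population, sister)
    note("patterns")

    robustness <- robustnessCheck(
        means, geneSets$TF, geneSets$effector,
        config$subsample$fraction, config$subsample$reps,
        deriveSeed(config$seed, "robustness"),
        config$similarity$qLow, config$similarity$qHighTop,
        config$similarity$mode)
    note("robustness")

    classified <- patternTable(intersected)
    classified <- classified[classified$pattern != "unclassified", ,
                             drop = FALSE]
    de <- list()
    for (i in seq_len(nrow(classified)))
        de[[classified$pair[i]]] <- findMarkersPair(
            cells, classified$a[i], classified$b[i],
            config$de$minPct, config$de$minDiffPct)
    note("pair_de")

    rbpReport <- NULL
    targetProportions <- NULL
    if (nrow(classified)) {
        rbpReport <- patternSpecificRbps(intersected, de, catalog,
                                         config$de$alpha)
        if (!is.null(rbpTargets))
            targetProportions <- targetCategoryProportions(
                rbpReport$patternSpecific, rbpTargets, catalog)
        note("rbp")
    }

    manifest <- list(
        package = "regpatterns",
        version = as.character(packageVersion("regpatterns")),
        seed = config$seed,
        config = unclass(config),
        input = list(datasetTag = datasetTag(cells),
                     nGenes = nrow(cells), nCells = ncol(cells),
                     nClusters = length(unique(clusterLabels(cells))),
                     countSum = sum(Matrix::colSums(umiCounts(cells)))),
        stages = stages,
        elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

    out <- list(qcReport = qcReport, cells = cells, means = means,
                geneSets = geneSets, dist = dist,
                subsampledDist = subsampledDist, trees = trees,
                sisters = sisters, treeCut = treeCut,
                discordance = discordance, bootstrap = boot, calls = calls,
                patterns = list(population = population, sister = sister,
                                intersected = intersected),
                robustness = robustness, de = de, rbpReport = rbpReport,
                targetProportions = targetProportions, manifest = manifest)

    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeResults(dist$effector, file.path(outDir, "dist_effector.tsv"))
        writeResults(dist$TF, file.path(outDir, "dist_tf.tsv"))
        writeResults(trees$effector, file.path(outDir, "tree_effector.nwk"))
        writeResults(trees$TF, file.path(outDir, "tree_tf.nwk"))
        writeResults(population, file.path(outDir, "patterns_population.json"))
        writeResults(sister, file.path(outDir, "patterns_sister.json"))
        writeResults(intersected,
                     file.path(outDir, "patterns_intersected.json"))
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    out
}
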