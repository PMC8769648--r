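#' Analysis configuration
#'
#' Central container for every fixed constant of the pipeline. Defaults are
#' the reference values used throughout: QC keeps cells with >= 600 UMIs, a
#' UMI/gene ratio >= 1.2, >= 500 detected genes and mitochondrial fraction
#' <= 5%, and genes detected in >= 20 cells and <= 60% of cells;
#' normalization scales to 10,000 counts per cell before `log(1 + x)`;
#' variable genes come from dispersion z-scores over 300 equal-count mean
#' bins with mean window (0.0125, 8) and z cutoff 0.5; similarity calls use
#' the lowest-10% / top-80% rank rule; gene subsampling draws 80% of genes 20
#' times; Ward trees are cut at height 0.42; Jaccard stability uses 80% cell
#' subsampling, 20 repetitions and a 0.6 stability threshold; differential
#' expression uses min.pct 0.10, min.diff.pct 0.25 and alpha 0.05; the
#' identity rule uses >5% expressing cells or mean UMI >2 among expressing
#' cells; NNLS mapping uses each reference cluster's top 20 markers;
#' morphology marking requires >= 4 labelings from >= 4 fish; clades with
#' AU > 0.9 count as strongly supported.
#'
#' @param qc,hvg,similarity,subsample,jaccard,de,identity,morphologyRule
#'   named lists overriding individual fields of the corresponding group.
#' @param normalizeScale,wardCutHeight,nnlsTopKMarkers,auThreshold,seed
#'   scalar overrides.
#' @return a validated nested list of class `"regAnalysisConfig"`.
#' @examples
#' cfg <- analysisConfig(similarity = list(mode = "global"))
#' cfg$similarity$mode
#' @export
analysisConfig <- function(qc = list(), hvg = list(), similarity = list(),
                           subsample = list(), jaccard = list(), de = list(),
                           identity = list(), morphologyRule = list(),
                           normalizeScale = 10000, wardCutHeight = 0.42,
                           nnlsTopKMarkers = 20L, auThreshold = 0.9,
                           seed = 1L) {
    cfg <- list(
        qc = utils::modifyList(list(
            minUmi = 600, minRatioUmiPerGene = 1.2, minCellsPerGene = 20L,
            maxCellFractionPerGene = 0.60, minGenesPerCell = 500L,
            maxMitoFraction = 0.05, mitoPrefix = "mt-"), qc),
        hvg = utils::modifyList(list(
            nBins = 300L, xLow = 0.0125, xHigh = 8, yCutoff = 0.5), hvg),
        normalizeScale = normalizeScale,
        similarity = utils::modifyList(list(
            qLow = 0.10, qHighTop = 0.80, mode = "conditional"), similarity),
        subsample = utils::modifyList(list(fraction = 0.80, reps = 20L), subsample),
        wardCutHeight = wardCutHeight,
        jaccard = utils::modifyList(list(
            fraction = 0.80, reps = 20L, stableThreshold = 0.6), jaccard),
        de = utils::modifyList(list(
            minPct = 0.10, minDiffPct = 0.25, alpha = 0.05), de),
        identity = utils::modifyList(list(
            minPctExpressing = 0.05, minMeanUmiExpressing = 2.0), identity),
        nnlsTopKMarkers = nnlsTopKMarkers,
        morphologyRule = utils::modifyList(list(
            minTimes = 4L, minFish = 4L), morphologyRule),
        auThreshold = auThreshold,
        seed = as.integer(seed))
    validateConfig(cfg)
    class(cfg) <- c("regAnalysisConfig", "list")
    cfg
}

validateConfig <- function(cfg) {
    fr <- c(cfg$subsample$fraction, cfg$jaccard$fraction,
            cfg$similarity$qLow, cfg$similarity$qHighTop)
    if (any(fr <= 0 | fr > 1)) stop("all fractions must lie in (0, 1]")
    if (cfg$similarity$qLow > 1 - cfg$similarity$qHighTop + 1e-9)
        stop("similar and dissimilar zones overlap: need qLow <= 1 - qHighTop")
    if (!cfg$similarity$mode %in% c("conditional", "global"))
        stop("similarity mode must be 'conditional' or 'global'")
    invisible(cfg)
}

#' Serialize / deserialize an analysis configuration as JSON
#' @param cfg a configuration from [analysisConfig()].
#' @param path JSON file path.
#' @return `writeConfig` returns `path` invisibly; `readConfig` the
#'   reconstructed configuration.
#' @export
writeConfig <- function(cfg, path) {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- utils::modifyList(unclass(analysisConfig()), raw)
    validateConfig(cfg)
    class(cfg) <- c("regAnalysisConfig", "list")
    cfg
}
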