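#' @import methods
#' @importFrom stats cor cutree hclust as.dist median mad sd var
#'   quantile rnbinom rlnorm rnorm runif p.adjust wilcox.test pnorm qnorm
#'   dnorm prcomp kmeans setNames
#' @importFrom utils head read.delim write.table packageVersion
#' @importFrom Matrix readMM writeMM t Diagonal sparseMatrix
#' @importFrom jsonlite write_json read_json
#' @importFrom ape write.tree read.tree as.phylo prop.part
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

setOldClass("hclust")

# -- CellMatrix ---------------------------------------------------------------

#' Cell-level UMI count container
#'
#' `CellMatrix` extends [SingleCellExperiment::SingleCellExperiment] and is the
#' raw substrate for every cell-level computation in the package: QC filtering,
#' log-normalization, variable-gene selection, differential expression, the
#' identity-assignment rule and cluster stability. Genes are rows and cells are
#' columns. The raw UMI matrix lives in the `"counts"` assay; after
#' [normalizeCells()] the log-normalized layer lives in `"logcounts"`. Each
#' cell carries its cluster label in `colData(x)$cluster`.
#'
#' Validity requires: finite, integer-valued, non-negative counts; unique
#' gene and cell identifiers; a cluster label for every cell (no `NA`, no
#' empty string); and, when present, a `"logcounts"` assay with the same
#' dimensions as `"counts"`.
#'
#' @aliases CellMatrix-class
#' @seealso [CellMatrix()] the constructor, [readCellMatrix()],
#'   [clusterLabels()], [datasetTag()]
#' @exportClass CellMatrix
setClass("CellMatrix", contains = "SingleCellExperiment")

.validCellMatrix <- function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("'counts' assay is required")
    cts <- SummarizedExperiment::assay(object, "counts")
    vals <- if (methods::is(cts, "sparseMatrix")) cts@x else as.numeric(cts)
    if (length(vals) && (anyNA(vals) || any(!is.finite(vals))))
        msg <- c(msg, "counts must be finite")
    if (length(vals) && any(vals < 0))
        msg <- c(msg, "counts must be non-negative")
    if (length(vals) && any(vals != floor(vals)))
        msg <- c(msg, "counts must be integer-valued (UMIs)")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "cell ids must be present and unique")
    cl <- SummarizedExperiment::colData(object)$cluster
    if (is.null(cl)) {
        msg <- c(msg, "colData(x)$cluster is required (one label per cell)")
    } else if (anyNA(cl) || any(!nzchar(as.character(cl)))) {
        msg <- c(msg, "cluster labels must be non-missing, non-empty strings")
    }
    if ("logcounts" %in% SummarizedExperiment::assayNames(object)) {
        if (!identical(dim(SummarizedExperiment::assay(object, "logcounts")),
                       dim(cts)))
            msg <- c(msg, "logcounts must have the same dimensions as counts")
    }
    if (length(msg)) msg else TRUE
}
setValidity("CellMatrix", .validCellMatrix)

# -- GeneCatalog --------------------------------------------------------------

#' Gene regulatory-category catalog
#'
#' Maps every gene to exactly one primary regulatory category: `"TF"`
#' (transcription factor), `"effector"` (terminal-function gene: receptor,
#' ion channel, transporter, synaptic protein, neuropeptide, ...), `"RBP"`
#' (RNA-binding protein) or `"other"`. The TF / effector / RBP sets are
#' pairwise disjoint by construction. Optional annotations carry an effector
#' subcategory and an RBP functional class.
#'
#' @slot category named character vector, gene id -> category.
#' @slot effectorSubcategory named character vector (optional annotation).
#' @slot rbpFunction named character vector (optional annotation).
#' @aliases GeneCatalog-class
#' @seealso [GeneCatalog()], [readGeneCatalog()], [tfGenes()],
#'   [effectorGenes()], [rbpGenes()], [partitionGenes()]
#' @exportClass GeneCatalog
setClass("GeneCatalog",
    representation(category = "character",
                   effectorSubcategory = "character",
                   rbpFunction = "character"))

.geneCategories <- c("TF", "effector", "RBP", "other")

setValidity("GeneCatalog", function(object) {
    msg <- character()
    if (is.null(names(object@category)) || anyDuplicated(names(object@category)))
        msg <- c(msg, "category must be named by unique gene ids")
    if (!all(object@category %in% .geneCategories))
        msg <- c(msg, sprintf("categories must be one of: %s",
                              paste(.geneCategories, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

# -- ClusterMeanMatrix --------------------------------------------------------

#' Cluster-by-gene mean expression profiles
#'
#' Holds the per-cluster arithmetic mean expression profile (clusters as rows,
#' genes as columns) that is the unit of all distance computations, tree
#' building and NNLS decompositions. Values are non-negative and finite (mean
#' log-normalized expression from [clusterMeans()], or relative expression
#' from the synthetic generator). Optional per-cluster metadata (brain region,
#' neurotransmitter / neuromodulator class) rides along in `meta`.
#'
#' @slot means numeric matrix, clusters x genes, with unique dimnames.
#' @slot meta data.frame with one row per cluster (possibly 0 columns).
#' @aliases ClusterMeanMatrix-class
#' @seealso [ClusterMeanMatrix()], [clusterMeans()], [profileDistance()]
#' @exportClass ClusterMeanMatrix
setClass("ClusterMeanMatrix",
    representation(means = "matrix", meta = "data.frame"))

setValidity("ClusterMeanMatrix", function(object) {
    msg <- character()
    m <- object@means
    if (!is.numeric(m)) msg <- c(msg, "means must be numeric")
    if (anyNA(m) || any(!is.finite(m))) msg <- c(msg, "means must be finite")
    else if (any(m < 0)) msg <- c(msg, "means must be non-negative")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        msg <- c(msg, "cluster ids (rownames) must be present and unique")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
        msg <- c(msg, "gene ids (colnames) must be present and unique")
    if (nrow(object@meta) && nrow(object@meta) != nrow(m))
        msg <- c(msg, "meta must have one row per cluster")
    if (length(msg)) msg else TRUE
})

# -- PairwiseDistance ---------------------------------------------------------

#' Correlation-based pairwise cluster distance
#'
#' Symmetric matrix of `(1 - Pearson r) / 2` distances between cluster mean
#' profiles over one gene set (TF, effector, RBP or custom). Entries are in
#' `[0, 1]` with a zero diagonal. Produced by [profileDistance()] or, as a
#' subsample average, by [subsampledDistance()].
#'
#' @slot d symmetric numeric matrix over cluster ids.
#' @slot geneSetTag one of `"TF"`, `"effector"`, `"RBP"`, `"custom"`.
#' @slot nGenesUsed number of genes the distance was computed over.
#' @aliases PairwiseDistance-class
#' @exportClass PairwiseDistance
setClass("PairwiseDistance",
    representation(d = "matrix", geneSetTag = "character",
                   nGenesUsed = "integer"))

setValidity("PairwiseDistance", function(object) {
    d <- object@d
    msg <- character()
    if (nrow(d) != ncol(d)) msg <- c(msg, "distance matrix must be square")
    if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
        msg <- c(msg, "distance matrix must carry matching cluster-id dimnames")
    if (anyNA(d) || any(!is.finite(d))) msg <- c(msg, "distances must be finite")
    else {
        if (max(abs(d - t(d))) > 1e-8) msg <- c(msg, "distance must be symmetric")
        if (any(abs(diag(d)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
        if (any(d < -1e-12) || any(d > 1 + 1e-12))
            msg <- c(msg, "distances must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

# -- SimilarityCalls ----------------------------------------------------------

#' Population-level similarity calls for cluster pairs
#'
#' For every unordered cluster pair, the rank-based call
#' (`similar` / `dissimilar` / `intermediate`) derived from one
#' [PairwiseDistance], together with the rank statistics that reproduce it:
#' the pair's ascending competition rank within its reference set and the
#' reference-set size. See [similarityCalls()] for the calling rule.
#'
#' @slot calls data.frame with columns `pair`, `a`, `b`, `d`, `rank`,
#'   `refSize`, `call`.
#' @slot geneSetTag gene set the underlying distance was computed on.
#' @slot mode `"conditional"` or `"global"` reference-set mode.
#' @slot qLow,qHighTop the quantile parameters used.
#' @aliases SimilarityCalls-class
#' @exportClass SimilarityCalls
setClass("SimilarityCalls",
    representation(calls = "data.frame", geneSetTag = "character",
                   mode = "character", qLow = "numeric", qHighTop = "numeric"))

setValidity("SimilarityCalls", function(object) {
    msg <- character()
    need <- c("pair", "a", "b", "d", "rank", "refSize", "call")
    if (!all(need %in% names(object@calls)))
        msg <- c(msg, paste("calls must have columns:", paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(object@calls$pair))
            msg <- c(msg, "exactly one call per pair is required")
        if (!all(object@calls$call %in% c("similar", "dissimilar", "intermediate")))
            msg <- c(msg, "calls must be similar/dissimilar/intermediate")
    }
    if (length(msg)) msg else TRUE
})

# -- PatternAssignment --------------------------------------------------------

#' Matched / convergent / divergent pattern assignment
#'
#' One pattern per unordered cluster pair, with provenance recording which
#' strategy produced it: `"population"` (rank-based similarity calls on both
#' gene sets), `"sister"` (cherry co-occurrence in the two Ward trees) or
#' `"intersected"` (agreement of the two). Patterns are mutually exclusive by
#' construction:
#' * `matched` -- similar in both effector-gene and TF profiles;
#' * `convergent` -- similar in effector genes, dissimilar in TFs;
#' * `divergent` -- similar in TFs, dissimilar in effector genes;
#' * `unclassified` -- everything else (including any intermediate call).
#'
#' @slot assignments data.frame with columns `pair`, `a`, `b`, `pattern`
#'   and (for population calls) `effCall`, `tfCall`.
#' @slot provenance `"population"`, `"sister"` or `"intersected"`.
#' @aliases PatternAssignment-class
#' @seealso [classifyPatterns()], [sisterPatternAnalysis()],
#'   [intersectPatterns()]
#' @exportClass PatternAssignment
setClass("PatternAssignment",
    representation(assignments = "data.frame", provenance = "character"))

.patternLevels <- c("matched", "convergent", "divergent", "unclassified")

setValidity("PatternAssignment", function(object) {
    msg <- character()
    a <- object@assignments
    if (!all(c("pair", "a", "b", "pattern") %in% names(a)))
        msg <- c(msg, "assignments needs columns pair, a, b, pattern")
    else {
        if (anyDuplicated(a$pair)) msg <- c(msg, "one pattern per pair")
        if (!all(a$pattern %in% .patternLevels))
            msg <- c(msg, "patterns must be matched/convergent/divergent/unclassified")
    }
    if (!object@provenance %in% c("population", "sister", "intersected"))
        msg <- c(msg, "provenance must be population/sister/intersected")
    if (length(msg)) msg else TRUE
})

# -- SyntheticTruth -----------------------------------------------------------

#' Ground truth for the synthetic-data generator
#'
#' Parameters of the planted-pair simulation plus the planted pattern labels;
#' the ground truth against which recovery is scored. The defaults are the
#' package's reference simulation conditions: 30 clusters, 3 planted pairs per
#' pattern, 500 TF + 500 effector + 100 RBP + 100 other genes, within-pair
#' profile correlation 0.95 on the log scale, background correlation 0,
#' 200 cells per cluster, negative-binomial size 2, mean library size 2000
#' UMIs (lognormal, sdlog 0.3).
#'
#' @slot nClusters number of clusters.
#' @slot genesPerCategory named integer vector (TF, effector, RBP, other).
#' @slot plantedPairs data.frame with columns `a`, `b`, `pattern`; planted
#'   pairs are disjoint (no cluster in two pairs).
#' @slot rhoSimilar target within-pair Pearson correlation, log scale.
#' @slot rhoBackground target correlation between unrelated clusters.
#' @slot cellsPerCluster cells simulated per cluster.
#' @slot nbDispersion negative-binomial size parameter (variance
#'   `mu + mu^2/size`); large values approach Poisson.
#' @slot librarySizeMean mean UMIs per cell.
#' @slot librarySizeSdLog lognormal sdlog of library size (0 = constant).
#' @slot logSd sd of per-cluster log-expression deviations.
#' @slot rbpOffset fixed log-scale offset planted on designated RBP genes of
#'   divergent pairs (must be >= 1).
#' @slot nRbpDiffGenes number of offset RBP genes per divergent pair.
#' @slot seed integer seed; generation is a pure function of it.
#' @aliases SyntheticTruth-class
#' @seealso [syntheticTruth()], [generateClusterMeans()], [generateCounts()]
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
    representation(nClusters = "integer", genesPerCategory = "integer",
                   plantedPairs = "data.frame", rhoSimilar = "numeric",
                   rhoBackground = "numeric", cellsPerCluster = "integer",
                   nbDispersion = "numeric", librarySizeMean = "numeric",
                   librarySizeSdLog = "numeric", logSd = "numeric",
                   rbpOffset = "numeric", nRbpDiffGenes = "integer",
                   seed = "integer"))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    pp <- object@plantedPairs
    if (nrow(pp)) {
        if (!all(c("a", "b", "pattern") %in% names(pp)))
            msg <- c(msg, "plantedPairs needs columns a, b, pattern")
        else {
            ids <- c(pp$a, pp$b)
            if (anyDuplicated(ids))
                msg <- c(msg, "planted pairs must be disjoint")
            if (!all(pp$pattern %in% c("matched", "convergent", "divergent")))
                msg <- c(msg, "planted patterns must be matched/convergent/divergent")
            if (2L * nrow(pp) > object@nClusters)
                msg <- c(msg, "2 x planted pairs must be <= nClusters")
        }
    }
    if (!all(c("TF", "effector", "RBP", "other") %in% names(object@genesPerCategory)))
        msg <- c(msg, "genesPerCategory needs TF, effector, RBP, other")
    if (object@rhoBackground < 0 || object@rhoBackground >= object@rhoSimilar)
        msg <- c(msg, "need 0 <= rhoBackground < rhoSimilar")
    if (object@rhoSimilar <= 0 || object@rhoSimilar > 1)
        msg <- c(msg, "rhoSimilar must be in (0, 1]")
    if (object@nbDispersion <= 0)
        msg <- c(msg, "nbDispersion must be > 0")
    if (object@librarySizeMean <= 0)
        msg <- c(msg, "librarySizeMean must be > 0")
    if (object@rbpOffset < 1)
        msg <- c(msg, "rbpOffset must be >= 1 (log scale)")
    nDiv <- if (nrow(pp)) sum(pp$pattern == "divergent") else 0L
    if (nDiv * object@nRbpDiffGenes > object@genesPerCategory[["RBP"]])
        msg <- c(msg, "not enough RBP genes for the divergent offset subsets")
    if (length(msg)) msg else TRUE
})
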