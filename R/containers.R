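#' Construct a CellMatrix
#'
#' @param counts genes x cells matrix of UMI counts (dense or
#'   `Matrix::sparseMatrix`), with gene ids as rownames and cell ids as
#'   colnames.
#' @param clusters character vector of cluster labels, one per cell (named or
#'   in column order).
#' @param normalized optional log-normalized layer of identical shape.
#' @param datasetTag free-text tag identifying the dataset.
#' @return a validated [CellMatrix-class] object.
#' @examples
#' cts <- matrix(rpois(40, 2), nrow = 4,
#'               dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
#' cm <- CellMatrix(cts, rep(c("A", "B"), each = 5))
#' clusterLabels(cm)
#' @export
CellMatrix <- function(counts, clusters, normalized = NULL,
                       datasetTag = "dataset") {
    if (length(clusters) != ncol(counts))
        stop("need exactly one cluster label per cell (",
             length(clusters), " labels for ", ncol(counts), " cells)")
    if (!is.null(names(clusters)) && !is.null(colnames(counts)))
        clusters <- clusters[colnames(counts)]
    assays <- list(counts = counts)
    if (!is.null(normalized)) {
        if (!identical(dim(normalized), dim(counts)))
            stop("normalized layer must match counts dimensions")
        assays$logcounts <- normalized
    }
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = assays,
        colData = S4Vectors::DataFrame(cluster = as.character(clusters),
                                       row.names = colnames(counts)))
    S4Vectors::metadata(sce)$datasetTag <- datasetTag
    methods::validObject(out <- methods::new("CellMatrix", sce))
    out
}

#' @rdname accessors
#' @param x a `CellMatrix`.
#' @aliases clusterLabels,CellMatrix-method
#' @export
setMethod("clusterLabels", "CellMatrix", function(x)
    setNames(as.character(SummarizedExperiment::colData(x)$cluster), colnames(x)))

#' @rdname accessors
#' @param x a `CellMatrix`.
#' @export
setMethod("datasetTag", "CellMatrix", function(x)
    S4Vectors::metadata(x)$datasetTag %||% "dataset")

umiCounts <- function(x) SummarizedExperiment::assay(x, "counts")

logNorm <- function(x) {
    if (!"logcounts" %in% SummarizedExperiment::assayNames(x))
        stop("no log-normalized layer present; run normalizeCells() first")
    SummarizedExperiment::assay(x, "logcounts")
}

hasLogNorm <- function(x) "logcounts" %in% SummarizedExperiment::assayNames(x)

setMethod("show", "CellMatrix", function(object) {
    cl <- clusterLabels(object)
    cat("CellMatrix '", datasetTag(object), "': ",
        nrow(object), " genes x ", ncol(object), " cells, ",
        length(unique(cl)), " clusters",
        if (hasLogNorm(object)) " (log-normalized)" else "", "\n", sep = "")
})

# -- GeneCatalog --------------------------------------------------------------

#' Construct a GeneCatalog
#'
#' Unknown category strings are mapped to `"other"` with a warning; a gene
#' listed twice with conflicting categories is an error.
#'
#' @param geneIds character vector of gene ids.
#' @param category character vector of primary categories
#'   (`TF`/`effector`/`RBP`/`other`), recycled checks not applied.
#' @param effectorSubcategory,rbpFunction optional named annotation vectors.
#' @return a validated [GeneCatalog-class].
#' @examples
#' gc <- GeneCatalog(c("sox2", "gria1a", "rbfox1", "actb1"),
#'                   c("TF", "effector", "RBP", "other"))
#' tfGenes(gc)
#' @export
GeneCatalog <- function(geneIds, category,
                        effectorSubcategory = character(),
                        rbpFunction = character()) {
    if (length(geneIds) != length(category))
        stop("geneIds and category must have equal length")
    category <- as.character(category)
    if (anyDuplicated(geneIds)) {
        agg <- split(category, geneIds)
        bad <- names(agg)[vapply(agg, function(v) length(unique(v)) > 1L, TRUE)]
        if (length(bad))
            stop("conflicting categories for gene(s): ",
                 paste(head(bad, 5L), collapse = ", "))
        keep <- !duplicated(geneIds)
        geneIds <- geneIds[keep]; category <- category[keep]
    }
    unknown <- !category %in% .geneCategories
    if (any(unknown)) {
        warning(sum(unknown), " gene(s) with unknown category mapped to 'other'")
        category[unknown] <- "other"
    }
    methods::new("GeneCatalog",
                 category = setNames(category, geneIds),
                 effectorSubcategory = effectorSubcategory,
                 rbpFunction = rbpFunction)
}

#' @rdname accessors
#' @param x a `GeneCatalog`.
#' @export
setMethod("geneCategory", "GeneCatalog", function(x) x@category)

#' @rdname accessors
#' @param x a `GeneCatalog`.
#' @export
setMethod("tfGenes", "GeneCatalog", function(x)
    names(x@category)[x@category == "TF"])

#' @rdname accessors
#' @param x a `GeneCatalog`.
#' @export
setMethod("effectorGenes", "GeneCatalog", function(x)
    names(x@category)[x@category == "effector"])

#' @rdname accessors
#' @param x a `GeneCatalog`.
#' @export
setMethod("rbpGenes", "GeneCatalog", function(x)
    names(x@category)[x@category == "RBP"])

setMethod("show", "GeneCatalog", function(object) {
    tab <- table(factor(object@category, levels = .geneCategories))
    cat("GeneCatalog: ", length(object@category), " genes (",
        paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")\n",
        sep = "")
})

# -- ClusterMeanMatrix --------------------------------------------------------

#' Construct a ClusterMeanMatrix
#'
#' @param means numeric matrix, clusters x genes, with dimnames.
#' @param meta optional per-cluster data.frame (region, neurotransmitter
#'   class, ...), rownames matching cluster ids.
#' @return a validated [ClusterMeanMatrix-class].
#' @export
ClusterMeanMatrix <- function(means, meta = NULL) {
    if (is.null(meta)) meta <- data.frame(row.names = rownames(means))
    methods::new("ClusterMeanMatrix", means = means, meta = meta)
}

#' @rdname accessors
#' @param x a `ClusterMeanMatrix`.
#' @export
setMethod("profileMatrix", "ClusterMeanMatrix", function(x) x@means)

#' @rdname accessors
#' @param x a `ClusterMeanMatrix`.
#' @export
setMethod("clusterMeta", "ClusterMeanMatrix", function(x) x@meta)

setMethod("show", "ClusterMeanMatrix", function(object) {
    cat("ClusterMeanMatrix: ", nrow(object@means), " clusters x ",
        ncol(object@means), " genes\n", sep = "")
})

# -- PairwiseDistance ---------------------------------------------------------

#' @rdname accessors
#' @param x a `PairwiseDistance`.
#' @export
setMethod("distanceMatrix", "PairwiseDistance", function(x) x@d)

#' @rdname accessors
#' @param x a `PairwiseDistance` or `SimilarityCalls`.
#' @export
setMethod("geneSetTag", "PairwiseDistance", function(x) x@geneSetTag)

setMethod("show", "PairwiseDistance", function(object) {
    cat("PairwiseDistance [", object@geneSetTag, "]: ",
        nrow(object@d), " clusters, ", object@nGenesUsed, " genes, range [",
        sprintf("%.3f", min(object@d[upper.tri(object@d)])), ", ",
        sprintf("%.3f", max(object@d)), "]\n", sep = "")
})

# -- SimilarityCalls / PatternAssignment --------------------------------------

#' @rdname accessors
#' @param x a `SimilarityCalls`.
#' @export
setMethod("callTable", "SimilarityCalls", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("geneSetTag", "SimilarityCalls", function(x) x@geneSetTag)

setMethod("show", "SimilarityCalls", function(object) {
    tab <- table(factor(object@calls$call,
                        levels = c("similar", "dissimilar", "intermediate")))
    cat("SimilarityCalls [", object@geneSetTag, ", ", object@mode, "]: ",
        paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n",
        sep = "")
})

#' @rdname accessors
#' @param x a `PatternAssignment`.
#' @export
setMethod("patternTable", "PatternAssignment", function(x) x@assignments)

#' @rdname accessors
#' @param x a `PatternAssignment`.
#' @export
setMethod("provenance", "PatternAssignment", function(x) x@provenance)

setMethod("show", "PatternAssignment", function(object) {
    tab <- table(factor(object@assignments$pattern, levels = .patternLevels))
    cat("PatternAssignment (", object@provenance, "): ",
        paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n",
        sep = "")
})

#' @rdname accessors
#' @param x a `SyntheticTruth`.
#' @export
setMethod("plantedPairs", "SyntheticTruth", function(x) x@plantedPairs)

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth: ", object@nClusters, " clusters, ",
        nrow(object@plantedPairs), " planted pairs, rho ",
        object@rhoSimilar, " vs ", object@rhoBackground,
        " (seed ", object@seed, ")\n", sep = "")
})
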