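#' Quality-control filtering of cells and genes
#'
#' Removes low-quality cells and uninformative genes from the raw UMI matrix.
#' A cell is removed when any of these holds (strict inequalities: "less
#' than" removes, the boundary survives): total UMIs < `minUmi`; UMI /
#' detected-gene ratio < `minRatioUmiPerGene`; detected genes <
#' `minGenesPerCell`; mitochondrial UMI fraction > `maxMitoFraction`
#' (mitochondrial genes are identified by the configurable id prefix,
#' default `"mt-"`). On the retained cells, a gene is removed when it is
#' detected in fewer than `minCellsPerGene` cells or in more than
#' `maxCellFractionPerGene` of all cells.
#'
#' @param x a [CellMatrix-class] with raw counts.
#' @param config an [analysisConfig()]; only the `qc` group is used.
#' @return list with `cells` (the filtered [CellMatrix-class]) and `report`
#'   (cells/genes removed per rule and retained dimensions).
#' @export
qcFilter <- function(x, config = analysisConfig()) {
    qc <- config$qc
    cts <- umiCounts(x)
    umi <- Matrix::colSums(cts)
    genesDetected <- Matrix::colSums(cts > 0)
    ratio <- ifelse(genesDetected > 0, umi / genesDetected, 0)
    mito <- grepl(paste0("^", qc$mitoPrefix), rownames(cts), ignore.case = TRUE)
    mitoFrac <- if (any(mito))
        Matrix::colSums(cts[mito, , drop = FALSE]) / pmax(umi, 1) else rep(0, ncol(cts))

    lowUmi <- umi < qc$minUmi
    lowRatio <- ratio < qc$minRatioUmiPerGene
    fewGenes <- genesDetected < qc$minGenesPerCell
    highMito <- mitoFrac > qc$maxMitoFraction
    keepCell <- !(lowUmi | lowRatio | fewGenes | highMito)
    if (!any(keepCell)) stop("QC removed every cell")

    sub <- cts[, keepCell, drop = FALSE]
    nCells <- Matrix::rowSums(sub > 0)
    rare <- nCells < qc$minCellsPerGene
    ubiquitous <- nCells > qc$maxCellFractionPerGene * ncol(sub)
    keepGene <- !(rare | ubiquitous)
    if (!any(keepGene)) stop("QC removed every gene")

    out <- CellMatrix(sub[keepGene, , drop = FALSE],
                      clusterLabels(x)[keepCell], datasetTag = datasetTag(x))
    report <- list(
        cellsRemoved = list(lowUmi = sum(lowUmi), lowRatio = sum(lowRatio),
                            fewGenes = sum(fewGenes), highMito = sum(highMito),
                            total = sum(!keepCell)),
        genesRemoved = list(rare = sum(rare), ubiquitous = sum(ubiquitous),
                            total = sum(!keepGene)),
        retained = c(genes = sum(keepGene), cells = sum(keepCell)))
    list(cells = out, report = report)
}

#' Log-normalize counts per cell
#'
#' Per cell: `log(1 + scale * count / cellTotal)` (natural log, counts per
#' `scale`), stored as the `"logcounts"` layer; the raw counts are untouched.
#'
#' @param x a [CellMatrix-class].
#' @param scale counts-per-cell scale factor (default 10,000).
#' @return the [CellMatrix-class] with a `"logcounts"` assay.
#' @export
normalizeCells <- function(x, scale = 10000) {
    cts <- umiCounts(x)
    totals <- Matrix::colSums(cts)
    if (any(totals == 0))
        stop("cell(s) with zero total counts: ",
             paste(head(colnames(cts)[totals == 0], 5L), collapse = ", "))
    ln <- if (methods::is(cts, "sparseMatrix")) {
        log1p(cts %*% Matrix::Diagonal(x = scale / totals))
    } else {
        log1p(sweep(cts, 2L, totals / scale, "/"))
    }
    dimnames(ln) <- dimnames(cts)
    SummarizedExperiment::assay(x, "logcounts") <- ln
    methods::validObject(x)
    x
}

#' Select highly variable genes by dispersion binning
#'
#' Computes, per gene, the mean and dispersion of the back-transformed
#' normalized values (`expm1` of logcounts; mean reported on the
#' `log(mean + 1)` scale, dispersion as `log(variance / mean)`), bins genes
#' into `nBins` equal-count bins of mean expression, and z-scores the
#' dispersion within each bin using the bin median and median absolute
#' deviation. A gene is selected when its mean lies strictly inside
#' `(xLow, xHigh)` and its dispersion z-score is at least `yCutoff`.
#'
#' @param x a normalized [CellMatrix-class].
#' @param nBins number of equal-count mean bins (reduced with a warning when
#'   there are fewer genes than bins).
#' @param xLow,xHigh open interval for the mean (log scale).
#' @param yCutoff minimum within-bin dispersion z-score.
#' @return character vector of selected gene ids.
#' @export
selectVariableGenes <- function(x, nBins = 300L, xLow = 0.0125, xHigh = 8,
                                yCutoff = 0.5) {
    e <- expm1(logNorm(x))
    mu <- Matrix::rowMeans(e)
    v <- rowVars(e)
    disp <- ifelse(mu > 0 & v > 0, log(v / mu), -Inf)
    gm <- log1p(mu)
    usable <- is.finite(disp)
    nGenes <- sum(usable)
    if (nGenes < 2L) return(character())
    if (nGenes < nBins) {
        nBins <- max(1L, nGenes %/% 5L)
        warning("fewer genes than bins; using ", nBins, " bins")
    }
    bin <- rep(NA_integer_, length(mu))
    bin[usable] <- ceiling(rank(gm[usable], ties.method = "first") /
                               (nGenes / nBins))
    z <- rep(NA_real_, length(mu))
    for (b in unique(bin[usable])) {
        idx <- which(bin == b)
        d <- disp[idx]
        center <- median(d)
        spread <- mad(d)
        if (!is.finite(spread) || spread == 0) spread <- max(sd(d), 1e-12)
        z[idx] <- (d - center) / spread
    }
    sel <- usable & gm > xLow & gm < xHigh & !is.na(z) & z >= yCutoff
    rownames(x)[sel]
}

#' Mean log-normalized expression per cluster
#'
#' Entry `(k, g)` is the arithmetic mean of the normalized expression of gene
#' `g` over cells labelled `k`. Invariant to cell order.
#'
#' @param x a normalized [CellMatrix-class].
#' @param genes optional gene subset; an error lists any requested gene that
#'   is absent from the matrix.
#' @param meta optional per-cluster metadata data.frame.
#' @return a [ClusterMeanMatrix-class] (clusters x genes).
#' @export
clusterMeans <- function(x, genes = NULL, meta = NULL) {
    ln <- logNorm(x)
    if (!is.null(genes)) {
        missing <- setdiff(genes, rownames(ln))
        if (length(missing))
            stop("gene(s) absent from matrix: ",
                 paste(head(missing, 10L), collapse = ", "))
        ln <- ln[genes, , drop = FALSE]
    }
    cl <- clusterLabels(x)
    ids <- sort(unique(cl))
    ind <- Matrix::sparseMatrix(
        i = seq_along(cl), j = match(cl, ids),
        x = 1 / as.vector(table(cl)[cl]),
        dims = c(length(cl), length(ids)))
    m <- t(as.matrix(ln %*% ind))
    dimnames(m) <- list(ids, rownames(ln))
    if (!is.null(meta)) meta <- meta[ids, , drop = FALSE]
    ClusterMeanMatrix(m, meta)
}

#' Partition variable genes by regulatory category
#'
#' Intersects a variable-gene list with the catalog's TF, effector and RBP
#' sets. Every variable gene must be present in the catalog; an empty TF or
#' effector intersection is an error because downstream profile distances
#' would be undefined.
#'
#' @param catalog a [GeneCatalog-class].
#' @param variableGenes character vector of gene ids.
#' @return list with elements `TF`, `effector`, `RBP` (disjoint character
#'   vectors).
#' @export
partitionGenes <- function(catalog, variableGenes) {
    domain <- names(geneCategory(catalog))
    missing <- setdiff(variableGenes, domain)
    if (length(missing))
        stop("variable gene(s) absent from catalog: ",
             paste(head(missing, 10L), collapse = ", "))
    out <- list(TF = intersect(variableGenes, tfGenes(catalog)),
                effector = intersect(variableGenes, effectorGenes(catalog)),
                RBP = intersect(variableGenes, rbpGenes(catalog)))
    if (!length(out$TF) || !length(out$effector))
        stop("empty TF or effector gene set: profile distances undefined")
    out
}

#' Correlation-based profile distance between clusters
#'
#' `d(i, j) = (1 - r(i, j)) / 2` where `r` is the sample Pearson correlation
#' of the two clusters' mean profiles across the gene set; `d` is symmetric,
#' has a zero diagonal and lies in `[0, 1]`. A cluster with zero variance
#' over the gene set makes the correlation undefined and raises an error
#' naming the cluster -- the value is never imputed.
#'
#' @param means a [ClusterMeanMatrix-class].
#' @param genes gene set (>= 3 genes) to compute the profile over.
#' @param geneSetTag tag stored on the result.
#' @return a [PairwiseDistance-class].
#' @export
profileDistance <- function(means, genes = colnames(profileMatrix(means)),
                            geneSetTag = "custom") {
    m <- profileMatrix(means)
    if (nrow(m) < 2L) stop("need >= 2 clusters for a distance")
    missing <- setdiff(genes, colnames(m))
    if (length(missing))
        stop("gene(s) absent from cluster means: ",
             paste(head(missing, 10L), collapse = ", "))
    if (length(genes) < 3L) stop("need >= 3 genes for a profile correlation")
    sub <- m[, genes, drop = FALSE]
    vars <- apply(sub, 1L, var)
    if (any(vars == 0))
        stop("zero-variance profile for cluster(s): ",
             paste(rownames(sub)[vars == 0], collapse = ", "))
    d <- (1 - cor(t(sub))) / 2
    d[] <- pmin(pmax(d, 0), 1)
    diag(d) <- 0
    d <- (d + t(d)) / 2
    methods::new("PairwiseDistance", d = d, geneSetTag = geneSetTag,
                 nGenesUsed = length(genes))
}

#' Subsample-averaged profile distance
#'
#' Draws `floor(fraction * |genes|)` genes without replacement `reps` times,
#' computes [profileDistance()] on each draw, and returns the elementwise
#' mean distance matrix. Deterministic given `seed`. With `fraction = 1` the
#' result equals the full-gene distance exactly.
#'
#' @inheritParams profileDistance
#' @param fraction fraction of genes per draw, in (0, 1].
#' @param reps number of subsampling repetitions.
#' @param seed integer seed.
#' @return a [PairwiseDistance-class] (the subsample average).
#' @export
subsampledDistance <- function(means, genes, fraction = 0.8, reps = 20L,
                               seed = 1L, geneSetTag = "custom") {
    if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
    nSub <- as.integer(floor(fraction * length(genes)))
    if (nSub < 3L) stop("subsample would have fewer than 3 genes")
    withSeed(seed, {
        acc <- NULL
        for (r in seq_len(reps)) {
            g <- sample(genes, nSub)
            d <- distanceMatrix(profileDistance(means, g, geneSetTag))
            acc <- if (is.null(acc)) d else acc + d
        }
        methods::new("PairwiseDistance", d = acc / reps,
                     geneSetTag = geneSetTag, nGenesUsed = nSub)
    })
}
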