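#' Non-negative least squares by the Lawson-Hanson active-set algorithm
#'
#' Solves `argmin ||A x - b||^2` subject to `x >= 0`. The solution satisfies
#' the Karush-Kuhn-Tucker conditions: the gradient components of the active
#' (zero) coefficients are non-negative and those of the positive
#' coefficients vanish, both to within `1e-8` on well-scaled problems.
#'
#' @param A design matrix (>= 1 column, finite entries).
#' @param b response vector.
#' @param maxIter iteration cap (default `10 * ncol(A)`); exceeding it raises
#'   a convergence error carrying the current iterate.
#' @return list with `x` (non-negative coefficients), `fitted`,
#'   `residualNorm` (`||A x - b||`), `gradient` (`A'(b - A x)`) and
#'   `iterations`.
#' @export
nnlsSolve <- function(A, b, maxIter = NULL) {
    A <- as.matrix(A)
    if (!ncol(A)) stop("design must have >= 1 column")
    if (anyNA(A) || any(!is.finite(A)) || anyNA(b) || any(!is.finite(b)))
        stop("non-finite values in the NNLS inputs")
    if (length(b) != nrow(A)) stop("length(b) must equal nrow(A)")
    n <- ncol(A)
    if (is.null(maxIter)) maxIter <- 10L * n
    x <- numeric(n)
    passive <- logical(n)
    tol <- 1e-10 * max(abs(A)) * max(1, max(abs(b)))
    w <- drop(crossprod(A, b - A %*% x))
    iter <- 0L
    while (any(!passive) && any(w[!passive] > tol)) {
        iter <- iter + 1L
        if (iter > maxIter)
            stop("NNLS failed to converge; iterate: ",
                 paste(signif(x, 6), collapse = ", "))
        j <- which(!passive)[which.max(w[!passive])]
        passive[j] <- TRUE
        repeat {
            z <- numeric(n)
            z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
            z[passive][is.na(z[passive])] <- 0
            if (all(z[passive] > tol)) break
            inPass <- which(passive & z <= tol)
            ratio <- x[inPass] / (x[inPass] - z[inPass])
            ratio[!is.finite(ratio)] <- 0
            alpha <- min(ratio)
            x <- x + alpha * (z - x)
            passive[passive & x <= tol] <- FALSE
            x[!passive] <- 0
        }
        x <- z
        w <- drop(crossprod(A, b - A %*% x))
    }
    fitted <- drop(A %*% x)
    list(x = x, fitted = fitted,
         residualNorm = sqrt(sum((fitted - b)^2)),
         gradient = drop(crossprod(A, b - fitted)),
         iterations = iter)
}

#' Map query clusters onto reference clusters by NNLS
#'
#' Decomposes each query cluster's mean profile over the reference clusters'
#' top marker genes as a non-negative mixture of the reference cluster
#' profiles. The marker genes are intersected with both matrices; fewer than
#' 3 surviving genes for any reference cluster's marker set is an error.
#'
#' @param query,reference [ClusterMeanMatrix-class] objects.
#' @param markers named list (reference cluster -> marker gene ids), e.g.
#'   from [findAllClusterMarkers()] + [topMarkers()], or one character
#'   vector used as a common gene set.
#' @param k cap on markers used per reference cluster.
#' @return list with `coefficients` (query x reference matrix),
#'   `residualNorms` (per query) and `genesUsed`.
#' @export
nnlsClusterMapping <- function(query, reference, markers, k = 20L) {
    qm <- profileMatrix(query); rm_ <- profileMatrix(reference)
    if (!is.list(markers)) markers <- list(all = markers)
    markers <- lapply(markers, function(g)
        head(intersect(intersect(g, colnames(qm)), colnames(rm_)), k))
    tooFew <- names(markers)[vapply(markers, length, 1L) < 3L]
    if (length(tooFew))
        stop("fewer than 3 usable marker genes for: ",
             paste(tooFew, collapse = ", "))
    genes <- unique(unlist(markers))
    A <- t(rm_[, genes, drop = FALSE])   # genes x reference clusters
    fits <- lapply(rownames(qm), function(q) nnlsSolve(A, qm[q, genes]))
    coef <- do.call(rbind, lapply(fits, `[[`, "x"))
    dimnames(coef) <- list(rownames(qm), rownames(rm_))
    list(coefficients = coef,
         residualNorms = setNames(vapply(fits, `[[`, 1.0, "residualNorm"),
                                  rownames(qm)),
         genesUsed = genes)
}

#' Jaccard-index cluster stability under cell subsampling
#'
#' Per repetition, `floor(fraction * nCells)` cells are drawn without
#' replacement and re-clustered by the supplied procedure; every original
#' cluster records the maximum Jaccard index between its subsampled member
#' set and any new cluster (no bipartite matching is enforced). The verdict
#' uses the mean over repetitions against the threshold (median also
#' reported); clusters below the threshold are considered unstable. The
#' result is invariant to cluster label renaming.
#'
#' @param x a [CellMatrix-class].
#' @param clusterer function mapping a [CellMatrix-class] to a label vector
#'   (one label per cell); see [kmeansClusterer()] for the built-in
#'   reference clusterer.
#' @param fraction cell fraction per repetition.
#' @param reps repetitions (>= 1).
#' @param seed integer seed.
#' @param threshold stability cutoff on the mean Jaccard index.
#' @return data.frame with per-cluster `meanJaccard`, `medianJaccard`,
#'   `stable`.
#' @export
jaccardStability <- function(x, clusterer, fraction = 0.8, reps = 20L,
                             seed = 1L, threshold = 0.6) {
    if (reps < 1L) stop("reps must be >= 1")
    cl <- clusterLabels(x)
    ids <- sort(unique(cl))
    nSub <- floor(fraction * ncol(x))
    jac <- withSeed(seed, {
        vapply(seq_len(reps), function(r) {
            idx <- sort(sample(ncol(x), nSub))
            sub <- CellMatrix(umiCounts(x)[, idx, drop = FALSE],
                              cl[idx], datasetTag = datasetTag(x))
            newLab <- as.character(clusterer(sub))
            if (!length(unique(newLab)))
                stop("clusterer returned no labels")
            if (length(newLab) != nSub)
                stop("clusterer must label every cell")
            vapply(ids, function(k) {
                orig <- which(cl[idx] == k)
                if (!length(orig)) return(NA_real_)
                max(vapply(unique(newLab), function(nk) {
                    new <- which(newLab == nk)
                    length(intersect(orig, new)) / length(union(orig, new))
                }, 1.0))
            }, 1.0)
        }, numeric(length(ids)))
    })
    jac <- matrix(jac, nrow = length(ids))
    out <- data.frame(
        cluster = ids,
        meanJaccard = rowMeans(jac, na.rm = TRUE),
        medianJaccard = apply(jac, 1L, median, na.rm = TRUE))
    out$stable <- out$meanJaccard >= threshold
    rownames(out) <- NULL
    out
}

#' Built-in reference clusterer: k-means on top principal components
#'
#' A deliberately simple stand-in used to exercise the stability module; it
#' is not a product-grade clustering method.
#'
#' @param k number of clusters.
#' @param nPcs principal components to keep.
#' @param seed seed for the k-means starts.
#' @return a function suitable for [jaccardStability()].
#' @export
kmeansClusterer <- function(k, nPcs = 10L, seed = 1L) {
    force(k); force(nPcs); force(seed)
    function(cells) {
        if (!hasLogNorm(cells)) cells <- normalizeCells(cells)
        m <- t(as.matrix(logNorm(cells)))
        keep <- apply(m, 2L, var) > 0
        pc <- prcomp(m[, keep, drop = FALSE], rank. = min(nPcs, sum(keep)),
                     center = TRUE, scale. = FALSE)$x
        withSeed(seed, kmeans(pc, centers = k, nstart = 5L)$cluster)
    }
}

#' Binary ON/OFF marking of gene expression per cluster
#'
#' ON iff the fraction of the cluster's cells expressing the gene (raw
#' count above zero) is at least `minPct`, or the mean raw UMI over the expressing cells
#' is at least `minMeanUmi`. Both boundaries are attainable (inclusive),
#' unlike the strict identity-assignment rule of [assignIdentity()].
#'
#' @param x a [CellMatrix-class].
#' @param genes genes to mark (must be present).
#' @param minPct expressing-fraction cutoff.
#' @param minMeanUmi mean-UMI-over-expressing-cells cutoff.
#' @return integer matrix (genes x clusters, 1 = ON) with attribute
#'   `ruleTag = "expression"`.
#' @export
binaryMarkingExpression <- function(x, genes, minPct = 0.05,
                                    minMeanUmi = 2.0) {
    missing <- setdiff(genes, rownames(x))
    if (length(missing))
        stop("gene(s) absent: ", paste(missing, collapse = ", "))
    cl <- clusterLabels(x)
    ids <- sort(unique(cl))
    cts <- umiCounts(x)[genes, , drop = FALSE]
    m <- vapply(ids, function(k) {
        sub <- cts[, cl == k, drop = FALSE]
        if (!ncol(sub)) stop("cluster ", k, " is empty")
        pct <- Matrix::rowMeans(sub > 0)
        meanUmi <- ifelse(Matrix::rowSums(sub > 0) > 0,
                          Matrix::rowSums(sub) / Matrix::rowSums(sub > 0), 0)
        as.integer(pct >= minPct | meanUmi >= minMeanUmi)
    }, integer(length(genes)))
    m <- matrix(m, nrow = length(genes), dimnames = list(genes, ids))
    attr(m, "ruleTag") <- "expression"
    m
}

#' Binary ON/OFF marking from labeling counts
#'
#' From a table of (gene, subclass, fish, count) labeling observations, a
#' (gene, subclass) cell is ON iff the total labelings reach `minTimes` AND
#' they come from at least `minFish` distinct fish.
#'
#' @param labelCounts data.frame with columns `gene`, `subclass`, `fish`,
#'   `count` (counts >= 0).
#' @param minTimes minimum total labelings.
#' @param minFish minimum distinct fish with at least one labeling.
#' @return integer matrix (genes x subclasses) with attribute
#'   `ruleTag = "labeling"`.
#' @export
binaryMarkingLabeling <- function(labelCounts, minTimes = 4L, minFish = 4L) {
    need <- c("gene", "subclass", "fish", "count")
    if (!all(need %in% names(labelCounts)))
        stop("labelCounts needs columns: ", paste(need, collapse = ", "))
    if (any(labelCounts$count < 0)) stop("counts must be >= 0")
    genes <- sort(unique(labelCounts$gene))
    subs <- sort(unique(labelCounts$subclass))
    m <- matrix(0L, length(genes), length(subs), dimnames = list(genes, subs))
    for (g in genes) for (s in subs) {
        rows <- labelCounts$gene == g & labelCounts$subclass == s
        total <- sum(labelCounts$count[rows])
        fish <- length(unique(labelCounts$fish[rows & labelCounts$count > 0]))
        m[g, s] <- as.integer(total >= minTimes && fish >= minFish)
    }
    attr(m, "ruleTag") <- "labeling"
    m
}

#' NNLS correspondence between clusters and morphological subclasses
#'
#' Decomposes each morphology column (a 0/1 gene vector) against the cluster
#' columns of the expression marking matrix by NNLS; after normalizing each
#' coefficient row to sum one, a cluster corresponds to a subclass when its
#' normalized coefficient exceeds the cutoff. An all-zero morphology column
#' yields zero coefficients and no correspondence.
#'
#' @param tfByCluster,tfByMorph binary matrices with identical gene rows
#'   (from [binaryMarkingExpression()] / [binaryMarkingLabeling()]).
#' @param cutoff normalized-coefficient threshold.
#' @return list with `coefficients` (subclass x cluster), `normalized`,
#'   `correspondence` (logical matrix) and `residualNorms`.
#' @export
morphologyClusterCorrespondence <- function(tfByCluster, tfByMorph,
                                            cutoff = 0.1) {
    if (!identical(rownames(tfByCluster), rownames(tfByMorph)))
        stop("gene rows of the two binary matrices must match")
    fits <- lapply(colnames(tfByMorph), function(s)
        nnlsSolve(tfByCluster, tfByMorph[, s]))
    coef <- do.call(rbind, lapply(fits, `[[`, "x"))
    dimnames(coef) <- list(colnames(tfByMorph), colnames(tfByCluster))
    rs <- rowSums(coef)
    norm <- coef / ifelse(rs > 0, rs, 1)
    list(coefficients = coef, normalized = norm,
         correspondence = norm > cutoff,
         residualNorms = setNames(vapply(fits, `[[`, 1.0, "residualNorm"),
                                  colnames(tfByMorph)))
}
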