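#' Ward dendrogram from a pairwise distance
#'
#' Agglomerative tree under the classical Ward criterion applied to the given
#' dissimilarities un-squared ("ward.D" in [stats::hclust]), the variant with
#' non-decreasing merge heights used throughout this package. Deterministic
#' for a given distance matrix.
#'
#' @param dist a [PairwiseDistance-class].
#' @return an [stats::hclust] tree whose labels are the cluster ids.
#' @seealso [sisterPairs()], [cutDendrogram()], [treeDistance()]
#' @export
wardTree <- function(dist) {
    d <- distanceMatrix(dist)
    if (nrow(d) < 2L) stop("need >= 2 clusters to build a tree")
    hc <- hclust(as.dist(d), method = "ward.D")
    hc$geneSetTag <- geneSetTag(dist)
    hc
}

#' Cut a dendrogram at a fixed height
#'
#' Groups are the connected components that remain after removing all merges
#' above the cutoff; a cut above the root yields one group, a cut at zero
#' makes every leaf its own group.
#'
#' @param tree an [stats::hclust] tree.
#' @param height cut height (>= 0).
#' @return named character vector, cluster id -> group label.
#' @export
cutDendrogram <- function(tree, height) {
    if (height < 0) stop("height must be >= 0")
    grp <- cutree(tree, h = height)
    setNames(as.character(grp), names(grp))
}

#' Terminal sister pairs (cherries) of a dendrogram
#'
#' A cherry is an internal node whose two children are both leaves; its two
#' leaves are the "sister clusters" -- the most similar pair under the tree's
#' gene set. The result is invariant to child order within merges, the pairs
#' are disjoint, and an n-leaf binary tree carries between 1 and
#' `floor(n/2)` cherries.
#'
#' @param tree an [stats::hclust] tree.
#' @return data.frame with columns `pair`, `a`, `b` (canonical order) and a
#'   `"source"` attribute carrying the tree's gene-set tag.
#' @export
sisterPairs <- function(tree) {
    m <- tree$merge
    cherry <- which(m[, 1L] < 0 & m[, 2L] < 0)
    a <- tree$labels[-m[cherry, 1L]]
    b <- tree$labels[-m[cherry, 2L]]
    out <- data.frame(pair = pairKey(a, b), a = pmin(a, b), b = pmax(a, b))
    out <- out[order(out$pair), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "source") <- tree$geneSetTag %||% "custom"
    out
}

# Leaf sets of all internal nodes of an hclust tree, root excluded.
# Returned as a list of sorted character vectors.
hclustClades <- function(tree) {
    m <- tree$merge
    n <- nrow(m) + 1L
    sets <- vector("list", nrow(m))
    for (i in seq_len(nrow(m))) {
        left <- if (m[i, 1L] < 0) tree$labels[-m[i, 1L]] else sets[[m[i, 1L]]]
        right <- if (m[i, 2L] < 0) tree$labels[-m[i, 2L]] else sets[[m[i, 2L]]]
        sets[[i]] <- sort(c(left, right))
    }
    sets[-nrow(m)]  # drop root
}

# Clades of an ape::phylo tree (internal nodes, root excluded).
phyloClades <- function(tree) {
    pp <- ape::prop.part(tree)
    lab <- attr(pp, "labels")
    sets <- lapply(pp, function(i) sort(lab[i]))
    sets[vapply(sets, length, 1L) < length(lab)]
}

treeClades <- function(tree) {
    if (inherits(tree, "hclust")) hclustClades(tree)
    else if (inherits(tree, "phylo")) phyloClades(tree)
    else stop("tree must be an hclust or phylo object")
}

treeLeaves <- function(tree) {
    if (inherits(tree, "hclust")) sort(tree$labels)
    else sort(tree$tip.label)
}

# Canonical nontrivial bipartitions over `leaves`: logical membership vector,
# flipped so the first leaf is always FALSE; trivial splits dropped.
cladeSplits <- function(clades, leaves) {
    n <- length(leaves)
    out <- list()
    for (cl in clades) {
        k <- length(cl)
        if (k < 2L || k > n - 2L) next
        mem <- leaves %in% cl
        if (mem[1L]) mem <- !mem
        out[[paste(as.integer(mem), collapse = "")]] <- mem
    }
    out
}

splitEntropy <- function(mem) {
    n <- length(mem); k <- sum(mem)
    p <- c(k, n - k) / n
    -sum(p * log2(p))
}

splitMutualInfo <- function(m1, m2) {
    n <- length(m1)
    total <- 0
    for (x in c(TRUE, FALSE)) for (y in c(TRUE, FALSE)) {
        nxy <- sum(m1 == x & m2 == y)
        if (nxy == 0) next
        p <- nxy / n
        total <- total + p * log2(p / ((sum(m1 == x) / n) * (sum(m2 == y) / n)))
    }
    total
}

# Jonker-style Hungarian algorithm, minimizing over a square cost matrix.
# Returns the columns assigned to each row.
hungarianMin <- function(a) {
    n <- nrow(a)
    stopifnot(ncol(a) == n)
    u <- numeric(n); v <- numeric(n + 1L)
    p <- integer(n + 1L)   # p[j]: row matched to column j (0 = free)
    way <- integer(n + 1L)
    for (i in seq_len(n)) {
        p[n + 1L] <- i
        j0 <- n + 1L
        minv <- rep(Inf, n + 1L)
        used <- rep(FALSE, n + 1L)
        repeat {
            used[j0] <- TRUE
            i0 <- p[j0]; delta <- Inf; j1 <- 0L
            for (j in seq_len(n)) {
                if (used[j]) next
                cur <- a[i0, j] - u[i0] - v[j]
                if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
                if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
            }
            for (j in seq_len(n + 1L)) {
                if (used[j]) {
                    if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
                    v[j] <- v[j] - delta
                } else minv[j] <- minv[j] - delta
            }
            j0 <- j1
            if (p[j0] == 0L) break
        }
        repeat {
            j1 <- way[j0]
            p[j0] <- p[j1]
            j0 <- j1
            if (j0 == n + 1L) break
        }
    }
    assignment <- integer(n)
    for (j in seq_len(n)) assignment[p[j]] <- j
    assignment
}

# Maximum-weight assignment total for a (possibly rectangular) non-negative
# weight matrix; unmatched rows/columns contribute zero.
maxAssignmentTotal <- function(w) {
    if (!length(w) || !nrow(w) || !ncol(w)) return(0)
    k <- max(nrow(w), ncol(w))
    cost <- matrix(0, k, k)
    cost[seq_len(nrow(w)), seq_len(ncol(w))] <- -w
    assign <- hungarianMin(cost)
    total <- 0
    for (i in seq_len(nrow(w))) {
        j <- assign[i]
        if (j <= ncol(w)) total <- total + w[i, j]
    }
    total
}

#' Discordance between two dendrograms over the same clusters
#'
#' Compares two trees with identical leaf sets. `metric = "cid"` is the
#' normalized clustering-information distance: the pairwise mutual clustering
#' information between the two trees' nontrivial bipartitions is maximized
#' over an optimal one-to-one matching (solved exactly by a Hungarian
#' assignment), and the distance is one minus that shared information
#' normalized by the mean total split information of the two trees.
#' `metric = "rf"` is the Robinson-Foulds distance on induced bipartitions,
#' normalized by `2(n - 3)`. Both are symmetric, zero iff the topologies are
#' identical, and at most 1.
#'
#' Also reported: `matchingNodes`, the number of internal nodes (root
#' excluded) whose induced leaf sets are identical in both trees, and
#' `matchedPairs`, the sister pairs (cherries) shared by both trees.
#'
#' @param t1,t2 [stats::hclust] or [ape::phylo] trees over the same leaves.
#' @param metric `"cid"` (default) or `"rf"`.
#' @return list with `distance`, `metric`, `matchingNodes`, `matchedPairs`.
#' @export
treeDistance <- function(t1, t2, metric = c("cid", "rf")) {
    metric <- match.arg(metric)
    leaves <- treeLeaves(t1)
    if (!identical(leaves, treeLeaves(t2))) {
        diff <- c(setdiff(treeLeaves(t1), treeLeaves(t2)),
                  setdiff(treeLeaves(t2), treeLeaves(t1)))
        stop("leaf sets differ: ", paste(diff, collapse = ", "))
    }
    n <- length(leaves)
    c1 <- treeClades(t1); c2 <- treeClades(t2)
    keys1 <- vapply(c1, paste, "", collapse = ",")
    keys2 <- vapply(c2, paste, "", collapse = ",")
    matchingNodes <- length(intersect(unique(keys1), unique(keys2)))
    cherries1 <- c1[vapply(c1, length, 1L) == 2L]
    cherries2 <- c2[vapply(c2, length, 1L) == 2L]
    shared <- intersect(vapply(cherries1, paste, "", collapse = "|"),
                        vapply(cherries2, paste, "", collapse = "|"))
    s1 <- cladeSplits(c1, leaves); s2 <- cladeSplits(c2, leaves)
    distance <- if (metric == "rf") {
        if (n <= 3L || (!length(s1) && !length(s2))) 0
        else length(c(setdiff(names(s1), names(s2)),
                      setdiff(names(s2), names(s1)))) / (2 * (n - 3))
    } else {
        h1 <- sum(vapply(s1, splitEntropy, 1.0))
        h2 <- sum(vapply(s2, splitEntropy, 1.0))
        if (h1 == 0 && h2 == 0) 0 else {
            w <- matrix(0, length(s1), length(s2))
            for (i in seq_along(s1)) for (j in seq_along(s2))
                w[i, j] <- max(0, splitMutualInfo(s1[[i]], s2[[j]]))
            1 - maxAssignmentTotal(w) / mean(c(h1, h2))
        }
    }
    list(distance = max(0, min(1, distance)), metric = metric,
         matchingNodes = matchingNodes, matchedPairs = shared)
}

#' Bootstrap clade support (with optional multiscale AU p-values)
#'
#' Resamples genes (the columns of the profile matrix) with replacement,
#' rebuilds the Ward tree for each replicate, and reports for every internal
#' node of the full-data tree its bootstrap proportion (BP): the fraction of
#' replicate trees containing the node's exact leaf set. With
#' `multiscale = TRUE`, the approximately-unbiased (AU) p-value is computed
#' from the multiscale bootstrap: at scales `r` the replicate gene count is
#' `round(r * m)`, `z(r) = sqrt(r) * qnorm(1 - BP_r)` is fitted by weighted
#' least squares as `z(r) = d * sqrt(r) + c / sqrt(r)`, and
#' `AU = 1 - pnorm(d - c)`. A clade absent (or present) in every replicate at
#' every scale is reported with the boundary AU value 0 (or 1) and flagged as
#' degenerate rather than raising an error.
#'
#' @param means a [ClusterMeanMatrix-class].
#' @param genes gene set to resample over.
#' @param nBoot bootstrap replicates per scale (>= 100).
#' @param seed integer seed (the whole computation is deterministic given it).
#' @param multiscale compute AU p-values over `scales`.
#' @param scales scale factors for the multiscale bootstrap.
#' @param auThreshold clades with `AU > auThreshold` are flagged strongly
#'   supported.
#' @param geneSetTag tag for the underlying distance.
#' @return list with `tree` (the full-data [stats::hclust]) and `support`, a
#'   data.frame with one row per internal node (root excluded): `clade`
#'   (comma-joined leaf set), `size`, `bp`, and when `multiscale` also `au`,
#'   `degenerate` and `stronglySupported`.
#' @export
bootstrapSupport <- function(means, genes, nBoot = 1000L, seed = 1L,
                             multiscale = FALSE,
                             scales = seq(0.5, 1.4, by = 0.1),
                             auThreshold = 0.9, geneSetTag = "custom") {
    if (nBoot < 100L) stop("nBoot must be >= 100")
    base <- wardTree(profileDistance(means, genes, geneSetTag))
    clades <- hclustClades(base)
    keys <- vapply(clades, paste, "", collapse = ",")
    m <- length(genes)
    scaleSet <- if (multiscale) scales else 1.0

    countAtScale <- function(r) {
        hits <- setNames(numeric(length(keys)), keys)
        ok <- 0L
        for (b in seq_len(nBoot)) {
            g <- sample(genes, max(3L, round(r * m)), replace = TRUE)
            d <- tryCatch(profileDistance(means, g, geneSetTag),
                          error = function(e) NULL)
            if (is.null(d)) next
            ok <- ok + 1L
            bk <- vapply(hclustClades(wardTree(d)), paste, "", collapse = ",")
            present <- keys %in% bk
            hits[present] <- hits[present] + 1
        }
        hits / max(ok, 1L)
    }

    bpMat <- withSeed(seed,
        vapply(scaleSet, countAtScale, numeric(length(keys))))
    bpMat <- matrix(bpMat, nrow = length(keys))
    bpAt1 <- bpMat[, which.min(abs(scaleSet - 1.0)), drop = TRUE]

    support <- data.frame(clade = keys,
                          size = vapply(clades, length, 1L),
                          bp = bpAt1)
    if (multiscale) {
        eps <- 1 / (2 * nBoot)
        au <- numeric(length(keys)); degen <- logical(length(keys))
        for (i in seq_along(keys)) {
            bps <- bpMat[i, ]
            if (all(bps <= 0)) { au[i] <- 0; degen[i] <- TRUE; next }
            if (all(bps >= 1)) { au[i] <- 1; degen[i] <- TRUE; next }
            bps <- pmin(pmax(bps, eps), 1 - eps)
            z <- sqrt(scaleSet) * qnorm(1 - bps)
            wts <- nBoot * dnorm(qnorm(bps))^2 / (bps * (1 - bps))
            X <- cbind(sqrt(scaleSet), 1 / sqrt(scaleSet))
            fit <- stats::lm.wfit(X, z, wts)
            au[i] <- 1 - pnorm(fit$coefficients[1L] - fit$coefficients[2L])
        }
        support$au <- au
        support$degenerate <- degen
        support$stronglySupported <- au > auThreshold
    }
    list(tree = base, support = support)
}
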