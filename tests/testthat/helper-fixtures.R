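# Fixture builders shared across test files.

# Small CellMatrix with the given counts (genes x cells) and labels.
toyCells <- function(counts, clusters, norm = TRUE) {
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
    cm <- CellMatrix(counts, clusters)
    if (norm) cm <- normalizeCells(cm) else cm
}

# Two-group fixture with planted differential genes: `diffGenes` have mean
# `hiMean` in group A and `loMean` in group B; all other genes share `base`.
twoGroupCells <- function(nGenes = 50, nPerGroup = 20, diffGenes = 1,
                          hiMean = 3, loMean = 0.05, base = 1, seed = 1) {
    set.seed(seed)
    mu <- matrix(base, nGenes, 2 * nPerGroup)
    if (diffGenes > 0) {
        mu[seq_len(diffGenes), seq_len(nPerGroup)] <- hiMean
        mu[seq_len(diffGenes), nPerGroup + seq_len(nPerGroup)] <- loMean
    }
    counts <- matrix(rpois(length(mu), mu), nGenes)
    toyCells(counts, rep(c("A", "B"), each = nPerGroup))
}

# Cluster-mean fixture with two tight blocks {a,b} and {c,d}.
blockMeans <- function(withinNoise = 0.01, nGenes = 60, seed = 1) {
    set.seed(seed)
    base1 <- runif(nGenes, 0, 2); base2 <- runif(nGenes, 0, 2)
    m <- rbind(a = base1 + rnorm(nGenes, 0, withinNoise),
               b = base1 + rnorm(nGenes, 0, withinNoise),
               c = base2 + rnorm(nGenes, 0, withinNoise),
               d = base2 + rnorm(nGenes, 0, withinNoise))
    m <- pmax(m, 0)
    colnames(m) <- sprintf("g%03d", seq_len(nGenes))
    ClusterMeanMatrix(m)
}

# Distance matrix object from a plain symmetric matrix.
asDist <- function(d, tag = "custom") {
    methods::new("PairwiseDistance", d = d, geneSetTag = tag,
                 nGenesUsed = 10L)
}

randomDistanceMatrix <- function(n, seed, ties = FALSE) {
    set.seed(seed)
    vals <- if (ties) sample(seq(0.1, 0.9, by = 0.1), n * (n - 1) / 2,
                             replace = TRUE)
            else runif(n * (n - 1) / 2)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- vals
    d <- d + t(d)
    ids <- sprintf("K%02d", seq_len(n))
    dimnames(d) <- list(ids, ids)
    d
}

# hclust object built by hand from an explicit merge matrix.
manualTree <- function(merge, height, labels) {
    structure(list(merge = merge, height = height, order = seq_along(labels),
                   labels = labels, method = "ward.D"),
              class = "hclust")
}
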