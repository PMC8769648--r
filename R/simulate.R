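#' Construct the synthetic-data ground truth
#'
#' Defaults are the package's reference simulation: 30 clusters with 3
#' planted pairs per pattern (pairs are disjoint and occupy the first 18
#' clusters), 500 TF / 500 effector / 100 RBP / 100 other genes, within-pair
#' log-scale correlation 0.95 against a background of 0, 200 cells per
#' cluster, negative-binomial size 2, lognormal library sizes with mean
#' 2000 UMIs, and a log-scale offset of 1.5 planted on 15 designated RBP
#' genes of each divergent pair (disjoint across pairs).
#'
#' @param nClusters number of clusters.
#' @param pairsPerPattern planted pairs per pattern (used only when
#'   `plantedPairs` is `NULL`).
#' @param plantedPairs optional data.frame (`a`, `b`, `pattern`) of planted
#'   pairs; clusters are named `C01`, `C02`, ...
#' @param genesPerCategory named vector: genes per TF/effector/RBP/other block.
#' @param rhoSimilar,rhoBackground target log-scale Pearson correlations
#'   within planted pairs and between unrelated clusters.
#' @param cellsPerCluster,nbDispersion,librarySizeMean,librarySizeSdLog
#'   observation-model parameters (see [SyntheticTruth-class]).
#' @param logSd sd of per-cluster log-expression deviations.
#' @param rbpOffset,nRbpDiffGenes divergent-pair RBP offset (log scale, at
#'   least 1) and the number of offset genes per divergent pair.
#' @param seed integer seed; all generation is a pure function of it.
#' @return a validated [SyntheticTruth-class].
#' @export
syntheticTruth <- function(nClusters = 30L, pairsPerPattern = 3L,
                           plantedPairs = NULL,
                           genesPerCategory = c(TF = 500L, effector = 500L,
                                                RBP = 100L, other = 100L),
                           rhoSimilar = 0.95, rhoBackground = 0,
                           cellsPerCluster = 200L, nbDispersion = 2,
                           librarySizeMean = 2000, librarySizeSdLog = 0.3,
                           logSd = 1, rbpOffset = 1.5, nRbpDiffGenes = 15L,
                           seed = 1L) {
    ids <- sprintf("C%02d", seq_len(nClusters))
    if (is.null(plantedPairs)) {
        patterns <- rep(c("matched", "convergent", "divergent"),
                        each = pairsPerPattern)
        need <- 2L * length(patterns)
        if (need > nClusters)
            stop("more planted clusters (", need, ") than nClusters")
        plantedPairs <- data.frame(
            a = ids[seq(1L, need, by = 2L)],
            b = ids[seq(2L, need, by = 2L)],
            pattern = patterns)
    }
    methods::new("SyntheticTruth", nClusters = as.integer(nClusters),
                 genesPerCategory = vapply(genesPerCategory, as.integer, 1L),
                 plantedPairs = plantedPairs, rhoSimilar = rhoSimilar,
                 rhoBackground = rhoBackground,
                 cellsPerCluster = as.integer(cellsPerCluster),
                 nbDispersion = nbDispersion,
                 librarySizeMean = librarySizeMean,
                 librarySizeSdLog = librarySizeSdLog, logSd = logSd,
                 rbpOffset = rbpOffset,
                 nRbpDiffGenes = as.integer(nRbpDiffGenes),
                 seed = as.integer(seed))
}

truthClusterIds <- function(truth) sprintf("C%02d", seq_len(truth@nClusters))

truthGeneIds <- function(truth) {
    g <- truth@genesPerCategory
    list(TF = sprintf("TF%04d", seq_len(g[["TF"]])),
         effector = sprintf("EF%04d", seq_len(g[["effector"]])),
         RBP = sprintf("RB%04d", seq_len(g[["RBP"]])),
         other = sprintf("OT%04d", seq_len(g[["other"]])))
}

#' Generate planted cluster mean profiles
#'
#' Builds the cluster x gene relative-expression matrix with the planted
#' correlation structure. Per gene block, cluster log-profiles are
#' `mu_g + eps_kg` with a shared gene baseline variance and an independent
#' per-cluster deviation chosen analytically so that unrelated clusters hit
#' `rhoBackground` and planted pairs hit `rhoSimilar` on the log scale: the
#' second member of a correlated pair shares the first member's deviation
#' with mixing weight `(rhoSimilar - rhoBackground) / (1 - rhoBackground)`.
#' Which blocks a pair shares depends on its pattern: matched pairs share the
#' TF and effector blocks; convergent pairs share only the effector block;
#' divergent pairs share only the TF block. The RBP and "other" blocks are
#' shared within every planted pair so that differential-RBP signal is
#' attributable to the planted offsets: each divergent pair additionally
#' carries a disjoint designated subset of RBP genes offset by `rbpOffset`
#' (log scale) in its second member. Profiles are exponentiated and scaled to
#' 10,000 per cluster. Generation is a pure function of the truth's seed.
#'
#' @param truth a [SyntheticTruth-class].
#' @return list with `means` (a [ClusterMeanMatrix-class]) and `catalog`
#'   (the matching [GeneCatalog-class]).
#' @export
generateClusterMeans <- function(truth) {
    methods::validObject(truth)
    ids <- truthClusterIds(truth)
    geneSets <- truthGeneIds(truth)
    pp <- truth@plantedPairs
    rho <- truth@rhoSimilar; rhoBg <- truth@rhoBackground
    mix <- (rho - rhoBg) / (1 - rhoBg)
    sdMu <- truth@logSd * sqrt(rhoBg)        # shared gene baseline
    sdEps <- truth@logSd * sqrt(1 - rhoBg)   # per-cluster deviation

    sharesBlock <- function(pattern, block) {
        switch(block,
               TF = pattern %in% c("matched", "divergent"),
               effector = pattern %in% c("matched", "convergent"),
               TRUE)  # RBP and other blocks shared within every planted pair
    }

    logm <- withSeed(truth@seed, {
        out <- NULL
        divSeen <- 0L
        blockList <- lapply(names(geneSets), function(block) {
            genes <- geneSets[[block]]
            G <- length(genes)
            mu <- rnorm(G, 0, sdMu)
            eps <- matrix(rnorm(G * length(ids), 0, sdEps), nrow = G,
                          dimnames = list(genes, ids))
            for (p in seq_len(nrow(pp))) {
                if (!sharesBlock(pp$pattern[p], block)) next
                eps[, pp$b[p]] <- mix * eps[, pp$a[p]] +
                    sqrt(1 - mix^2) * eps[, pp$b[p]]
            }
            mu + eps
        })
        names(blockList) <- names(geneSets)
        # divergent-pair RBP offsets: disjoint designated gene subsets
        divPairs <- pp[pp$pattern == "divergent", , drop = FALSE]
        if (nrow(divPairs)) {
            for (p in seq_len(nrow(divPairs))) {
                idx <- ((p - 1L) * truth@nRbpDiffGenes + 1L):
                       (p * truth@nRbpDiffGenes)
                blockList$RBP[idx, divPairs$b[p]] <-
                    blockList$RBP[idx, divPairs$b[p]] + truth@rbpOffset
            }
        }
        do.call(rbind, blockList)
    })
    lam <- t(exp(logm))  # clusters x genes
    lam <- lam / rowSums(lam) * 1e4
    catalog <- GeneCatalog(unlist(geneSets, use.names = FALSE),
                           rep(names(geneSets),
                               vapply(geneSets, length, 1L)))
    list(means = ClusterMeanMatrix(lam), catalog = catalog)
}

#' Generate UMI counts from cluster mean profiles
#'
#' Each cell draws a lognormal library size, then gene counts are negative
#' binomial with mean `librarySize * profile / sum(profile)` and size
#' `nbDispersion` (variance `mu + mu^2 / size`; the large-size limit is
#' Poisson). Cluster labels are attached; the RNG stream is derived from the
#' truth's seed (offset by one) so means and counts are independently
#' reproducible.
#'
#' @param means the [ClusterMeanMatrix-class] from [generateClusterMeans()].
#' @param truth the matching [SyntheticTruth-class].
#' @return a [CellMatrix-class] with `truth@cellsPerCluster` cells per cluster.
#' @export
generateCounts <- function(means, truth) {
    if (truth@nbDispersion <= 0) stop("nbDispersion must be > 0")
    lam <- profileMatrix(means)
    ids <- rownames(lam)
    nc <- truth@cellsPerCluster
    G <- ncol(lam)
    sdl <- truth@librarySizeSdLog
    meanlog <- log(truth@librarySizeMean) - sdl^2 / 2
    counts <- withSeed(truth@seed + 1L, {
        blocks <- lapply(ids, function(k) {
            p <- lam[k, ] / sum(lam[k, ])
            lib <- rlnorm(nc, meanlog, sdl)
            mu <- outer(p, lib)   # genes x cells
            matrix(rnbinom(G * nc, size = truth@nbDispersion, mu = mu),
                   nrow = G)
        })
        do.call(cbind, blocks)
    })
    rownames(counts) <- colnames(lam)
    colnames(counts) <- paste0(rep(ids, each = nc), "_",
                               sprintf("%03d", seq_len(nc)))
    CellMatrix(counts, rep(ids, each = nc), datasetTag = "synthetic")
}

#' One-call synthetic dataset
#'
#' Convenience wrapper running [generateClusterMeans()] and
#' [generateCounts()].
#'
#' @param truth a [SyntheticTruth-class].
#' @return list with `truth`, `means`, `catalog`, `cells`.
#' @export
simulateRegulatoryData <- function(truth = syntheticTruth()) {
    gm <- generateClusterMeans(truth)
    cells <- generateCounts(gm$means, truth)
    list(truth = truth, means = gm$means, catalog = gm$catalog, cells = cells)
}

#' Score pattern recovery against planted truth
#'
#' A planted pair counts as recovered iff the prediction assigns it exactly
#' the planted pattern. Per pattern, precision is computed over all predicted
#' pairs carrying that pattern and recall over the planted pairs; overall
#' accuracy is the fraction of planted pairs recovered.
#'
#' @param predicted a [PatternAssignment-class].
#' @param truth the [SyntheticTruth-class] the data came from.
#' @return list with `perPattern` (data.frame: pattern, planted, predicted,
#'   recovered, precision, recall) and `accuracy`.
#' @export
evaluateRecovery <- function(predicted, truth) {
    tab <- patternTable(predicted)
    ids <- truthClusterIds(truth)
    covered <- unique(c(tab$a, tab$b))
    if (!all(ids %in% covered))
        stop("prediction does not cover the truth's clusters: missing ",
             paste(head(setdiff(ids, covered), 5L), collapse = ", "))
    pp <- truth@plantedPairs
    plantedKey <- pairKey(pp$a, pp$b)
    pats <- c("matched", "convergent", "divergent")
    per <- do.call(rbind, lapply(pats, function(p) {
        plantedP <- plantedKey[pp$pattern == p]
        predP <- tab$pair[tab$pattern == p]
        tp <- length(intersect(plantedP, predP))
        data.frame(pattern = p, planted = length(plantedP),
                   predicted = length(predP), recovered = tp,
                   precision = if (length(predP)) tp / length(predP) else NA_real_,
                   recall = if (length(plantedP)) tp / length(plantedP) else NA_real_)
    }))
    recovered <- sum(per$recovered)
    list(perPattern = per,
         accuracy = if (nrow(pp)) recovered / nrow(pp) else NA_real_)
}
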