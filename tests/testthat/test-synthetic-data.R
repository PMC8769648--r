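smallTruth <- function(seed = 1L, ...) {
    syntheticTruth(nClusters = 8L, pairsPerPattern = 1L,
                   genesPerCategory = c(TF = 120L, effector = 120L,
                                        RBP = 40L, other = 20L),
                   cellsPerCluster = 50L, nRbpDiffGenes = 8L,
                   seed = seed, ...)
}

test_that("generation is a pure function of the seed", {
    t1 <- smallTruth(seed = 5L)
    g1 <- generateClusterMeans(t1)
    g2 <- generateClusterMeans(t1)
    expect_identical(profileMatrix(g1$means), profileMatrix(g2$means))
    c1 <- generateCounts(g1$means, t1)
    c2 <- generateCounts(g2$means, t1)
    expect_identical(as.matrix(SummarizedExperiment::assay(c1, "counts")),
                     as.matrix(SummarizedExperiment::assay(c2, "counts")))
    g3 <- generateClusterMeans(smallTruth(seed = 6L))
    expect_false(identical(profileMatrix(g1$means), profileMatrix(g3$means)))
})

test_that("planted matched pairs realize the target block correlations", {
    truth <- syntheticTruth(nClusters = 6L, pairsPerPattern = 1L,
                            plantedPairs = data.frame(a = "C01", b = "C02",
                                                      pattern = "matched"),
                            genesPerCategory = c(TF = 500L, effector = 500L,
                                                 RBP = 50L, other = 50L),
                            rhoSimilar = 0.95, seed = 2L)
    gm <- generateClusterMeans(truth)
    pm <- profileMatrix(gm$means)
    gs <- partitionGenes(gm$catalog, colnames(pm))
    expect_gt(cor(pm["C01", gs$TF], pm["C02", gs$TF]), 0.8)
    expect_gt(cor(pm["C01", gs$effector], pm["C02", gs$effector]), 0.8)
})

test_that("with no planted pairs all block correlations stay at background", {
    for (s in 1:10) {
        truth <- syntheticTruth(nClusters = 6L,
                                plantedPairs = data.frame(a = character(),
                                                          b = character(),
                                                          pattern = character()),
                                genesPerCategory = c(TF = 500L, effector = 500L,
                                                     RBP = 20L, other = 20L),
                                rhoBackground = 0, seed = s)
        pm <- profileMatrix(generateClusterMeans(truth)$means)
        gs <- list(TF = grep("^TF", colnames(pm), value = TRUE),
                   effector = grep("^EF", colnames(pm), value = TRUE))
        for (block in gs) {
            cc <- cor(t(pm[, block]))
            expect_lt(max(abs(cc[upper.tri(cc)])), 0.5)
        }
    }
})

test_that("pattern-specific block structure is planted correctly", {
    truth <- syntheticTruth(nClusters = 8L, pairsPerPattern = 1L,
                            genesPerCategory = c(TF = 400L, effector = 400L,
                                                 RBP = 40L, other = 20L),
                            cellsPerCluster = 50L, nRbpDiffGenes = 8L,
                            seed = 3L)
    gm <- generateClusterMeans(truth)
    pm <- profileMatrix(gm$means)
    gs <- partitionGenes(gm$catalog, colnames(pm))
    pp <- plantedPairs(truth)
    for (i in seq_len(nrow(pp))) {
        tfCor <- cor(pm[pp$a[i], gs$TF], pm[pp$b[i], gs$TF])
        effCor <- cor(pm[pp$a[i], gs$effector], pm[pp$b[i], gs$effector])
        switch(pp$pattern[i],
            matched = { expect_gt(tfCor, 0.8); expect_gt(effCor, 0.8) },
            convergent = { expect_lt(abs(tfCor), 0.5); expect_gt(effCor, 0.8) },
            divergent = { expect_gt(tfCor, 0.8); expect_lt(abs(effCor), 0.5) })
    }
})

test_that("counts carry the right cells and labels", {
    truth <- syntheticTruth(nClusters = 2L,
                            plantedPairs = data.frame(a = character(),
                                                      b = character(),
                                                      pattern = character()),
                            genesPerCategory = c(TF = 30L, effector = 30L,
                                                 RBP = 10L, other = 10L),
                            cellsPerCluster = 50L, seed = 1L)
    cells <- generateCounts(generateClusterMeans(truth)$means, truth)
    expect_identical(ncol(cells), 100L)
    tab <- table(clusterLabels(cells))
    expect_identical(as.integer(tab[c("C01", "C02")]), c(50L, 50L))
})

test_that("cluster means recomputed from counts track the generating profile", {
    truth <- syntheticTruth(nClusters = 4L, pairsPerPattern = 0L,
                            plantedPairs = data.frame(a = character(),
                                                      b = character(),
                                                      pattern = character()),
                            genesPerCategory = c(TF = 400L, effector = 400L,
                                                 RBP = 100L, other = 100L),
                            cellsPerCluster = 200L, seed = 4L)
    gm <- generateClusterMeans(truth)
    cells <- normalizeCells(generateCounts(gm$means, truth))
    rec <- clusterMeans(cells)
    lam <- profileMatrix(gm$means)
    for (k in rownames(lam)) {
        recovered <- expm1(profileMatrix(rec)[k, colnames(lam)])
        expect_gt(cor(log1p(recovered), log1p(lam[k, ])), 0.9)
    }
})

test_that("the large-dispersion limit is Poisson-like", {
    ratios <- numeric(10)
    for (s in 1:10) {
        truth <- syntheticTruth(nClusters = 2L,
                                plantedPairs = data.frame(a = character(),
                                                          b = character(),
                                                          pattern = character()),
                                genesPerCategory = c(TF = 50L, effector = 50L,
                                                     RBP = 20L, other = 20L),
                                cellsPerCluster = 150L, nbDispersion = 1e6,
                                librarySizeSdLog = 0, seed = s)
        cells <- generateCounts(generateClusterMeans(truth)$means, truth)
        cts <- as.matrix(SummarizedExperiment::assay(cells, "counts"))
        sub <- cts[, clusterLabels(cells) == "C01"]
        mu <- rowMeans(sub)
        keep <- mu > 0.5
        ratios[s] <- median(apply(sub[keep, ], 1, var) / mu[keep])
    }
    expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("infeasible truth configurations are rejected", {
    expect_error(syntheticTruth(nClusters = 4L, pairsPerPattern = 1L),
                 "planted clusters")
    expect_error(syntheticTruth(rhoSimilar = 0.5, rhoBackground = 0.6),
                 "rhoBackground")
    expect_error(syntheticTruth(nbDispersion = 0), "nbDispersion")
    expect_error(syntheticTruth(rbpOffset = 0.5), "rbpOffset")
})

test_that("recovery scoring counts planted pairs exactly", {
    truth <- syntheticTruth(seed = 1L)  # 9 planted pairs over 30 clusters
    pp <- plantedPairs(truth)
    pairs <- regpatterns:::allPairs(sprintf("C%02d", 1:30))
    perfect <- pairs
    perfect$pattern <- "unclassified"
    key <- regpatterns:::pairKey(pp$a, pp$b)
    perfect$pattern[match(key, perfect$pair)] <- pp$pattern
    pa <- methods::new("PatternAssignment", assignments = perfect,
                       provenance = "intersected")
    rec <- evaluateRecovery(pa, truth)
    expect_equal(rec$accuracy, 1)
    expect_equal(rec$perPattern$precision, rep(1, 3))
    expect_equal(rec$perPattern$recall, rep(1, 3))

    empty <- pairs; empty$pattern <- "unclassified"
    recEmpty <- evaluateRecovery(
        methods::new("PatternAssignment", assignments = empty,
                     provenance = "intersected"), truth)
    expect_equal(recEmpty$accuracy, 0)

    # 8 of 9 correct plus one spurious extra pair
    partial <- perfect
    partial$pattern[match(key[1], partial$pair)] <- "unclassified"  # drop one
    spare <- setdiff(partial$pair, key)[1]
    partial$pattern[match(spare, partial$pair)] <- pp$pattern[1]
    recPart <- evaluateRecovery(
        methods::new("PatternAssignment", assignments = partial,
                     provenance = "intersected"), truth)
    expect_equal(recPart$accuracy, 8 / 9)
})

test_that("planted pairs separate from the background distance population", {
    hits <- 0L
    for (s in 1:20) {
        truth <- syntheticTruth(seed = s)
        gm <- generateClusterMeans(truth)
        pm <- profileMatrix(gm$means)
        gs <- partitionGenes(gm$catalog, colnames(pm))
        pp <- plantedPairs(truth)
        ok <- TRUE
        for (block in c("TF", "effector")) {
            d <- distanceMatrix(profileDistance(gm$means, gs[[block]], block))
            q10 <- quantile(d[upper.tri(d)], 0.10)
            rel <- pp[pp$pattern == "matched" |
                      (pp$pattern == "divergent" & block == "TF") |
                      (pp$pattern == "convergent" & block == "effector"), ]
            for (i in seq_len(nrow(rel)))
                if (d[rel$a[i], rel$b[i]] >= q10) ok <- FALSE
        }
        hits <- hits + ok
    }
    expect_gte(hits, 19L)
})
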