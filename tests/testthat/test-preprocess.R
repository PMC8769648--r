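test_that("QC cell rules use strict boundaries", {
    nGenes <- 700
    counts <- matrix(0L, nGenes, 3,
                     dimnames = list(sprintf("g%03d", 1:nGenes),
                                     c("low", "boundary", "good")))
    counts[1:599, "low"] <- 1L                      # 599 UMIs -> removed
    counts[1:600, "boundary"] <- 1L                 # 600 UMIs, ratio 1 -> removed
    counts[1:600, "good"] <- 1L; counts[1:150, "good"] <- 2L  # 750/600 = 1.25
    cm <- CellMatrix(counts, c("A", "A", "A"))
    res <- qcFilter(cm, analysisConfig(qc = list(minCellsPerGene = 1L,
                                                 maxCellFractionPerGene = 1)))
    expect_identical(colnames(res$cells), "good")
    expect_identical(res$report$cellsRemoved$lowUmi, 1L)
    expect_identical(res$report$cellsRemoved$lowRatio, 2L)
})

test_that("QC gene rules use strict boundaries", {
    set.seed(1)
    nCells <- 40
    counts <- matrix(rpois(10 * nCells, 5), 10,
                     dimnames = list(sprintf("g%02d", 1:10),
                                     sprintf("c%03d", 1:nCells)))
    counts[counts == 0] <- 1L            # every gene in every cell
    counts["g01", ] <- 0L; counts["g01", 1:19] <- 1L  # 19 cells -> removed
    counts["g02", ] <- 0L; counts["g02", 1:20] <- 1L  # 20 cells -> kept
    counts["g03", ] <- 0L; counts["g03", 1:24] <- 1L  # 24/40 = 60% -> kept
    counts["g04", ] <- 0L; counts["g04", 1:25] <- 1L  # 25/40 > 60% -> removed
    cm <- CellMatrix(counts, rep("A", nCells))
    res <- qcFilter(cm, analysisConfig(qc = list(minUmi = 1,
                                                 minRatioUmiPerGene = 0,
                                                 minGenesPerCell = 1L)))
    kept <- rownames(res$cells)
    expect_false("g01" %in% kept)
    expect_true("g02" %in% kept)
    expect_true("g03" %in% kept)
    expect_false("g04" %in% kept)
})

test_that("a hand-built 5-cell matrix filters exactly as enumerated", {
    nGenes <- 30
    mkCell <- function(umisPerGene, nUsed) {
        v <- integer(nGenes); v[seq_len(nUsed)] <- umisPerGene; v
    }
    counts <- cbind(ok1 = mkCell(2L, 20),          # 40 UMIs, ratio 2
                    lowU = mkCell(1L, 9),          # 9 UMIs < 10
                    ok2 = mkCell(3L, 15),          # 45 UMIs, ratio 3
                    lowG = mkCell(10L, 3),         # 3 genes < 5
                    ok3 = mkCell(2L, 25))
    rownames(counts) <- sprintf("g%02d", seq_len(nGenes))
    mito <- counts; rownames(mito)[1] <- "mt-nd1"
    cm <- CellMatrix(counts, rep("A", 5))
    cfg <- analysisConfig(qc = list(minUmi = 10, minRatioUmiPerGene = 1.2,
                                    minGenesPerCell = 5L,
                                    minCellsPerGene = 1L,
                                    maxCellFractionPerGene = 1))
    res <- qcFilter(cm, cfg)
    expect_identical(sort(colnames(res$cells)), c("ok1", "ok2", "ok3"))
    expect_identical(res$report$cellsRemoved$total, 2L)
    expect_identical(res$report$cellsRemoved$lowUmi, 1L)
    expect_identical(res$report$cellsRemoved$fewGenes, 1L)
})

test_that("mitochondrial fraction rule removes high-mito cells", {
    counts <- matrix(5L, 20, 2, dimnames = list(
        c("mt-nd1", sprintf("g%02d", 1:19)), c("hiMito", "ok")))
    counts["mt-nd1", "hiMito"] <- 50L   # 50/145 ~ 34% mito
    counts["mt-nd1", "ok"] <- 2L        # 2/97 ~ 2%
    cm <- CellMatrix(counts, c("A", "A"))
    res <- qcFilter(cm, analysisConfig(qc = list(
        minUmi = 1, minRatioUmiPerGene = 0, minGenesPerCell = 1L,
        minCellsPerGene = 1L, maxCellFractionPerGene = 1)))
    expect_identical(colnames(res$cells), "ok")
    expect_identical(res$report$cellsRemoved$highMito, 1L)
})

test_that("normalization matches the closed form and an independent oracle", {
    counts <- matrix(c(10L, 0L), 2, 1,
                     dimnames = list(c("g1", "g2"), "c1"))
    cm <- normalizeCells(CellMatrix(counts, "A"))
    ln <- as.matrix(SummarizedExperiment::assay(cm, "logcounts"))
    expect_equal(ln["g1", 1], log(10001), tolerance = 1e-12)
    expect_equal(ln["g2", 1], 0)

    set.seed(7)
    r <- matrix(rpois(12, 4) + 1L, 4, 3,
                dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
    cmr <- normalizeCells(CellMatrix(r, rep("A", 3)))
    oracle <- r
    for (j in 1:3) for (i in 1:4)
        oracle[i, j] <- log1p(1e4 * r[i, j] / sum(r[, j]))
    expect_equal(as.matrix(SummarizedExperiment::assay(cmr, "logcounts")),
                 oracle, tolerance = 1e-12)

    # per-cell scaling: proportional cells normalize identically
    prop <- cbind(c1 = c(2L, 4L, 6L), c2 = c(4L, 8L, 12L))
    rownames(prop) <- paste0("g", 1:3)
    cmp <- normalizeCells(CellMatrix(prop, c("A", "A")))
    lnp <- as.matrix(SummarizedExperiment::assay(cmp, "logcounts"))
    expect_equal(lnp[, 1], lnp[, 2], tolerance = 1e-12)

    zero <- matrix(c(1L, 0L, 0L, 0L), 2)
    dimnames(zero) <- list(paste0("g", 1:2), paste0("c", 1:2))
    expect_error(normalizeCells(CellMatrix(zero, c("A", "A"))), "zero total")
})

test_that("variable-gene selection finds planted high-dispersion genes", {
    set.seed(42)
    nGenes <- 200; nCells <- 80
    counts <- matrix(rpois(nGenes * nCells, 2), nGenes,
                     dimnames = list(sprintf("g%03d", 1:nGenes),
                                     sprintf("c%03d", 1:nCells)))
    # same mean, inflated variance: mixture of 0 and large values
    counts["g001", ] <- ifelse(runif(nCells) < 0.9, 0L, 20L)
    counts["g002", ] <- 2L                      # constant gene
    counts["g003", ] <- 3000L                   # huge mean, beyond xHigh
    cm <- normalizeCells(CellMatrix(counts, rep("A", nCells)))
    expect_warning(hv <- selectVariableGenes(cm), "fewer genes than bins")
    expect_true("g001" %in% hv)
    expect_false("g002" %in% hv)
    expect_false("g003" %in% hv)
})

test_that("cluster means equal hand-computed values and ignore cell order", {
    counts <- matrix(c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L), 2,
                     dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
    cm <- normalizeCells(CellMatrix(counts, c("A", "A", "B", "B")))
    ln <- as.matrix(SummarizedExperiment::assay(cm, "logcounts"))
    means <- clusterMeans(cm)
    expect_equal(profileMatrix(means)["A", "g1"],
                 mean(ln["g1", 1:2]), tolerance = 1e-12)
    expect_equal(profileMatrix(means)["B", "g2"],
                 mean(ln["g2", 3:4]), tolerance = 1e-12)

    perm <- c(3, 1, 4, 2)
    cmp <- normalizeCells(CellMatrix(counts[, perm],
                                     c("A", "A", "B", "B")[perm]))
    expect_equal(profileMatrix(clusterMeans(cmp)), profileMatrix(means),
                 tolerance = 1e-12)

    single <- normalizeCells(CellMatrix(counts, c("A", "B", "B", "B")))
    lnS <- as.matrix(SummarizedExperiment::assay(single, "logcounts"))
    expect_equal(profileMatrix(clusterMeans(single))["A", ],
                 lnS[, 1], tolerance = 1e-12)

    expect_error(clusterMeans(cm, genes = c("g1", "nope")), "nope")
})

test_that("gene partitioning is an intersection with disjoint output", {
    gc <- GeneCatalog(c("g1", "g2", "g3"), c("TF", "effector", "RBP"))
    parts <- partitionGenes(gc, c("g1", "g2"))
    expect_identical(parts$TF, "g1")
    expect_identical(parts$effector, "g2")
    expect_identical(parts$RBP, character(0))
    expect_true(all(unlist(parts) %in% c("g1", "g2")))
    expect_error(partitionGenes(gc, c("g1", "gX")), "absent from catalog")
    gc2 <- GeneCatalog(c("g1", "g2"), c("TF", "RBP"))
    expect_error(partitionGenes(gc2, c("g1", "g2")), "empty TF or effector")
})

test_that("profile distance reproduces hand-computed values", {
    m <- rbind(A = c(1, 2, 3), B = c(1, 2, 3), C = c(3, 2, 1),
               D = c(1, 3, 2))
    colnames(m) <- paste0("g", 1:3)
    d <- distanceMatrix(profileDistance(ClusterMeanMatrix(m)))
    expect_equal(d["A", "B"], 0, tolerance = 1e-12)
    expect_equal(d["A", "C"], 1, tolerance = 1e-12)
    expect_equal(d["A", "D"], 0.25, tolerance = 1e-12)

    flat <- rbind(A = c(1, 1, 1), B = c(1, 2, 3))
    colnames(flat) <- paste0("g", 1:3)
    expect_error(profileDistance(ClusterMeanMatrix(flat)),
                 "zero-variance profile for cluster\\(s\\): A")
})

test_that("profile distance matches the two-pass Pearson oracle", {
    for (s in 1:25) {
        set.seed(s)
        m <- matrix(runif(50, 0, 5), 5,
                    dimnames = list(paste0("K", 1:5), paste0("g", 1:10)))
        d <- distanceMatrix(profileDistance(ClusterMeanMatrix(m)))
        expect_equal(d, profileDistanceOracle(m), tolerance = 1e-12)
        expect_equal(d, t(d))
        expect_true(all(diag(d) == 0))
        expect_true(all(d >= 0 & d <= 1))
    }
})

test_that("subsampled distance is deterministic and converges to the full one", {
    mm <- blockMeans(nGenes = 1000, withinNoise = 0.3, seed = 9)
    genes <- colnames(profileMatrix(mm))
    full <- distanceMatrix(profileDistance(mm, genes))
    s1 <- subsampledDistance(mm, genes, 0.8, 20L, seed = 11L)
    s2 <- subsampledDistance(mm, genes, 0.8, 20L, seed = 11L)
    s3 <- subsampledDistance(mm, genes, 0.8, 20L, seed = 12L)
    expect_identical(distanceMatrix(s1), distanceMatrix(s2))
    expect_false(identical(distanceMatrix(s1), distanceMatrix(s3)))
    ut <- upper.tri(full)
    expect_gt(cor(distanceMatrix(s1)[ut], full[ut]), 0.95)

    whole <- subsampledDistance(mm, genes, 1.0, 5L, seed = 1L)
    expect_equal(distanceMatrix(whole), full, tolerance = 1e-12)

    expect_error(subsampledDistance(mm, genes[1:3], 0.5, 5L, seed = 1L),
                 "fewer than 3 genes")
})
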