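test_that("conditional calls implement the lowest-10%/top-80% rank rule", {
    # n = 4: |S| = 5, similar iff rank <= ceiling(0.5) = 1 (strict minimum).
    # Distinct background distances so no tie ambiguity.
    d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    bg <- c(0.40, 0.41, 0.42, 0.43, 0.44)
    d["a", "b"] <- 0.05
    d["a", "c"] <- bg[1]; d["a", "d"] <- bg[2]; d["b", "c"] <- bg[3]
    d["b", "d"] <- bg[4]; d["c", "d"] <- bg[5]
    d <- d + t(d)
    calls <- callTable(similarityCalls(asDist(d)))
    expect_identical(calls$call[calls$pair == "a|b"], "similar")
    # every other pair: rank >= 2 > floor(0.2 * 5) = 1 -> dissimilar
    expect_true(all(calls$call[calls$pair != "a|b"] == "dissimilar"))
    expect_identical(unique(calls$refSize), 5L)
})

test_that("tied reference distances share the minimum rank (all similar)", {
    # with every distance involving c or d tied, (c,d) has rank 1 -> similar
    d <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    diag(d) <- 0
    d["a", "b"] <- d["b", "a"] <- 0.05
    calls <- callTable(similarityCalls(asDist(d)))
    expect_identical(calls$call[calls$pair == "c|d"], "similar")
    involving <- calls$pair %in% c("a|c", "a|d", "b|c", "b|d")
    expect_true(all(calls$call[involving] == "dissimilar"))
})

test_that("global mode ranks within all pair distances", {
    set.seed(1)
    d <- randomDistanceMatrix(4, seed = 2)
    calls <- callTable(similarityCalls(asDist(d), mode = "global"))
    # 6 pairs: ceiling(0.6) = 1 similar, rank > floor(1.2) = 1 dissimilar
    off <- sort(d[upper.tri(d)])
    expect_identical(sum(calls$call == "similar"), 1L)
    expect_identical(calls$call[which.min(calls$d)], "similar")
    expect_identical(sum(calls$call == "intermediate"), 0L)
})

test_that("similarity calls match the sort-and-rank brute force", {
    for (s in 1:50) {
        d <- randomDistanceMatrix(6, seed = s, ties = s %% 2 == 0)
        for (mode in c("conditional", "global")) {
            suppressWarnings({
                ours <- callTable(similarityCalls(asDist(d), mode = mode))
                oracle <- similarityOracle(d, mode = mode)
            })
            expect_identical(setNames(ours$call, ours$pair), oracle,
                             label = paste("seed", s, mode))
        }
    }
})

test_that("calls are monotone in the quantile parameters", {
    d <- randomDistanceMatrix(8, seed = 9)
    base <- callTable(similarityCalls(asDist(d), qLow = 0.10))
    wider <- callTable(similarityCalls(asDist(d), qLow = 0.20,
                                       qHighTop = 0.80))
    expect_true(all(base$pair[base$call == "similar"] %in%
                    wider$pair[wider$call == "similar"]))
    moreDis <- callTable(similarityCalls(asDist(d), qLow = 0.10,
                                         qHighTop = 0.90))
    expect_true(all(base$pair[base$call == "dissimilar"] %in%
                    moreDis$pair[moreDis$call == "dissimilar"]))
})

test_that("degenerate constant distances warn and tie every pair as similar", {
    d <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    diag(d) <- 0
    expect_warning(calls <- similarityCalls(asDist(d)), "degenerate")
    expect_true(all(callTable(calls)$call == "similar"))
})

test_that("pattern classification follows the two-axis rule table", {
    mkCalls <- function(callVec, tag) {
        pairs <- regpatterns:::allPairs(letters[1:4])
        methods::new("SimilarityCalls",
            calls = data.frame(pair = pairs$pair, a = pairs$a, b = pairs$b,
                               d = 0.5, rank = 1L, refSize = 5L,
                               call = callVec),
            geneSetTag = tag, mode = "conditional", qLow = 0.1,
            qHighTop = 0.8)
    }
    eff <- mkCalls(c("similar", "similar", "dissimilar", "intermediate",
                     "dissimilar", "similar"), "effector")
    tf <- mkCalls(c("similar", "dissimilar", "similar", "similar",
                    "intermediate", "intermediate"), "TF")
    pat <- patternTable(classifyPatterns(eff, tf))
    expect_identical(pat$pattern,
                     c("matched", "convergent", "divergent", "unclassified",
                       "unclassified", "unclassified"))
    # mutually exclusive and exhaustive by construction
    expect_identical(anyDuplicated(pat$pair), 0L)

    effShort <- mkCalls(rep("similar", 6), "effector")
    effShort@calls <- effShort@calls[-1, ]
    expect_error(classifyPatterns(effShort, tf), "only one call set")
})

test_that("sister pattern analysis performs cherry set arithmetic", {
    tr <- randomTree(6, seed = 2)
    same <- patternTable(sisterPatternAnalysis(tr, tr))
    cherries <- sisterPairs(tr)$pair
    expect_true(all(same$pattern[same$pair %in% cherries] == "matched"))
    expect_true(all(same$pattern[!same$pair %in% cherries] == "unclassified"))

    effSis <- data.frame(pair = c("a|b", "c|d"), a = c("a", "c"),
                         b = c("b", "d"))
    tfSis <- data.frame(pair = c("a|b", "c|e"), a = c("a", "c"),
                        b = c("b", "e"))
    pat <- patternTable(sisterPatternAnalysis(effSis, tfSis))
    lookup <- setNames(pat$pattern, pat$pair)
    expect_identical(unname(lookup["a|b"]), "matched")
    expect_identical(unname(lookup["c|d"]), "convergent")
    expect_identical(unname(lookup["c|e"]), "divergent")
})

test_that("one shared cherry among eleven yields 1 matched, 10 convergent", {
    ids <- sprintf("L%02d", 1:22)
    effSis <- data.frame(a = ids[seq(1, 22, 2)], b = ids[seq(2, 22, 2)])
    effSis$pair <- regpatterns:::pairKey(effSis$a, effSis$b)
    tfSis <- effSis[1, ]
    pat <- patternTable(sisterPatternAnalysis(
        effSis, rbind(tfSis)))
    expect_identical(sum(pat$pattern == "matched"), 1L)
    expect_identical(sum(pat$pattern == "convergent"), 10L)
    expect_identical(sum(pat$pattern == "divergent"), 0L)
})

test_that("intersection keeps a pattern only on exact agreement", {
    mkPa <- function(patterns, prov) {
        pairs <- regpatterns:::allPairs(letters[1:4])
        methods::new("PatternAssignment",
            assignments = data.frame(pair = pairs$pair, a = pairs$a,
                                     b = pairs$b, pattern = patterns),
            provenance = prov)
    }
    pop <- mkPa(c("matched", "convergent", "unclassified", "convergent",
                  "divergent", "unclassified"), "population")
    sis <- mkPa(c("matched", "divergent", "unclassified", "unclassified",
                  "divergent", "convergent"), "sister")
    out <- patternTable(intersectPatterns(pop, sis))
    expect_identical(out$pattern,
                     c("matched", "unclassified", "unclassified",
                       "unclassified", "divergent", "unclassified"))
    expect_identical(patternTable(intersectPatterns(pop, pop))$pattern,
                     patternTable(pop)$pattern)
})

test_that("planted patterns are recovered end-to-end on generated profiles", {
    perPattern <- c(matched = 0L, convergent = 0L, divergent = 0L)
    mislabels <- 0L
    for (s in 1:5) {
        truth <- syntheticTruth(nClusters = 12L, pairsPerPattern = 1L,
                                seed = s)
        gm <- generateClusterMeans(truth)
        gs <- partitionGenes(gm$catalog, colnames(profileMatrix(gm$means)))
        res <- regpatterns:::classifyFromDistances(
            profileDistance(gm$means, gs$effector, "effector"),
            profileDistance(gm$means, gs$TF, "TF"))
        tab <- patternTable(res$intersected)
        pp <- plantedPairs(truth)
        got <- tab$pattern[match(regpatterns:::pairKey(pp$a, pp$b), tab$pair)]
        for (i in seq_along(got)) {
            if (got[i] == pp$pattern[i])
                perPattern[pp$pattern[i]] <- perPattern[pp$pattern[i]] + 1L
            else if (got[i] != "unclassified") mislabels <- mislabels + 1L
        }
    }
    # a planted pair may fall in the rank gray zone (-> unclassified) but is
    # never assigned a wrong pattern after intersection
    expect_identical(mislabels, 0L)
    expect_identical(perPattern[["matched"]], 5L)
    expect_gte(perPattern[["convergent"]], 3L)
    expect_gte(perPattern[["divergent"]], 3L)
})

test_that("robustness concordance is 1 at fraction 1 and honest under noise", {
    truth <- syntheticTruth(nClusters = 12L, pairsPerPattern = 1L, seed = 3L)
    gm <- generateClusterMeans(truth)
    gs <- partitionGenes(gm$catalog, colnames(profileMatrix(gm$means)))
    rb <- robustnessCheck(gm$means, gs$TF, gs$effector, fraction = 1.0,
                          reps = 3L, seed = 1L)
    expect_true(all(rb$concordance == 1))

    # weak planted signal: concordance reported below 1 in at least one seed
    anyBelow <- FALSE
    for (s in 1:5) {
        weak <- syntheticTruth(nClusters = 12L, pairsPerPattern = 1L,
                               rhoSimilar = 0.55,
                               genesPerCategory = c(TF = 50L, effector = 50L,
                                                    RBP = 20L, other = 20L),
                               nRbpDiffGenes = 5L, seed = s)
        gmW <- generateClusterMeans(weak)
        gsW <- partitionGenes(gmW$catalog,
                              colnames(profileMatrix(gmW$means)))
        rbW <- robustnessCheck(gmW$means, gsW$TF, gsW$effector, seed = s)
        if (any(rbW$concordance < 1)) anyBelow <- TRUE
    }
    expect_true(anyBelow)
})

test_that("vote-mode robustness returns a modal classification", {
    truth <- syntheticTruth(nClusters = 10L, pairsPerPattern = 1L, seed = 8L)
    gm <- generateClusterMeans(truth)
    gs <- partitionGenes(gm$catalog, colnames(profileMatrix(gm$means)))
    rb <- robustnessCheck(gm$means, gs$TF, gs$effector, reps = 5L,
                          seed = 2L, mode = "vote")
    expect_true(all(patternTable(rb$subsampled)$pattern %in%
                    c("matched", "convergent", "divergent", "unclassified")))
    expect_named(rb$concordance)
})
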