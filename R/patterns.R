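#' Population-level similarity calls from a distance matrix
#'
#' For every unordered cluster pair `(i, j)` the pair's distance is ranked
#' (ascending competition ranks; tied distances share the minimum rank)
#' within a reference set `S`:
#' * `mode = "conditional"` (default): `S` is every distance involving `i` or
#'   `j`, including `d(i, j)` itself, so `|S| = 2(n - 2) + 1`;
#' * `mode = "global"`: `S` is all `n(n - 1)/2` pair distances.
#'
#' The pair is called `similar` when its rank is at most
#' `ceiling(qLow * |S|)` (the lowest-`qLow` zone), `dissimilar` when its rank
#' exceeds `floor((1 - qHighTop) * |S|)` (the top-`qHighTop` zone), and
#' `intermediate` otherwise. With the defaults (`qLow = 0.10`,
#' `qHighTop = 0.80`) the gray zone between the 10% and 20% boundaries can
#' never support a pattern. A constant distance matrix ties every pair at
#' rank 1 -- all pairs become similar -- and emits a degenerate-input warning.
#'
#' `perClusterRule = TRUE` switches to the stricter reading in which the rank
#' condition must hold within each member cluster's own distance set
#' separately.
#'
#' @param dist a [PairwiseDistance-class] over >= 4 clusters.
#' @param qLow similar-zone quantile.
#' @param qHighTop dissimilar-zone quantile (zone is the top `qHighTop`).
#' @param mode reference-set mode, `"conditional"` or `"global"`.
#' @param perClusterRule require the rank rule per member cluster (AND).
#' @return a [SimilarityCalls-class].
#' @export
similarityCalls <- function(dist, qLow = 0.10, qHighTop = 0.80,
                            mode = c("conditional", "global"),
                            perClusterRule = FALSE) {
    mode <- match.arg(mode)
    if (qLow > 1 - qHighTop + 1e-9)
        stop("similar and dissimilar zones overlap: need qLow <= 1 - qHighTop")
    d <- distanceMatrix(dist)
    n <- nrow(d)
    if (n < 4L) stop("need >= 4 clusters for population-level calls")
    ids <- rownames(d)
    pairs <- allPairs(ids)
    off <- d[upper.tri(d)]
    if (length(unique(off)) == 1L)
        warning("degenerate distance matrix: all pairs tied; every pair ",
                "will be called similar under competition ranking")

    compRank <- function(value, set) sum(set < value) + 1L

    callOne <- function(a, b) {
        dij <- d[a, b]
        if (mode == "global") {
            S <- off
            r <- compRank(dij, S)
            sz <- length(S)
            sim <- r <= ceiling(qLow * sz)
            dis <- r > floor((1 - qHighTop) * sz)
        } else if (!perClusterRule) {
            S <- c(d[a, setdiff(ids, a)], d[b, setdiff(ids, c(a, b))])
            r <- compRank(dij, S)
            sz <- length(S)
            sim <- r <= ceiling(qLow * sz)
            dis <- r > floor((1 - qHighTop) * sz)
        } else {
            Sa <- d[a, setdiff(ids, a)]
            Sb <- d[b, setdiff(ids, b)]
            ra <- compRank(dij, Sa); rb <- compRank(dij, Sb)
            sim <- ra <= ceiling(qLow * length(Sa)) &&
                   rb <= ceiling(qLow * length(Sb))
            dis <- ra > floor((1 - qHighTop) * length(Sa)) &&
                   rb > floor((1 - qHighTop) * length(Sb))
            r <- max(ra, rb); sz <- length(Sa)
        }
        call <- if (sim) "similar" else if (dis) "dissimilar" else "intermediate"
        list(d = dij, rank = r, refSize = sz, call = call)
    }

    res <- Map(callOne, pairs$a, pairs$b)
    calls <- data.frame(pair = pairs$pair, a = pairs$a, b = pairs$b,
                        d = vapply(res, `[[`, 1.0, "d"),
                        rank = vapply(res, `[[`, 1L, "rank"),
                        refSize = vapply(res, `[[`, 1L, "refSize"),
                        call = vapply(res, `[[`, "", "call"))
    rownames(calls) <- NULL
    methods::new("SimilarityCalls", calls = calls,
                 geneSetTag = geneSetTag(dist), mode = mode,
                 qLow = qLow, qHighTop = qHighTop)
}

#' Classify cluster pairs as matched / convergent / divergent
#'
#' Combines the similarity calls from the effector-gene and TF distance
#' matrices: `matched` = similar in both; `convergent` = similar in effector
#' genes and dissimilar in TFs; `divergent` = dissimilar in effector genes
#' and similar in TFs; every other combination -- including any intermediate
#' call -- is `unclassified` (a conservative rule: a gray-zone call never
#' supports a pattern).
#'
#' @param effCalls,tfCalls [SimilarityCalls-class] objects over the same
#'   cluster pairs (effector-gene-based and TF-based).
#' @return a [PatternAssignment-class] with provenance `"population"`.
#' @export
classifyPatterns <- function(effCalls, tfCalls) {
    eff <- callTable(effCalls); tf <- callTable(tfCalls)
    if (!setequal(eff$pair, tf$pair)) {
        only <- c(setdiff(eff$pair, tf$pair), setdiff(tf$pair, eff$pair))
        stop("pair(s) present in only one call set: ",
             paste(head(only, 5L), collapse = ", "))
    }
    tf <- tf[match(eff$pair, tf$pair), ]
    pattern <- ifelse(eff$call == "similar" & tf$call == "similar", "matched",
               ifelse(eff$call == "similar" & tf$call == "dissimilar", "convergent",
               ifelse(eff$call == "dissimilar" & tf$call == "similar", "divergent",
                      "unclassified")))
    out <- data.frame(pair = eff$pair, a = eff$a, b = eff$b,
                      pattern = pattern, effCall = eff$call, tfCall = tf$call)
    methods::new("PatternAssignment", assignments = out,
                 provenance = "population")
}

#' Sister-cluster (cherry) pattern analysis
#'
#' Classifies pairs by cherry co-occurrence in the two Ward trees: a pair
#' that is a cherry in both trees is `matched`; a cherry of the effector tree
#' only is `convergent`; a cherry of the TF tree only is `divergent`. All
#' remaining pairs over the shared leaf set are `unclassified`.
#'
#' @param effTree,tfTree [stats::hclust] trees over the same clusters
#'   (effector-gene-based and TF-based), or data.frames from [sisterPairs()].
#' @return a [PatternAssignment-class] with provenance `"sister"`.
#' @export
sisterPatternAnalysis <- function(effTree, tfTree) {
    effSis <- if (inherits(effTree, "hclust")) sisterPairs(effTree) else effTree
    tfSis <- if (inherits(tfTree, "hclust")) sisterPairs(tfTree) else tfTree
    ids <- if (inherits(effTree, "hclust")) effTree$labels
           else unique(c(effSis$a, effSis$b, tfSis$a, tfSis$b))
    if (inherits(tfTree, "hclust") && !setequal(ids, tfTree$labels))
        stop("the two trees must cover the same clusters")
    pairs <- allPairs(ids)
    inEff <- pairs$pair %in% effSis$pair
    inTf <- pairs$pair %in% tfSis$pair
    pattern <- ifelse(inEff & inTf, "matched",
               ifelse(inEff, "convergent",
               ifelse(inTf, "divergent", "unclassified")))
    out <- data.frame(pair = pairs$pair, a = pairs$a, b = pairs$b,
                      pattern = pattern)
    methods::new("PatternAssignment", assignments = out, provenance = "sister")
}

#' Intersect population-level and sister-cluster assignments
#'
#' A pair keeps a pattern only when both strategies assign it that same
#' pattern; any disagreement (including one side unclassified) yields
#' `unclassified`. Intersection requires pattern equality, not mere
#' co-occurrence of the pair.
#'
#' @param population,sister [PatternAssignment-class] objects over the same
#'   pairs.
#' @return a [PatternAssignment-class] with provenance `"intersected"`.
#' @export
intersectPatterns <- function(population, sister) {
    p <- patternTable(population); s <- patternTable(sister)
    if (!setequal(p$pair, s$pair))
        stop("assignments must cover the same cluster pairs")
    s <- s[match(p$pair, s$pair), ]
    pattern <- ifelse(p$pattern == s$pattern, p$pattern, "unclassified")
    pattern[pattern == "unclassified"] <- "unclassified"
    out <- data.frame(pair = p$pair, a = p$a, b = p$b, pattern = pattern)
    if (!is.null(p$effCall)) { out$effCall <- p$effCall; out$tfCall <- p$tfCall }
    methods::new("PatternAssignment", assignments = out,
                 provenance = "intersected")
}

# Population + sister + intersection in one step, from two distances.
classifyFromDistances <- function(effDist, tfDist, qLow = 0.10,
                                  qHighTop = 0.80, mode = "conditional") {
    effCalls <- similarityCalls(effDist, qLow, qHighTop, mode)
    tfCalls <- similarityCalls(tfDist, qLow, qHighTop, mode)
    population <- classifyPatterns(effCalls, tfCalls)
    sister <- sisterPatternAnalysis(wardTree(effDist), wardTree(tfDist))
    list(population = population, sister = sister,
         intersected = intersectPatterns(population, sister),
         effCalls = effCalls, tfCalls = tfCalls)
}

#' Gene-subsampling robustness of the pattern classification
#'
#' Recomputes the population-level classification from subsample-averaged
#' distances ([subsampledDistance()]; `mode = "average"`, the default) or
#' from a per-repetition majority vote of classifications
#' (`mode = "vote"`), and reports the per-pattern concordance with the
#' full-gene run: the fraction of pairs carrying each pattern in the full run
#' that carry the same pattern in the subsampled run.
#'
#' @param means a [ClusterMeanMatrix-class].
#' @param tfGenes,effGenes the two gene sets.
#' @param fraction fraction of genes per draw.
#' @param reps subsampling repetitions.
#' @param seed integer seed.
#' @param qLow,qHighTop,callMode parameters passed to [similarityCalls()].
#' @param mode `"average"` (average distances, then classify) or `"vote"`
#'   (classify per repetition, then take the modal pattern).
#' @return list with `full` and `subsampled` (population-level
#'   [PatternAssignment-class]s) and `concordance`, a named vector over
#'   patterns present in the full run.
#' @export
robustnessCheck <- function(means, tfGenes, effGenes, fraction = 0.8,
                            reps = 20L, seed = 1L, qLow = 0.10,
                            qHighTop = 0.80, callMode = "conditional",
                            mode = c("average", "vote")) {
    mode <- match.arg(mode)
    effFull <- profileDistance(means, effGenes, "effector")
    tfFull <- profileDistance(means, tfGenes, "TF")
    full <- classifyPatterns(
        similarityCalls(effFull, qLow, qHighTop, callMode),
        similarityCalls(tfFull, qLow, qHighTop, callMode))

    if (mode == "average") {
        effSub <- subsampledDistance(means, effGenes, fraction, reps,
                                     deriveSeed(seed, "eff"), "effector")
        tfSub <- subsampledDistance(means, tfGenes, fraction, reps,
                                    deriveSeed(seed, "tf"), "TF")
        sub <- classifyPatterns(
            similarityCalls(effSub, qLow, qHighTop, callMode),
            similarityCalls(tfSub, qLow, qHighTop, callMode))
    } else {
        votes <- withSeed(seed, {
            lapply(seq_len(reps), function(r) {
                eg <- sample(effGenes, floor(fraction * length(effGenes)))
                tg <- sample(tfGenes, floor(fraction * length(tfGenes)))
                pa <- classifyPatterns(
                    similarityCalls(profileDistance(means, eg, "effector"),
                                    qLow, qHighTop, callMode),
                    similarityCalls(profileDistance(means, tg, "TF"),
                                    qLow, qHighTop, callMode))
                patternTable(pa)$pattern
            })
        })
        tab <- patternTable(full)
        voteMat <- do.call(cbind, votes)
        modal <- apply(voteMat, 1L, function(v) names(which.max(table(v))))
        sub <- methods::new("PatternAssignment",
            assignments = data.frame(pair = tab$pair, a = tab$a, b = tab$b,
                                     pattern = modal),
            provenance = "population")
    }

    fullTab <- patternTable(full); subTab <- patternTable(sub)
    subTab <- subTab[match(fullTab$pair, subTab$pair), ]
    pats <- setdiff(unique(fullTab$pattern), character(0))
    concordance <- vapply(pats, function(p) {
        idx <- fullTab$pattern == p
        mean(subTab$pattern[idx] == p)
    }, 1.0)
    list(full = full, subsampled = sub, concordance = concordance)
}
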