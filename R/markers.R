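#' Differential expression between two cell groups
#'
#' Candidate genes must be expressed (raw count > 0) in at least `minPct` of
#' the cells of one group and differ in expressing fraction by at least
#' `minDiffPct`; surviving genes are tested by a two-sided Wilcoxon rank-sum
#' test on the log-normalized values (exact for small tie-free samples,
#' normal approximation with tie correction otherwise) and
#' Bonferroni-adjusted over the genes actually tested -- never over the full
#' panel. Rows are sorted by `(p_adj, -|mean_log_diff|)`;
#' `mean_log_diff` is the difference of group means on the normalized layer
#' (a simple monotone surrogate for a log fold change, not identical to
#' Seurat's `avg_logFC`).
#'
#' @param x a normalized [CellMatrix-class].
#' @param groupA,groupB cluster ids (vectors allowed) naming the two groups;
#'   each group needs >= 3 cells for the rank test.
#' @param minPct minimum expressing fraction in the higher group.
#' @param minDiffPct minimum difference in expressing fractions.
#' @param genes optional gene universe to restrict to.
#' @return data.frame with columns `gene_id`, `group_a`, `group_b`,
#'   `mean_log_diff`, `pct_a`, `pct_b`, `p`, `p_adj`.
#' @export
findMarkersPair <- function(x, groupA, groupB, minPct = 0.1,
                            minDiffPct = 0.25, genes = NULL) {
    cl <- clusterLabels(x)
    idxA <- which(cl %in% groupA)
    idxB <- which(cl %in% groupB)
    if (length(idxA) < 3L || length(idxB) < 3L)
        stop("each group needs >= 3 cells for the rank-sum test")
    cts <- umiCounts(x); ln <- logNorm(x)
    if (!is.null(genes)) {
        missing <- setdiff(genes, rownames(cts))
        if (length(missing))
            stop("gene(s) absent: ", paste(head(missing, 5L), collapse = ", "))
        cts <- cts[genes, , drop = FALSE]; ln <- ln[genes, , drop = FALSE]
    }
    pctA <- Matrix::rowMeans(cts[, idxA, drop = FALSE] > 0)
    pctB <- Matrix::rowMeans(cts[, idxB, drop = FALSE] > 0)
    keep <- pmax(pctA, pctB) >= minPct & abs(pctA - pctB) >= minDiffPct
    tested <- which(keep)
    if (!length(tested))
        return(data.frame(gene_id = character(), group_a = character(),
                          group_b = character(), mean_log_diff = numeric(),
                          pct_a = numeric(), pct_b = numeric(),
                          p = numeric(), p_adj = numeric()))
    lnA <- as.matrix(ln[tested, idxA, drop = FALSE])
    lnB <- as.matrix(ln[tested, idxB, drop = FALSE])
    p <- vapply(seq_along(tested), function(i)
        suppressWarnings(wilcox.test(lnA[i, ], lnB[i, ])$p.value), 1.0)
    res <- data.frame(
        gene_id = rownames(cts)[tested],
        group_a = paste(groupA, collapse = "+"),
        group_b = paste(groupB, collapse = "+"),
        mean_log_diff = rowMeans(lnA) - rowMeans(lnB),
        pct_a = pctA[tested], pct_b = pctB[tested],
        p = p, p_adj = p.adjust(p, method = "bonferroni"))
    res <- res[order(res$p_adj, -abs(res$mean_log_diff)), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' One-vs-rest marker detection for every cluster
#'
#' Runs [findMarkersPair()] for each cluster against all remaining cells.
#'
#' @inheritParams findMarkersPair
#' @return named list of data.frames, one per cluster.
#' @export
findAllClusterMarkers <- function(x, minPct = 0.1, minDiffPct = 0.25,
                                  genes = NULL) {
    ids <- sort(unique(clusterLabels(x)))
    setNames(lapply(ids, function(k)
        findMarkersPair(x, k, setdiff(ids, k), minPct, minDiffPct, genes)),
        ids)
}

#' Top-k markers from a differential result
#'
#' Ranking: ascending adjusted p, ties broken by descending mean log
#' difference (the table order produced by [findMarkersPair()]).
#'
#' @param result a data.frame from [findMarkersPair()].
#' @param k maximum number of markers.
#' @param positiveOnly keep only genes enriched in group A.
#' @param alpha significance cutoff on `p_adj`.
#' @return character vector of at most `k` gene ids.
#' @export
topMarkers <- function(result, k = 20L, positiveOnly = TRUE, alpha = 0.05) {
    keep <- result$p_adj < alpha
    if (positiveOnly) keep <- keep & result$mean_log_diff > 0
    head(result$gene_id[keep], k)
}

#' Region-specific markers shared by all cell types
#'
#' Within each requested cell type, every region is tested one-vs-rest
#' (cells of that type in the region against cells of that type elsewhere);
#' a gene is a region-specific marker iff it is a significant, positively
#' enriched marker of that region in every cell type. A missing
#' (region, cell type) stratum is an error unless `allowPartial = TRUE`, in
#' which case the stratum is skipped with a warning and the intersection
#' taken over the remaining cell types.
#'
#' @param x a normalized [CellMatrix-class].
#' @param regionLabels,typeLabels per-cell region and cell-type labels.
#' @param types cell types to use (default: all).
#' @param allowPartial skip missing strata instead of failing.
#' @param minPct,minDiffPct,alpha DE parameters.
#' @return named list: region -> character vector of marker gene ids.
#' @export
regionSpecificMarkers <- function(x, regionLabels, typeLabels, types = NULL,
                                  allowPartial = FALSE, minPct = 0.1,
                                  minDiffPct = 0.25, alpha = 0.05) {
    stopifnot(length(regionLabels) == ncol(x), length(typeLabels) == ncol(x))
    regions <- sort(unique(regionLabels))
    if (is.null(types)) types <- sort(unique(typeLabels))
    out <- list()
    for (r in regions) {
        perType <- list()
        for (t in types) {
            inStratum <- typeLabels == t & regionLabels == r
            outStratum <- typeLabels == t & regionLabels != r
            if (sum(inStratum) < 3L || sum(outStratum) < 3L) {
                msg <- sprintf("stratum (region %s, type %s) too small", r, t)
                if (allowPartial) { warning(msg, "; skipped"); next }
                stop(msg)
            }
            sub <- CellMatrix(umiCounts(x),
                              ifelse(inStratum, "IN", "OUT"),
                              normalized = logNorm(x),
                              datasetTag = datasetTag(x))
            de <- findMarkersPair(sub, "IN", "OUT", minPct, minDiffPct)
            perType[[t]] <- de$gene_id[de$p_adj < alpha & de$mean_log_diff > 0]
        }
        out[[r]] <- if (length(perType)) Reduce(intersect, perType) else character()
    }
    out
}

#' Assign identities to clusters by marker expression
#'
#' A cluster is assigned iff strictly more than `minPct` of its cells express
#' at least one of the marker genes (raw count > 0), or the mean total marker
#' UMI over the expressing cells strictly exceeds `minMeanUmi`. Both
#' inequalities are strict ("over 5%", "over 2").
#'
#' @param x a [CellMatrix-class].
#' @param markerGenes non-empty character vector of marker gene ids.
#' @param minPct expressing-fraction threshold.
#' @param minMeanUmi mean-UMI-over-expressing-cells threshold.
#' @return data.frame with per-cluster `pctExpressing`, `meanUmiExpressing`
#'   and the boolean `assigned`.
#' @export
assignIdentity <- function(x, markerGenes, minPct = 0.05, minMeanUmi = 2.0) {
    if (!length(markerGenes)) stop("marker gene set is empty")
    missing <- setdiff(markerGenes, rownames(x))
    if (length(missing))
        stop("marker gene(s) absent: ", paste(missing, collapse = ", "))
    cts <- umiCounts(x)[markerGenes, , drop = FALSE]
    cl <- clusterLabels(x)
    ids <- sort(unique(cl))
    markerUmi <- Matrix::colSums(cts)
    expressing <- markerUmi > 0
    out <- do.call(rbind, lapply(ids, function(k) {
        inK <- cl == k
        pct <- mean(expressing[inK])
        meanUmi <- if (any(expressing & inK))
            mean(markerUmi[expressing & inK]) else 0
        data.frame(cluster = k, pctExpressing = pct,
                   meanUmiExpressing = meanUmi,
                   assigned = pct > minPct || meanUmi > minMeanUmi)
    }))
    rownames(out) <- NULL
    out
}
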