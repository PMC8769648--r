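#' Pattern-specific RNA-binding-protein markers
#'
#' For every classified cluster pair, the differential RBPs are the
#' significant genes of its differential-expression result (`p_adj < alpha`,
#' after the min.pct / min.diff.pct filters applied upstream) whose catalog
#' category is RBP. An RBP is specific to pattern P iff it is differential in
#' at least one pair of pattern P and in no pair of any other pattern, so the
#' pattern-specific sets are pairwise disjoint by construction.
#'
#' @param assignment a [PatternAssignment-class]; only pairs with a pattern
#'   (not `unclassified`) are used, and each must have a DE result.
#' @param deResults named list of data.frames from [findMarkersPair()], named
#'   by canonical pair key (`"a|b"`).
#' @param catalog a [GeneCatalog-class].
#' @param alpha significance cutoff on `p_adj`.
#' @return list of class `"RbpPatternReport"`: `perPair` (pair -> RBP ids),
#'   `pairPattern` (pair -> pattern), `patternSpecific` (pattern -> RBP ids),
#'   `reuse` (data.frame: rbp, nPairs), `rbpsPerPair` (data.frame by pattern).
#' @export
patternSpecificRbps <- function(assignment, deResults, catalog, alpha = 0.05) {
    tab <- patternTable(assignment)
    tab <- tab[tab$pattern != "unclassified", , drop = FALSE]
    missing <- setdiff(tab$pair, names(deResults))
    if (length(missing))
        stop("classified pair(s) without a DE result: ",
             paste(missing, collapse = ", "))
    rbps <- rbpGenes(catalog)
    perPair <- lapply(setNames(tab$pair, tab$pair), function(p) {
        de <- deResults[[p]]
        intersect(de$gene_id[de$p_adj < alpha], rbps)
    })
    pairPattern <- setNames(tab$pattern, tab$pair)
    byPattern <- lapply(split(perPair, pairPattern[names(perPair)]),
                        function(l) unique(unlist(l)))
    pats <- names(byPattern)
    patternSpecific <- lapply(setNames(pats, pats), function(p) {
        others <- unique(unlist(byPattern[setdiff(pats, p)]))
        setdiff(byPattern[[p]], others)
    })
    usage <- unlist(lapply(perPair, unique))
    reuse <- if (length(usage)) {
        cnt <- table(usage)
        data.frame(rbp = names(cnt), nPairs = as.integer(cnt))
    } else data.frame(rbp = character(), nPairs = integer())
    rbpsPerPair <- data.frame(
        pair = names(perPair),
        pattern = unname(pairPattern[names(perPair)]),
        nRbps = vapply(perPair, length, 1L))
    rownames(rbpsPerPair) <- NULL
    structure(list(perPair = perPair, pairPattern = pairPattern,
                   patternSpecific = patternSpecific, reuse = reuse,
                   rbpsPerPair = rbpsPerPair),
              class = "RbpPatternReport")
}

#' @export
print.RbpPatternReport <- function(x, ...) {
    cat("RbpPatternReport:", length(x$perPair), "pairs;",
        nrow(x$reuse), "distinct differential RBPs\n")
    for (p in names(x$patternSpecific))
        cat("  ", p, "-specific RBPs: ", length(x$patternSpecific[[p]]),
            "\n", sep = "")
    invisible(x)
}

#' RBP reuse frequency across cluster pairs
#'
#' Fraction of the distinct differential RBPs (over all pairs jointly) that
#' are differential in two or more pairs.
#'
#' @param perPairRbps list of per-pair differential RBP id vectors (e.g. the
#'   `perPair` element of [patternSpecificRbps()]).
#' @return list with `fraction`, `nReused`, `nTotal` and the `counts` table.
#' @export
rbpReuseFrequency <- function(perPairRbps) {
    if (!length(perPairRbps)) stop("need >= 1 pair")
    usage <- unlist(lapply(perPairRbps, unique))
    if (!length(usage))
        return(list(fraction = NA_real_, nReused = 0L, nTotal = 0L,
                    counts = table(character())))
    cnt <- table(usage)
    list(fraction = sum(cnt >= 2L) / length(cnt),
         nReused = sum(cnt >= 2L), nTotal = length(cnt), counts = cnt)
}

#' Target-category proportions of pattern-specific RBPs
#'
#' Pools, per pattern, all target rows of that pattern's RBPs from the
#' RBP -> target table and reports the proportion of rows falling in each
#' catalog category of the target gene. An RBP absent from the table is
#' excluded with a warning; a pattern whose RBPs are all absent gets `NA`
#' proportions and is flagged `undefined` rather than reported as zero.
#'
#' @param rbpSets named list: pattern -> RBP gene ids.
#' @param targets data.frame with `rbp_gene_id`, `target_gene_id` (see
#'   [readRbpTargets()]).
#' @param catalog a [GeneCatalog-class] supplying target categories.
#' @return data.frame with one row per (pattern, category) plus a per-pattern
#'   `undefined` flag in attribute `"undefined"`.
#' @export
targetCategoryProportions <- function(rbpSets, targets, catalog) {
    if (!nrow(targets)) stop("target table is empty")
    cat_ <- geneCategory(catalog)
    undefined <- logical(0)
    rows <- list()
    for (p in names(rbpSets)) {
        rbps <- rbpSets[[p]]
        absent <- setdiff(rbps, unique(targets$rbp_gene_id))
        if (length(absent))
            warning(length(absent), " RBP(s) of pattern ", p,
                    " absent from the target table; excluded")
        sub <- targets[targets$rbp_gene_id %in% rbps, , drop = FALSE]
        undefined[p] <- nrow(sub) == 0L
        if (undefined[p]) {
            rows[[p]] <- data.frame(pattern = p, category = .geneCategories,
                                    proportion = NA_real_, nRows = 0L)
            next
        }
        tcat <- cat_[sub$target_gene_id]
        tcat[is.na(tcat)] <- "other"
        tab <- table(factor(tcat, levels = .geneCategories))
        rows[[p]] <- data.frame(pattern = p, category = names(tab),
                                proportion = as.numeric(tab) / nrow(sub),
                                nRows = as.integer(tab))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "undefined") <- undefined
    out
}
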