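# Internal helpers shared across modules.

# Canonical unordered pair key: members sorted, joined by "|".
pairKey <- function(a, b) {
    stopifnot(length(a) == length(b))
    if (any(a == b)) stop("a pair must join two distinct clusters")
    paste(pmin(a, b), pmax(a, b), sep = "|")
}

pairMembers <- function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)
    data.frame(a = vapply(parts, `[`, "", 1L),
               b = vapply(parts, `[`, "", 2L))
}

# All unordered pairs over a set of cluster ids, canonical order.
allPairs <- function(ids) {
    ids <- sort(ids)
    if (length(ids) < 2L) return(data.frame(pair = character(),
                                            a = character(), b = character()))
    cmb <- utils::combn(ids, 2L)
    data.frame(pair = paste(cmb[1L, ], cmb[2L, ], sep = "|"),
               a = cmb[1L, ], b = cmb[2L, ])
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(seed)
    }
    force(expr)
}

# Deterministic per-stage seed derivation; keeps results < 2^31.
deriveSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    (as.integer(seed) %% 1000003L) * 1009L + (h %% 99991L)
}

rowVars <- function(m) {
    n <- ncol(m)
    if (n < 2L) return(rep(NA_real_, nrow(m)))
    mu <- Matrix::rowMeans(m)
    (Matrix::rowMeans(m^2) - mu^2) * n / (n - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
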