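# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# Two-pass sample Pearson correlation.
pearsonOracle <- function(x, y) {
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    num <- sum((x - mx) * (y - my))
    num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

profileDistanceOracle <- function(m) {
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n)) for (j in seq_len(n))
        if (i != j) d[i, j] <- (1 - pearsonOracle(m[i, ], m[j, ])) / 2
    d
}

# Literal build-the-reference-set-and-sort similarity caller.
similarityOracle <- function(d, qLow = 0.10, qHighTop = 0.80,
                             mode = "conditional") {
    ids <- rownames(d)
    n <- length(ids)
    out <- list()
    globalSet <- d[upper.tri(d)]
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        a <- ids[i]; b <- ids[j]
        dij <- d[a, b]
        S <- if (mode == "global") globalSet else {
            vals <- c()
            for (k in ids) {
                if (k != a) vals <- c(vals, d[a, k])
                if (k != b && k != a) vals <- c(vals, d[b, k])
            }
            vals
        }
        S <- sort(S)
        rank <- which(S >= dij)[1]   # competition rank, ties share minimum
        call <- if (rank <= ceiling(qLow * length(S))) "similar"
                else if (rank > floor((1 - qHighTop) * length(S))) "dissimilar"
                else "intermediate"
        out[[paste(a, b, sep = "|")]] <- call
    }
    unlist(out)
}

# Projected-gradient NNLS run to convergence.
projGradNnls <- function(A, b, iters = 50000, tol = 1e-12) {
    AtA <- crossprod(A); Atb <- crossprod(A, b)
    L <- max(eigen(AtA, symmetric = TRUE, only.values = TRUE)$values)
    x <- rep(0, ncol(A))
    for (i in seq_len(iters)) {
        xNew <- pmax(0, x - (AtA %*% x - Atb) / L)
        if (max(abs(xNew - x)) < tol) { x <- xNew; break }
        x <- xNew
    }
    drop(x)
}

nnlsObjective <- function(A, x, b) sum((A %*% x - b)^2)

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# group-A index subsets (tie-free data only); mirrors the exact two-sided
# rule p = min(1, 2 * tail probability).
wilcoxEnumOracle <- function(a, b) {
    nA <- length(a); nB <- length(b)
    pooled <- c(a, b)
    r <- rank(pooled)
    u <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
    combs <- utils::combn(nA + nB, nA)
    us <- apply(combs, 2, function(idx) sum(r[idx]) - nA * (nA + 1) / 2)
    if (u > nA * nB / 2) p <- 2 * mean(us >= u) else p <- 2 * mean(us <= u)
    min(p, 1)
}

# All nontrivial bipartitions of a tree, as canonical "0/1" strings over the
# sorted leaf set (complement-normalized so the first leaf is always 0).
enumSplits <- function(tree) {
    leaves <- sort(tree$labels)
    m <- tree$merge
    sets <- vector("list", nrow(m))
    for (i in seq_len(nrow(m))) {
        l <- if (m[i, 1] < 0) tree$labels[-m[i, 1]] else sets[[m[i, 1]]]
        r <- if (m[i, 2] < 0) tree$labels[-m[i, 2]] else sets[[m[i, 2]]]
        sets[[i]] <- c(l, r)
    }
    keys <- character()
    for (s in sets) {
        k <- length(s)
        if (k < 2 || k > length(leaves) - 2) next
        mem <- leaves %in% s
        if (mem[1]) mem <- !mem
        keys <- c(keys, paste(as.integer(mem), collapse = ""))
    }
    unique(keys)
}

rfOracle <- function(t1, t2) {
    n <- length(t1$labels)
    s1 <- enumSplits(t1); s2 <- enumSplits(t2)
    if (n <= 3) return(0)
    (length(setdiff(s1, s2)) + length(setdiff(s2, s1))) / (2 * (n - 3))
}

# Exhaustive-matching clustering-information distance for small trees:
# tries every injective assignment between the two split sets.
cidOracle <- function(t1, t2) {
    leaves <- sort(t1$labels)
    n <- length(leaves)
    memOf <- function(key) as.logical(as.integer(strsplit(key, "")[[1]]))
    H <- function(mem) {
        p <- c(sum(mem), n - sum(mem)) / n
        -sum(p * log2(p))
    }
    MI <- function(m1, m2) {
        tot <- 0
        for (x in c(TRUE, FALSE)) for (y in c(TRUE, FALSE)) {
            nxy <- sum(m1 == x & m2 == y)
            if (nxy == 0) next
            p <- nxy / n
            tot <- tot + p * log2(p / ((sum(m1 == x) / n) * (sum(m2 == y) / n)))
        }
        tot
    }
    s1 <- lapply(enumSplits(t1), memOf)
    s2 <- lapply(enumSplits(t2), memOf)
    h1 <- sum(vapply(s1, H, 1.0)); h2 <- sum(vapply(s2, H, 1.0))
    if (h1 == 0 && h2 == 0) return(0)
    w <- matrix(0, length(s1), length(s2))
    for (i in seq_along(s1)) for (j in seq_along(s2))
        w[i, j] <- max(0, MI(s1[[i]], s2[[j]]))
    small <- if (nrow(w) <= ncol(w)) w else t(w)
    best <- 0
    if (nrow(small) > 0) {
        perms <- combinat_perms(ncol(small))
        for (p in perms) {
            sel <- p[seq_len(nrow(small))]
            best <- max(best, sum(small[cbind(seq_len(nrow(small)), sel)]))
        }
    }
    max(0, min(1, 1 - best / mean(c(h1, h2))))
}

# All permutations of 1..n (n small).
combinat_perms <- function(n) {
    if (n == 1) return(list(1L))
    out <- list()
    for (i in seq_len(n)) {
        rest <- combinat_perms(n - 1L)
        for (r in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[r])
    }
    out
}

# Random dendrogram over k labelled leaves from a random distance matrix.
randomTree <- function(k, seed) {
    set.seed(seed)
    m <- matrix(runif(k * k), k)
    d <- (m + t(m)) / 2; diag(d) <- 0
    dimnames(d) <- list(letters[1:k], letters[1:k])
    hc <- hclust(as.dist(d), method = "ward.D")
    hc
}
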