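## Independent brute-force oracles used to cross-check the package's
## matrix-algebra implementations.

## random symmetric binary adjacency matrix with zero diagonal
randomAdjacency <- function(n, pEdge = 0.3) {
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, pEdge)
    a <- a + t(a)
    dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
    a
}

## degree from an explicit edge-list representation
bruteDegrees <- function(a) {
    n <- nrow(a)
    edges <- which(a == 1 & upper.tri(a), arr.ind = TRUE)
    k <- integer(n)
    for (e in seq_len(nrow(edges))) {
        k[edges[e, 1]] <- k[edges[e, 1]] + 1L
        k[edges[e, 2]] <- k[edges[e, 2]] + 1L
    }
    k
}

## O(n^3) triangle enumeration for the local clustering coefficient
bruteClustering <- function(a) {
    n <- nrow(a)
    k <- bruteDegrees(a)
    cc <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        if (k[i] <= 1L) next
        tri <- 0L
        for (j in seq_len(n)) for (l in seq_len(n)) {
            if (j != i && l != i && a[i, j] == 1 &&
                a[j, l] == 1 && a[l, i] == 1)
                tri <- tri + 1L
        }
        cc[i] <- tri / (k[i] * (k[i] - 1L))
    }
    cc
}

## upper hypergeometric tail by enumerating every 2x2 table with the given
## margins and summing point masses for overlaps >= x
bruteHyperTail <- function(N, K, n, x) {
    lo <- max(0L, n + K - N)
    hi <- min(n, K)
    support <- lo:hi
    mass <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
    sum(mass[support >= x])
}

## expression matrix of pure noise, used for threshold property tests
randomExprMatrix <- function(nGenes, nSamples) {
    matrix(stats::rnorm(nGenes * nSamples), nGenes, nSamples,
           dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                           sprintf("s%02d", seq_len(nSamples))))
}

## small CountMatrix fixture
toyCounts <- function() {
    m <- matrix(c(10L, 0L, 25L, 3L, 12L, 1L, 30L, 2L,
                  11L, 2L, 28L, 4L, 9L, 1L, 27L, 5L), nrow = 4,
                dimnames = list(paste0("G", 1:4), paste0("S", 1:4)))
    makeCountMatrix(m, rep(c("ctl", "trt"), each = 2))
}
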