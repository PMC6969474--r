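## small networks used across the block
adjFromEdges <- function(n, edges) {
    a <- matrix(0, n, n)
    for (e in edges) { a[e[1], e[2]] <- 1; a[e[2], e[1]] <- 1 }
    dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
    a
}
asNetwork <- function(a) new("AdjacencyNetwork",
                             geneIds = rownames(a), adjacency = a)

test_that("correlation p-values follow the exact t transform", {
    expect_equal(correlationPvalue(0, 9), 1)
    expect_equal(correlationPvalue(1, 9), 0)
    expect_equal(correlationPvalue(-1, 9), 0)
    expect_error(correlationPvalue(0.5, 2), "3 samples")
    expect_error(correlationPvalue(1.5, 9), "exceed")

    ## two-sided symmetry and the derived values at n = 9 (df = 7)
    expect_equal(correlationPvalue(-0.7, 9), correlationPvalue(0.7, 9))
    expect_equal(correlationPvalue(0.7, 9), 0.0358, tolerance = 1e-2)
    expect_equal(correlationPvalue(0.6664, 9), 0.050, tolerance = 1e-2)

    ## independent oracle: 2 * t-CDF tail at the transformed statistic
    r <- 0.7; n <- 9
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(correlationPvalue(r, n), 2 * (1 - pt(tstat, n - 2)),
                 tolerance = 1e-12)
})

test_that("pairwise Pearson matrix matches hand computation", {
    x <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 2, 4))
    colnames(x) <- paste0("s", 1:3)
    co <- pearsonMatrix(x)
    r <- corMatrix(co)
    expect_equal(diag(r), c(a = 1, b = 1, c = 1))
    expect_equal(r["a", "b"], -1)
    ## hand-evaluated Pearson formula for (1,2,3) vs (1,2,4)
    num <- sum((c(1, 2, 3) - 2) * (c(1, 2, 4) - 7 / 3))
    den <- sqrt(sum((c(1, 2, 3) - 2)^2) * sum((c(1, 2, 4) - 7 / 3)^2))
    expect_equal(r["a", "c"], num / den)
    expect_equal(r["a", "c"], 0.98198, tolerance = 1e-5)
    expect_true(all(is.na(diag(corPvalues(co)))))
})

test_that("constant genes are excluded with a warning, or error in strict mode", {
    x <- rbind(a = c(1, 2, 3, 1), b = c(5, 5, 5, 5), c = c(2, 1, 4, 2))
    colnames(x) <- paste0("s", 1:4)
    expect_warning(co <- pearsonMatrix(x), "constant")
    expect_identical(geneIds(co), c("a", "c"))
    expect_identical(excludedGenes(co), "b")
    expect_error(pearsonMatrix(x, strict = TRUE), "constant")
    x[1, 1] <- NA
    expect_error(suppressWarnings(pearsonMatrix(x)), "missing")
})

test_that("the adjacency rule is inclusive on both thresholds", {
    mk <- function(r, p) {
        rm <- matrix(c(1, r, r, 1), 2, 2)
        pm <- matrix(c(NA, p, p, NA), 2, 2)
        new("CorrelationResult", geneIds = c("a", "b"), r = rm, p = pm,
            nSamples = 9L, excluded = character())
    }
    edge <- function(r, p) adjacencyMatrix(thresholdAdjacency(mk(r, p)))[1, 2]
    expect_identical(edge(0.7, 0.036), 1)     # both pass
    expect_identical(edge(0.9, 0.06), 0)      # p fails
    expect_identical(edge(0.4, 0.01), 0)      # r fails
    expect_identical(edge(0.5, 0.05), 1)      # boundaries are inclusive
    expect_identical(edge(-0.6, 0.01), 1)     # |r| is what counts
    expect_error(thresholdAdjacency(mk(0.5, 0.5), rMin = -0.1), "rMin")
    expect_error(thresholdAdjacency(mk(0.5, 0.5), pMax = 0), "pMax")
})

test_that("connectivity and clustering coefficient match small known graphs", {
    triangle <- asNetwork(adjFromEdges(3, list(c(1, 2), c(2, 3), c(1, 3))))
    expect_identical(unname(connectivity(triangle)), c(2L, 2L, 2L))

    star <- asNetwork(adjFromEdges(4, list(c(1, 2), c(1, 3), c(1, 4))))
    expect_identical(unname(connectivity(star)), c(3L, 1L, 1L, 1L))
    expect_identical(unname(clusteringCoefficient(star)),
                     c(0, NA_real_, NA_real_, NA_real_))

    empty <- asNetwork(adjFromEdges(3, list()))
    expect_identical(unname(connectivity(empty)), c(0L, 0L, 0L))
    expect_true(all(is.na(clusteringCoefficient(empty))))

    k4 <- asNetwork(adjFromEdges(4, combn(4, 2, identity, simplify = FALSE)))
    expect_equal(unname(clusteringCoefficient(k4)), rep(1, 4))

    path3 <- asNetwork(adjFromEdges(3, list(c(1, 2), c(2, 3))))
    cc <- unname(clusteringCoefficient(path3))
    expect_identical(cc[2], 0)                # middle node, open triple
    expect_true(all(is.na(cc[c(1, 3)])))      # endpoints have k = 1

    ## triangle plus pendant: c_1 = 2 triangles-paths / (3 * 2) = 1/3
    g <- asNetwork(adjFromEdges(4, list(c(1, 2), c(1, 3), c(2, 3), c(1, 4))))
    expect_equal(unname(clusteringCoefficient(g))[1], 1 / 3)
    expect_equal(unname(clusteringCoefficient(g))[1], bruteClustering(
        adjacencyMatrix(g))[1])
})

test_that("node statistics agree with brute-force and igraph oracles", {
    set.seed(202)
    for (i in 1:50) {
        n <- sample(4:25, 1)
        a <- randomAdjacency(n, runif(1, 0.1, 0.6))
        net <- asNetwork(a)
        expect_identical(unname(connectivity(net)), bruteDegrees(a))
        expect_equal(unname(clusteringCoefficient(net)), bruteClustering(a))
        g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
        expect_identical(unname(connectivity(net)),
                         as.integer(igraph::degree(g)))
        ccig <- unname(igraph::transitivity(g, type = "local",
                                            isolates = "NaN"))
        ccig[is.nan(ccig)] <- NA_real_
        ccig[igraph::degree(g) <= 1] <- NA_real_
        expect_equal(unname(clusteringCoefficient(net)), ccig)
    }
})

test_that("the printed clustering denominator equals k(k-1) on binary graphs", {
    set.seed(77)
    for (i in 1:50) {
        a <- randomAdjacency(sample(3:20, 1), runif(1, 0, 1))
        k <- rowSums(a)
        denomPrinted <- rowSums(a)^2 - rowSums(a^2)
        expect_identical(denomPrinted, k * (k - 1))
    }
})

test_that("thresholding is monotone in both thresholds", {
    set.seed(31)
    x <- randomExprMatrix(15, 9)
    co <- pearsonMatrix(x)
    edges <- function(rMin, pMax)
        sum(adjacencyMatrix(thresholdAdjacency(co, rMin, pMax)))
    for (i in 1:20) {
        r1 <- runif(1, 0, 0.9); r2 <- runif(1, r1, 1)
        p1 <- runif(1, 0.01, 1); p2 <- runif(1, 0, p1)
        expect_lte(edges(r2, p1), edges(r1, p1))
        expect_lte(edges(r1, p2), edges(r1, p1))
    }
})

test_that("at n = 9 the significance threshold implies |r| >= 0.666", {
    set.seed(14)
    for (i in 1:10) {
        x <- randomExprMatrix(20, 9)
        co <- pearsonMatrix(x)
        ## edges from the p-criterion alone
        net <- thresholdAdjacency(co, rMin = 0, pMax = 0.05)
        a <- adjacencyMatrix(net)
        if (sum(a) > 0)
            expect_true(all(abs(corMatrix(co)[a == 1]) >= 0.666))
    }
})

test_that("network summaries count edges, density and isolated nodes", {
    empty <- asNetwork(adjFromEdges(3, list()))
    s <- networkSummary(empty)
    expect_identical(s$density, 0)
    expect_identical(s$meanK, 0)
    expect_true(is.na(s$meanC))

    k4 <- asNetwork(adjFromEdges(4, combn(4, 2, identity, simplify = FALSE)))
    s <- networkSummary(k4)
    expect_identical(s$density, 1)
    expect_identical(s$meanC, 1)

    triIso <- asNetwork(adjFromEdges(4, list(c(1, 2), c(2, 3), c(1, 3))))
    s <- networkSummary(triIso)
    expect_identical(s$nEdges, 3)
    expect_identical(s$nIsolated, 1L)
    expect_identical(s$meanC, 1)    # over the three defined nodes

    el <- edgeList(triIso)
    expect_identical(nrow(el), 3L)
    expect_identical(el$gene_i, c("g1", "g1", "g2"))
})
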