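test_that("BH step-up rejects exactly by the hand-applied rule", {
    ## p_(4) = 0.04 <= (4/4) * 0.05, so everything is rejected
    adj <- bhAdjust(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
    expect_identical(adj$nRejected, 4L)
    expect_true(all(adj$rejected))
    expect_equal(adj$impliedCutoff, 0.05)

    ## 0.04 > (1/4) * 0.05 = 0.0125: nothing survives
    adj0 <- bhAdjust(c(0.04, 0.5, 0.6, 0.7), q = 0.05)
    expect_identical(adj0$nRejected, 0L)
    expect_false(any(adj0$rejected))
    expect_identical(adj0$impliedCutoff, 0)

    expect_true(all(bhAdjust(rep(0, 5), q = 0.05)$rejected))
    expect_error(bhAdjust(numeric(0)), "empty")
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH q-values match p.adjust and the step-up set matches them", {
    set.seed(8)
    for (i in 1:20) {
        p <- runif(sample(5:200, 1))^sample(1:3, 1)
        q <- runif(1, 0.01, 0.2)
        adj <- bhAdjust(p, q)
        expect_equal(adj$qValues, p.adjust(p, "BH"))
        ## BH theorem: the step-up rejections are exactly q-value <= q
        expect_identical(adj$rejected, adj$qValues <= q)
        ## implied cutoff separates rejected from surviving p-values
        if (adj$nRejected > 0)
            expect_true(all(p[adj$rejected] <= adj$impliedCutoff))
    }
})

test_that("BH rejections grow with q and q-values are a monotone transform", {
    set.seed(15)
    p <- c(runif(50)^3, runif(50))
    qs <- sort(runif(10, 0.01, 0.5))
    nrej <- vapply(qs, function(q) bhAdjust(p, q)$nRejected, integer(1))
    expect_true(all(diff(nrej) >= 0))
    qv <- bhAdjust(p, 0.05)$qValues
    ## monotone transform: ordering of q-values follows ordering of p,
    ## and q-values never fall below their p-values
    expect_true(all(diff(qv[order(p)]) >= 0))
    expect_true(all(qv >= p))
    ## the cumulative-minimum step is a no-op on already-monotone input
    o <- order(p)
    scaled <- length(p) / seq_along(p) * p[o]
    monot <- rev(cummin(rev(scaled)))
    expect_identical(rev(cummin(rev(monot))), monot)
})

test_that("DE gene selection applies FDR and the annotation filter", {
    de <- data.frame(gene_id = sprintf("G%02d", 1:10),
                     p_value = c(rep(1e-6, 3), rep(0.5, 7)),
                     annotated = c(TRUE, FALSE, TRUE, rep(TRUE, 7)))
    expect_identical(selectDEGenes(de, q = 0.05), c("G01", "G03"))
    expect_identical(selectDEGenes(de, q = 0.05, requireAnnotation = FALSE),
                     c("G01", "G02", "G03"))

    deNull <- data.frame(gene_id = c("a", "b"), p_value = c(0.4, 0.9))
    expect_length(selectDEGenes(deNull), 0)

    deAll <- data.frame(gene_id = c("a", "b"), p_value = c(0, 0),
                        annotated = TRUE)
    expect_identical(selectDEGenes(deAll), c("a", "b"))
})

test_that("enrichment p-values match the single extreme table by hand", {
    bg <- sprintf("G%02d", 1:10)
    sets <- makeGeneSetCollection(list(S = bg[1:5]))
    res <- fisherEnrichment(bg[1:4], bg, sets)
    ## all 4 draws inside the 5-member set: p = C(5,4) C(5,0) / C(10,4)
    expect_equal(res$p_fisher, 5 / 210)
    expect_identical(res[, c("N", "K", "n", "x")],
                     data.frame(N = 10L, K = 5L, n = 4L, x = 4L))

    ## set = background forces x = n and p = 1
    resAll <- fisherEnrichment(bg[1:4], bg, makeGeneSetCollection(list(S = bg)))
    expect_identical(resAll$x, 4L)
    expect_equal(resAll$p_fisher, 1)

    ## zero overlap: P(X >= 0) = 1
    res0 <- fisherEnrichment(bg[6:8], bg, makeGeneSetCollection(list(S = bg[1:3])))
    expect_equal(res0$p_fisher, 1)

    expect_error(fisherEnrichment(c("G01", "ZZ"), bg, sets), "absent")
    expect_error(fisherEnrichment("G01", character(), sets), "background")
    expect_warning(fisherEnrichment(bg[1], bg,
        makeGeneSetCollection(list(S = "nope"))), "excluded")
})

test_that("enrichment matches table enumeration and fisher.test", {
    set.seed(404)
    for (i in 1:100) {
        N <- sample(5:60, 1)
        K <- sample(1:N, 1)
        n <- sample(1:N, 1)
        xRange <- max(0, n + K - N):min(n, K)
        x <- xRange[sample.int(length(xRange), 1)]
        bg <- sprintf("B%03d", seq_len(N))
        de <- c(bg[seq_len(x)], setdiff(bg, bg[seq_len(K)]))[seq_len(n)]
        sets <- makeGeneSetCollection(list(S = bg[seq_len(K)]))
        res <- fisherEnrichment(de, bg, sets)
        expect_identical(res$x, as.integer(x))
        expect_equal(res$p_fisher, bruteHyperTail(N, K, n, x),
                     tolerance = 1e-12)
    }
    ## spot cross-check against the standard exact-test routine
    tab <- matrix(c(7, 3, 5, 25), 2, 2)
    ft <- fisher.test(tab, alternative = "greater")$p.value
    bg <- sprintf("B%03d", 1:40)
    sets <- makeGeneSetCollection(list(S = bg[1:12]))   # K = 7 + 5
    de <- c(bg[1:7], bg[13:15])                         # n = 10, x = 7
    expect_equal(fisherEnrichment(de, bg, sets)$p_fisher, ft,
                 tolerance = 1e-12)
})

test_that("enrichment p never decreases when the overlap shrinks", {
    N <- 40; K <- 12; n <- 10
    ps <- vapply(max(0, n + K - N):min(n, K), function(x)
        bruteHyperTail(N, K, n, x), numeric(1))
    bg <- sprintf("B%03d", seq_len(N))
    sets <- makeGeneSetCollection(list(S = bg[seq_len(K)]))
    got <- vapply(max(0, n + K - N):min(n, K), function(x) {
        de <- c(bg[seq_len(x)], setdiff(bg, bg[seq_len(K)]))[seq_len(n)]
        fisherEnrichment(de, bg, sets)$p_fisher
    }, numeric(1))
    expect_equal(got, ps)
    expect_true(all(diff(got) <= 0))   # larger x, smaller (or equal) p
})
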