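## fast internal path: mean connectivity and mean clustering coefficient of
## the thresholded network built from a genes-by-samples matrix. Constant
## genes (undefined correlation) are dropped silently; isolated genes keep
## k = 0 and contribute to the k mean, matching the full pipeline.
.networkMeans <- function(x, rMin, pMax, tcrit) {
    keep <- .rowSds(x) > 0
    x <- x[keep, , drop = FALSE]
    if (nrow(x) < 2L)
        return(c(meanK = NA_real_, meanC = NA_real_))
    r <- stats::cor(t(x))
    n <- ncol(x)
    ## p <= pMax  <=>  |t| >= t-critical; threshold on |r| directly
    rp <- tcrit / sqrt(n - 2 + tcrit^2)
    a <- (abs(r) >= max(rMin, rp)) * 1
    diag(a) <- 0
    k <- rowSums(a)
    cc <- .clusterCoef(a)
    c(meanK = mean(k),
      meanC = if (any(!is.na(cc))) mean(cc, na.rm = TRUE) else NA_real_)
}

## rowSds without a matrixStats dependency
.rowSds <- function(x) {
    m <- rowMeans(x)
    sqrt(rowSums((x - m)^2) / (ncol(x) - 1))
}

#' Compare node statistics between two condition networks
#'
#' Aligns two [NodeStats-class] objects computed on the same genes, tabulates
#' per-gene differences (condition B minus condition A), and records the
#' condition means: mean connectivity over all genes and mean clustering
#' coefficient over the genes where it is defined.
#'
#' @param statsA,statsB [NodeStats-class] for conditions A and B, with
#'   identical gene ID lists.
#' @param conditionLabels labels for the two conditions in the report.
#' @return a [PreservationReport-class] without permutation p-values.
#' @export
compareNodeStats <- function(statsA, statsB,
                             conditionLabels = c("A", "B")) {
    stopifnot(is(statsA, "NodeStats"), is(statsB, "NodeStats"))
    if (!identical(statsA@geneIds, statsB@geneIds))
        stop("gene ID lists differ between the two conditions")
    tab <- data.frame(gene = statsA@geneIds,
                      k_A = statsA@k, k_B = statsB@k,
                      c_A = statsA@cc, c_B = statsB@cc)
    tab$delta_k <- tab$k_B - tab$k_A
    tab$delta_c <- tab$c_B - tab$c_A
    meanC <- function(cc) if (any(!is.na(cc))) mean(cc, na.rm = TRUE)
                          else NA_real_
    means <- data.frame(condition = conditionLabels,
                        mean_k = c(mean(tab$k_A), mean(tab$k_B)),
                        mean_c = c(meanC(tab$c_A), meanC(tab$c_B)))
    new("PreservationReport", table = tab, means = means,
        pValues = c(delta_k = NA_real_, delta_c = NA_real_),
        nPermutations = 0L, seed = NA_integer_)
}

#' Permutation test for network preservation between two conditions
#'
#' Tests whether the mean node connectivity and mean clustering coefficient
#' of the thresholded coexpression network differ between the two
#' conditions. The observed statistics are
#' \code{T_k = meanK(B) - meanK(A)} and \code{T_c = meanC(B) - meanC(A)}.
#' The null distribution is built by pooling all samples and randomly
#' reassigning them to two groups of the original sizes, rebuilding both
#' networks for every permutation; this preserves the gene-gene correlation
#' structure under the null hypothesis of no condition effect. Two-sided
#' p-values use the add-one estimator
#' \code{(1 + #(|T_perm| >= |T_obs|)) / (nPerm + 1)}, so they are never 0.
#'
#' @param exprA,exprB [ExpressionMatrix-class] (or numeric matrices) for the
#'   two conditions, same genes in the same order, >= 3 samples each.
#' @param nPerm number of permutations (>= 99).
#' @param seed integer RNG seed.
#' @param rMin,pMax adjacency thresholds, see [thresholdAdjacency()].
#' @param conditionLabels labels for the report.
#' @return a [PreservationReport-class] with permutation p-values. Rare
#'   permutations in which a statistic is undefined (e.g. no gene with two
#'   neighbours) are dropped from that statistic's p-value.
#' @export
permutationPreservationTest <- function(exprA, exprB, nPerm = 999L,
                                        seed = 1L, rMin = 0.5, pMax = 0.05,
                                        conditionLabels = c("A", "B")) {
    xA <- if (is(exprA, "ExpressionMatrix")) exprs(exprA) else as.matrix(exprA)
    xB <- if (is(exprB, "ExpressionMatrix")) exprs(exprB) else as.matrix(exprB)
    if (!identical(rownames(xA), rownames(xB)))
        stop("the two conditions must cover the same genes in the same order")
    nA <- ncol(xA); nB <- ncol(xB)
    if (nA < 3L || nB < 3L)
        stop("each condition needs at least 3 samples")
    nPerm <- as.integer(nPerm)
    if (nPerm < 99L)
        stop("use at least 99 permutations")
    if (rMin < 0 || rMin > 1) stop("rMin must lie in [0, 1]")
    if (pMax <= 0 || pMax > 1) stop("pMax must lie in (0, 1]")

    ## full per-gene report on the observed split
    corA <- suppressWarnings(pearsonMatrix(xA))
    corB <- suppressWarnings(pearsonMatrix(xB))
    common <- intersect(corA@geneIds, corB@geneIds)
    subNet <- function(co) {
        keep <- match(common, co@geneIds)
        new("CorrelationResult", geneIds = common,
            r = co@r[keep, keep, drop = FALSE],
            p = co@p[keep, keep, drop = FALSE],
            nSamples = co@nSamples, excluded = co@excluded)
    }
    statsA <- nodeStats(thresholdAdjacency(subNet(corA), rMin, pMax))
    statsB <- nodeStats(thresholdAdjacency(subNet(corB), rMin, pMax))
    report <- compareNodeStats(statsA, statsB, conditionLabels)

    tcritA <- stats::qt(1 - pMax / 2, df = nA - 2)
    tcritB <- stats::qt(1 - pMax / 2, df = nB - 2)
    obsA <- .networkMeans(xA, rMin, pMax, tcritA)
    obsB <- .networkMeans(xB, rMin, pMax, tcritB)
    tObs <- obsB - obsA

    ## canonical pooled column order, so the drawn permutations (and hence
    ## the p-value) are identical when the two condition labels are swapped
    pooled <- cbind(xA, xB)
    if (!is.null(colnames(pooled)))
        pooled <- pooled[, order(colnames(pooled)), drop = FALSE]
    nTot <- nA + nB
    set.seed(as.integer(seed))
    tPerm <- matrix(NA_real_, nPerm, 2,
                    dimnames = list(NULL, c("meanK", "meanC")))
    for (b in seq_len(nPerm)) {
        idx <- sample.int(nTot, nA)
        mA <- .networkMeans(pooled[, idx, drop = FALSE], rMin, pMax, tcritA)
        mB <- .networkMeans(pooled[, -idx, drop = FALSE], rMin, pMax, tcritB)
        tPerm[b, ] <- mB - mA
    }
    pval <- vapply(c("meanK", "meanC"), function(stat) {
        if (is.na(tObs[[stat]])) return(NA_real_)
        ok <- !is.na(tPerm[, stat])
        (1 + sum(abs(tPerm[ok, stat]) >= abs(tObs[[stat]]))) / (sum(ok) + 1)
    }, numeric(1))

    new("PreservationReport", table = report@table, means = report@means,
        pValues = c(delta_k = pval[["meanK"]], delta_c = pval[["meanC"]]),
        nPermutations = nPerm, seed = as.integer(seed))
}
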