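#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact null distribution of the sample correlation via the t
#' transform: \code{t = r * sqrt((n - 2) / (1 - r^2))} referred to a
#' Student-t distribution with \code{n - 2} degrees of freedom. At
#' \code{|r| = 1} the p-value is 0.
#'
#' @param r correlation coefficient(s) in [-1, 1] (vectorized).
#' @param n number of samples (>= 3).
#' @return two-sided p-value(s) in [0, 1].
#' @examples
#' correlationPvalue(0.7, 9)   # ~0.0358
#' @export
correlationPvalue <- function(r, n) {
    n <- as.integer(n)
    if (n < 3L)
        stop("at least 3 samples are required")
    if (any(abs(r) > 1 + 1e-8, na.rm = TRUE))
        stop("|r| must not exceed 1")
    r[r > 1] <- 1
    r[r < -1] <- -1
    p <- ifelse(abs(r) >= 1, 0,
                2 * stats::pt(abs(r) * sqrt((n - 2) / (1 - r^2)),
                              df = n - 2, lower.tail = FALSE))
    p
}

#' Pairwise Pearson correlations with significance for one condition
#'
#' Computes the gene-by-gene Pearson correlation matrix across the samples
#' of one condition, with two-sided p-values from [correlationPvalue()].
#' Genes with zero variance across samples have an undefined correlation;
#' they are excluded with a warning by default, or raise an error in strict
#' mode.
#'
#' @param object an [ExpressionMatrix-class] (a single condition's samples)
#'   or numeric genes-by-samples matrix.
#' @param strict error instead of excluding constant genes.
#' @return a [CorrelationResult-class].
#' @export
pearsonMatrix <- function(object, strict = FALSE) {
    x <- if (is(object, "ExpressionMatrix")) exprs(object)
         else as.matrix(object)
    if (anyNA(x))
        stop("missing expression values are not permitted")
    n <- ncol(x)
    if (n < 3L)
        stop("at least 3 samples are required")
    sds <- apply(x, 1, stats::sd)
    constant <- sds == 0
    if (any(constant)) {
        if (strict)
            stop("constant gene(s): ",
                 paste(rownames(x)[constant], collapse = ", "))
        warning("excluding ", sum(constant),
                " constant gene(s) before correlation")
    }
    excluded <- rownames(x)[constant]
    x <- x[!constant, , drop = FALSE]
    if (nrow(x) < 2L)
        stop("fewer than 2 genes with nonzero variance")
    r <- stats::cor(t(x))
    r[r > 1] <- 1
    r[r < -1] <- -1
    r <- (r + t(r)) / 2
    diag(r) <- 1
    p <- correlationPvalue(r, n)
    diag(p) <- NA_real_
    new("CorrelationResult", geneIds = rownames(x), r = r, p = p,
        nSamples = as.integer(n), excluded = excluded)
}

#' Hard-threshold a correlation matrix into a binary network
#'
#' Applies the adjacency rule: genes i and j are connected
#' (\code{a[i, j] = 1}) exactly when \code{|r| >= rMin} and the correlation
#' p-value is \code{<= pMax}; both thresholds are inclusive. The diagonal
#' is zero.
#'
#' @param object a [CorrelationResult-class].
#' @param rMin minimum absolute correlation, in [0, 1] (default 0.5).
#' @param pMax maximum p-value, in (0, 1] (default 0.05).
#' @return an [AdjacencyNetwork-class].
#' @export
thresholdAdjacency <- function(object, rMin = 0.5, pMax = 0.05) {
    stopifnot(is(object, "CorrelationResult"))
    if (rMin < 0 || rMin > 1)
        stop("rMin must lie in [0, 1]")
    if (pMax <= 0 || pMax > 1)
        stop("pMax must lie in (0, 1]")
    a <- (abs(object@r) >= rMin) & (object@p <= pMax)
    a[is.na(a)] <- FALSE
    a <- a * 1
    diag(a) <- 0
    dimnames(a) <- list(object@geneIds, object@geneIds)
    new("AdjacencyNetwork", geneIds = object@geneIds, adjacency = a)
}

## row sums of a binary adjacency matrix
.degrees <- function(a) rowSums(a)

#' @describeIn connectivity row sums of the adjacency matrix
#' @export
setMethod("connectivity", "AdjacencyNetwork", function(object) {
    stats::setNames(as.integer(.degrees(object@adjacency)), object@geneIds)
})

#' @describeIn connectivity extract stored connectivity
#' @export
setMethod("connectivity", "NodeStats", function(object) {
    stats::setNames(object@k, object@geneIds)
})

## c_i = (number of ordered neighbour paths closing a triangle) /
##       ((sum_j a_ij)^2 - sum_j a_ij^2), the denominator written exactly as
## the printed formula; for binary a it reduces to k_i (k_i - 1).
.clusterCoef <- function(a) {
    k <- rowSums(a)
    paths <- rowSums((a %*% a) * a)        # diag(A^3) = 2 * triangles through i
    denom <- rowSums(a)^2 - rowSums(a^2)
    ifelse(k <= 1, NA_real_, paths / denom)
}

#' @describeIn clusteringCoefficient computed from the adjacency matrix
#' @export
setMethod("clusteringCoefficient", "AdjacencyNetwork", function(object) {
    stats::setNames(.clusterCoef(object@adjacency), object@geneIds)
})

#' @describeIn clusteringCoefficient extract stored values
#' @export
setMethod("clusteringCoefficient", "NodeStats", function(object) {
    stats::setNames(object@cc, object@geneIds)
})

#' @describeIn nodeStats connectivity and clustering coefficient per gene
#' @export
setMethod("nodeStats", "AdjacencyNetwork", function(object) {
    new("NodeStats", geneIds = object@geneIds,
        k = unname(connectivity(object)),
        cc = unname(clusteringCoefficient(object)))
})

#' @describeIn networkSummary edge count, density, mean statistics
#' @export
setMethod("networkSummary", "AdjacencyNetwork", function(object) {
    a <- object@adjacency
    n <- nrow(a)
    k <- .degrees(a)
    cc <- .clusterCoef(a)
    nEdges <- sum(a) / 2
    list(nNodes = n,
         nEdges = nEdges,
         density = if (n >= 2) nEdges / choose(n, 2) else 0,
         meanK = mean(k),
         meanC = if (any(!is.na(cc))) mean(cc, na.rm = TRUE) else NA_real_,
         nIsolated = sum(k == 0))
})

#' Extract the edge list of a network
#'
#' @param object an [AdjacencyNetwork-class].
#' @return data.frame with columns \code{gene_i}, \code{gene_j} (one row per
#'   undirected edge, i before j in gene order) and \code{r} if a
#'   [CorrelationResult-class] is supplied via \code{corr}.
#' @param corr optional matching [CorrelationResult-class] to annotate the
#'   edges with their correlation.
#' @export
edgeList <- function(object, corr = NULL) {
    stopifnot(is(object, "AdjacencyNetwork"))
    a <- object@adjacency
    idx <- which(a == 1 & upper.tri(a), arr.ind = TRUE)
    out <- data.frame(gene_i = object@geneIds[idx[, 1]],
                      gene_j = object@geneIds[idx[, 2]])
    if (!is.null(corr)) {
        stopifnot(is(corr, "CorrelationResult"),
                  identical(corr@geneIds, object@geneIds))
        out$r <- corr@r[idx]
    }
    out
}
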