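#' Counts per million
#'
#' Plain library-size normalization: \code{count / librarySize * 1e6}. Each
#' sample's CPM values sum to exactly one million.
#'
#' @param object a [CountMatrix-class] or numeric count matrix.
#' @return numeric matrix of CPM values.
#' @export
cpmValues <- function(object) {
    m <- if (is(object, "CountMatrix")) counts(object) else as.matrix(object)
    lib <- colSums(m)
    if (any(lib <= 0))
        stop("zero library size in sample(s): ",
             paste(colnames(m)[lib <= 0], collapse = ", "))
    sweep(m, 2, lib, "/") * 1e6
}

#' Log2 counts-per-million normalization
#'
#' Computes \code{log2((count + prior) / (librarySize + 2 * prior) * 1e6)}.
#' The prior count stabilizes the log transform (and the Pearson
#' correlations downstream) for low counts.
#'
#' @param object a [CountMatrix-class].
#' @param prior positive prior count added to every cell (default 0.5).
#' @return an [ExpressionMatrix-class] on the log2-CPM scale, carrying the
#'   input's condition labels.
#' @examples
#' sim <- simulateExpression(simulationConfig(nGenes = 50, focalSetSize = 10,
#'     modules = list(), seed = 1))
#' e <- cpmLog2(sim$counts)
#' @export
cpmLog2 <- function(object, prior = 0.5) {
    stopifnot(is(object, "CountMatrix"))
    if (prior <= 0)
        stop("prior must be positive (use cpmValues() for plain CPM)")
    m <- counts(object)
    lib <- colSums(m)
    if (any(lib <= 0))
        stop("zero library size in sample(s): ",
             paste(colnames(m)[lib <= 0], collapse = ", "))
    v <- log2(sweep(m + prior, 2, lib + 2 * prior, "/") * 1e6)
    makeExpressionMatrix(v, condition(object))
}

#' Filter genes by minimum expression
#'
#' Keeps genes whose CPM exceeds \code{minCpm} in at least \code{minSamples}
#' samples, preserving gene order. The default \code{minSamples} is half the
#' samples (rounded up).
#'
#' @param object a [CountMatrix-class].
#' @param minCpm CPM threshold (strict inequality).
#' @param minSamples minimum number of samples; 0 keeps every gene.
#' @return the filtered [CountMatrix-class].
#' @export
filterLowExpression <- function(object, minCpm = 1.0, minSamples = NULL) {
    stopifnot(is(object, "CountMatrix"))
    if (is.null(minSamples))
        minSamples <- ceiling(ncol(object) / 2)
    minSamples <- as.integer(minSamples)
    if (minSamples > ncol(object))
        stop("minSamples exceeds the number of samples")
    keep <- rowSums(cpmValues(object) > minCpm) >= minSamples
    object[keep, ]
}

#' Restrict an expression matrix to a gene set
#'
#' Rows are restricted to the genes present in both the matrix and the set,
#' preserving the matrix's row order. Set members absent from the matrix are
#' reported via a message and recorded in
#' \code{metadata(result)$absentGenes}.
#'
#' @param object an [ExpressionMatrix-class].
#' @param set character vector of gene IDs, or a [GeneSetCollection-class]
#'   together with \code{setName}.
#' @param setName set name when \code{set} is a collection (defaults to its
#'   first set).
#' @return the restricted [ExpressionMatrix-class].
#' @export
subsetToGeneSet <- function(object, set, setName = NULL) {
    stopifnot(is(object, "ExpressionMatrix"))
    if (is(set, "GeneSetCollection")) {
        if (is.null(setName))
            setName <- geneSetNames(set)[1]
        set <- geneSetMembers(set, setName)
    }
    set <- unique(as.character(set))
    keep <- rownames(object) %in% set
    if (!any(keep))
        stop("no gene of the set is present in the expression matrix")
    absent <- setdiff(set, rownames(object))
    if (length(absent))
        message(length(absent),
                " set member(s) absent from the expression matrix")
    out <- object[keep, ]
    S4Vectors::metadata(out)$absentGenes <- absent
    out
}

#' Split an expression matrix by condition
#'
#' @param object an [ExpressionMatrix-class] with exactly two conditions.
#' @return named list of one [ExpressionMatrix-class] per condition, in the
#'   order the conditions first appear.
#' @export
splitByCondition <- function(object) {
    stopifnot(is(object, "ExpressionMatrix"))
    cond <- condition(object)
    lv <- unique(cond)
    out <- lapply(lv, function(lab) object[, cond == lab])
    stats::setNames(out, lv)
}
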