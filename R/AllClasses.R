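#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Two-condition gene expression count matrix
#'
#' A \linkS4class{SummarizedExperiment} holding non-negative integer
#' gene-by-sample counts in the \code{"counts"} assay, with a \code{condition}
#' column in \code{colData} assigning every sample to an experimental
#' condition (e.g. a maternal control diet versus a gossypol-rich diet).
#'
#' @slot . inherits all slots from \code{SummarizedExperiment}.
#' @seealso [makeCountMatrix()], [readCounts()]
#' @export
setClass("CountMatrix", contains = "SummarizedExperiment")

setValidity("CountMatrix", function(object) {
    msgs <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msgs <- c(msgs, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (anyNA(m)) msgs <- c(msgs, "counts contain missing values")
        else {
            if (any(m < 0)) msgs <- c(msgs, "counts must be non-negative")
            if (any(m != round(m))) msgs <- c(msgs, "counts must be integral")
        }
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msgs <- c(msgs, "gene IDs (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msgs <- c(msgs, "sample IDs (colnames) must be present and unique")
    if (!"condition" %in% colnames(SummarizedExperiment::colData(object)))
        msgs <- c(msgs, "colData must contain a 'condition' column")
    else if (anyNA(SummarizedExperiment::colData(object)$condition))
        msgs <- c(msgs, "every sample needs a condition label")
    if (length(msgs)) msgs else TRUE
})

#' Normalized expression matrix (log2-CPM scale)
#'
#' A \linkS4class{SummarizedExperiment} with a single \code{"exprs"} assay of
#' finite real values (typically log2 counts-per-million) and the same
#' \code{condition} column in \code{colData} as the source
#' \linkS4class{CountMatrix}.
#'
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
    msgs <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msgs <- c(msgs, "assay 'exprs' is required")
    else if (!all(is.finite(SummarizedExperiment::assay(object, "exprs"))))
        msgs <- c(msgs, "expression values must be finite")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msgs <- c(msgs, "gene IDs (rownames) must be present and unique")
    if (!"condition" %in% colnames(SummarizedExperiment::colData(object)))
        msgs <- c(msgs, "colData must contain a 'condition' column")
    if (length(msgs)) msgs else TRUE
})

#' Collection of named gene sets
#'
#' Holds gene sets as read from a GMT file: each set has a name, a free-text
#' description, and a vector of unique member gene IDs.
#'
#' @slot sets named list of character vectors of member gene IDs.
#' @slot descriptions named character vector, parallel to \code{sets}.
#' @seealso [readGeneSets()]
#' @export
setClass("GeneSetCollection",
    representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
    msgs <- character()
    if (length(object@sets) != length(object@descriptions))
        msgs <- c(msgs, "sets and descriptions must have equal length")
    if (length(object@sets)) {
        if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
            msgs <- c(msgs, "set names must be present and unique")
        if (!identical(names(object@sets), names(object@descriptions)))
            msgs <- c(msgs, "sets and descriptions must share names")
        dup <- vapply(object@sets, anyDuplicated, integer(1))
        if (any(dup > 0))
            msgs <- c(msgs, "member gene IDs must be unique within a set")
    }
    if (length(msgs)) msgs else TRUE
})

#' Pairwise Pearson correlation result for one condition
#'
#' Symmetric gene-by-gene Pearson correlation matrix together with two-sided
#' p-values for the null hypothesis of zero correlation, computed from the
#' t transform with n - 2 degrees of freedom. The p-value is defined
#' off-diagonal only (the diagonal is \code{NA}).
#'
#' @slot geneIds character vector of gene identifiers.
#' @slot r symmetric correlation matrix, unit diagonal.
#' @slot p symmetric matrix of two-sided p-values, \code{NA} diagonal.
#' @slot nSamples number of samples the correlations were computed from.
#' @slot excluded gene IDs dropped before correlation (zero variance).
#' @export
setClass("CorrelationResult",
    representation(geneIds = "character", r = "matrix", p = "matrix",
                   nSamples = "integer", excluded = "character"))

setValidity("CorrelationResult", function(object) {
    msgs <- character()
    ng <- length(object@geneIds)
    if (!identical(dim(object@r), c(ng, ng)) ||
        !identical(dim(object@p), c(ng, ng)))
        msgs <- c(msgs, "r and p must be square matrices over geneIds")
    else {
        if (!isTRUE(all.equal(object@r, t(object@r), tolerance = 1e-10)))
            msgs <- c(msgs, "r must be symmetric")
        if (max(abs(diag(object@r) - 1)) > 1e-10)
            msgs <- c(msgs, "diagonal of r must be 1")
        if (any(abs(object@r) > 1 + 1e-10))
            msgs <- c(msgs, "r must lie in [-1, 1]")
        off <- object@p[row(object@p) != col(object@p)]
        if (anyNA(off) || any(off < 0 | off > 1))
            msgs <- c(msgs, "off-diagonal p must lie in [0, 1]")
    }
    if (object@nSamples < 3L)
        msgs <- c(msgs, "at least 3 samples are required")
    if (length(msgs)) msgs else TRUE
})

#' Binary coexpression network
#'
#' Unweighted network encoded as a symmetric binary adjacency matrix with
#' zero diagonal: \code{a[i, j] = 1} when genes i and j are connected.
#'
#' @slot geneIds character vector of gene identifiers.
#' @slot adjacency numeric 0/1 matrix, symmetric, zero diagonal.
#' @seealso [thresholdAdjacency()]
#' @export
setClass("AdjacencyNetwork",
    representation(geneIds = "character", adjacency = "matrix"))

setValidity("AdjacencyNetwork", function(object) {
    msgs <- character()
    a <- object@adjacency
    ng <- length(object@geneIds)
    if (!identical(dim(a), c(ng, ng)))
        msgs <- c(msgs, "adjacency must be square over geneIds")
    else {
        if (!all(a %in% c(0, 1)))
            msgs <- c(msgs, "adjacency entries must be 0 or 1")
        if (!identical(a, t(a)))
            msgs <- c(msgs, "adjacency must be symmetric")
        if (any(diag(a) != 0))
            msgs <- c(msgs, "adjacency diagonal must be zero")
    }
    if (length(msgs)) msgs else TRUE
})

#' Per-gene network node statistics
#'
#' Connectivity (degree) k and local clustering coefficient c for every gene
#' of one network. The clustering coefficient is undefined (NA) exactly when
#' a gene has fewer than two neighbours.
#'
#' @slot geneIds character vector of gene identifiers.
#' @slot k integer connectivity per gene.
#' @slot cc clustering coefficient per gene, in [0, 1] or NA.
#' @export
setClass("NodeStats",
    representation(geneIds = "character", k = "integer", cc = "numeric"))

setValidity("NodeStats", function(object) {
    msgs <- character()
    ng <- length(object@geneIds)
    if (length(object@k) != ng || length(object@cc) != ng)
        msgs <- c(msgs, "k and cc must have one entry per gene")
    else {
        if (any(object@k < 0L) || any(object@k > ng - 1L))
            msgs <- c(msgs, "k must lie in [0, n - 1]")
        def <- !is.na(object@cc)
        if (any(object@cc[def] < -1e-10 | object@cc[def] > 1 + 1e-10))
            msgs <- c(msgs, "defined cc must lie in [0, 1]")
        if (!identical(is.na(object@cc), object@k <= 1L))
            msgs <- c(msgs, "cc must be NA exactly where k <= 1")
    }
    if (length(msgs)) msgs else TRUE
})

#' Network preservation report between two conditions
#'
#' Per-gene comparison of node statistics between the condition-A and
#' condition-B networks, the condition means, and (when a permutation test
#' has been run) two-sided permutation p-values for the difference in mean
#' connectivity and mean clustering coefficient.
#'
#' @slot table data.frame with columns gene, k_A, k_B, c_A, c_B,
#'   delta_k (= k_B - k_A) and delta_c.
#' @slot means data.frame with one row per condition: mean_k over all genes
#'   and mean_c over genes where the clustering coefficient is defined.
#' @slot pValues named numeric: permutation p-values for delta_k and
#'   delta_c (NA before the permutation test is run).
#' @slot nPermutations number of permutations used (0 if none).
#' @slot seed RNG seed of the permutation test (NA if none).
#' @export
setClass("PreservationReport",
    representation(table = "data.frame", means = "data.frame",
                   pValues = "numeric", nPermutations = "integer",
                   seed = "integer"))

setValidity("PreservationReport", function(object) {
    msgs <- character()
    need <- c("gene", "k_A", "k_B", "c_A", "c_B", "delta_k", "delta_c")
    if (!all(need %in% colnames(object@table)))
        msgs <- c(msgs, paste("table must have columns:",
                              paste(need, collapse = ", ")))
    if (!all(c("delta_k", "delta_c") %in% names(object@pValues)))
        msgs <- c(msgs, "pValues must be named delta_k and delta_c")
    pv <- object@pValues[!is.na(object@pValues)]
    if (any(pv <= 0 | pv > 1))
        msgs <- c(msgs, "p-values must lie in (0, 1]")
    if (length(msgs)) msgs else TRUE
})
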