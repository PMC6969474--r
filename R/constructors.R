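#' Construct a CountMatrix
#'
#' @param counts integer matrix, genes in rows (rownames = gene IDs),
#'   samples in columns (colnames = sample IDs).
#' @param condition condition label per sample, recycled names from
#'   \code{colnames(counts)} if unnamed; if named, matched by sample ID.
#' @return a validated [CountMatrix-class].
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'     dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' cm <- makeCountMatrix(m, rep(c("A", "B"), each = 2))
#' counts(cm)[1, 1]
#' @export
makeCountMatrix <- function(counts, condition) {
    counts <- as.matrix(counts)
    if (!is.null(names(condition))) {
        if (!all(colnames(counts) %in% names(condition)))
            stop("condition is missing labels for some samples")
        condition <- condition[colnames(counts)]
    }
    if (length(condition) != ncol(counts))
        stop("need one condition label per sample")
    storage.mode(counts) <- "integer"
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(
            condition = as.character(condition),
            row.names = colnames(counts)))
    new("CountMatrix", se)
}

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix of finite expression values (genes x samples).
#' @param condition condition label per sample (see [makeCountMatrix()]).
#' @return a validated [ExpressionMatrix-class].
#' @export
makeExpressionMatrix <- function(values, condition) {
    values <- as.matrix(values)
    if (!is.null(names(condition))) {
        if (!all(colnames(values) %in% names(condition)))
            stop("condition is missing labels for some samples")
        condition <- condition[colnames(values)]
    }
    if (length(condition) != ncol(values))
        stop("need one condition label per sample")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(
            condition = as.character(condition),
            row.names = colnames(values)))
    new("ExpressionMatrix", se)
}

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of member gene IDs;
#'   duplicate members within a set are removed.
#' @param descriptions optional named character vector of descriptions.
#' @return a validated [GeneSetCollection-class].
#' @export
makeGeneSetCollection <- function(sets, descriptions = NULL) {
    sets <- lapply(sets, function(x) unique(as.character(x)))
    if (is.null(descriptions))
        descriptions <- stats::setNames(rep("", length(sets)), names(sets))
    descriptions <- descriptions[names(sets)]
    names(descriptions) <- names(sets)
    descriptions[is.na(descriptions)] <- ""
    new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

#' @describeIn condition samples' condition labels of a CountMatrix
#' @export
setMethod("condition", "SummarizedExperiment", function(object) {
    stats::setNames(as.character(
        SummarizedExperiment::colData(object)$condition), colnames(object))
})

#' Count matrix accessor
#'
#' @param object a [CountMatrix-class].
#' @return integer matrix of counts (genes x samples).
#' @export
setMethod("counts", "CountMatrix", function(object) {
    SummarizedExperiment::assay(object, "counts")
})

#' Expression values accessor
#'
#' @param object an [ExpressionMatrix-class].
#' @return numeric matrix of expression values (genes x samples).
#' @export
exprs <- function(object) {
    stopifnot(is(object, "ExpressionMatrix"))
    SummarizedExperiment::assay(object, "exprs")
}

#' @describeIn geneIds gene IDs of a SummarizedExperiment-based matrix
#' @export
setMethod("geneIds", "SummarizedExperiment", function(object) rownames(object))

#' @describeIn geneIds gene IDs of a correlation result
#' @export
setMethod("geneIds", "CorrelationResult", function(object) object@geneIds)

#' @describeIn geneIds gene IDs of a network
#' @export
setMethod("geneIds", "AdjacencyNetwork", function(object) object@geneIds)

#' @describeIn geneIds gene IDs of node statistics
#' @export
setMethod("geneIds", "NodeStats", function(object) object@geneIds)

#' Correlation and p-value matrix accessors
#'
#' @param object a [CorrelationResult-class].
#' @return numeric matrix.
#' @export
corMatrix <- function(object) {
    stopifnot(is(object, "CorrelationResult"))
    object@r
}

#' @rdname corMatrix
#' @export
corPvalues <- function(object) {
    stopifnot(is(object, "CorrelationResult"))
    object@p
}

#' @rdname corMatrix
#' @export
excludedGenes <- function(object) {
    stopifnot(is(object, "CorrelationResult"))
    object@excluded
}

#' Adjacency matrix accessor
#'
#' @param object an [AdjacencyNetwork-class].
#' @return numeric 0/1 matrix with gene IDs as dimnames.
#' @export
adjacencyMatrix <- function(object) {
    stopifnot(is(object, "AdjacencyNetwork"))
    object@adjacency
}

#' Gene set collection accessors
#'
#' @param object a [GeneSetCollection-class].
#' @param name a set name.
#' @return \code{geneSetNames}: character vector of set names;
#'   \code{geneSetMembers}: character vector of member gene IDs;
#'   \code{geneSetDescriptions}: named character vector.
#' @export
geneSetNames <- function(object) {
    stopifnot(is(object, "GeneSetCollection"))
    names(object@sets)
}

#' @rdname geneSetNames
#' @export
geneSetMembers <- function(object, name) {
    stopifnot(is(object, "GeneSetCollection"))
    if (!name %in% names(object@sets))
        stop("unknown gene set: ", name)
    object@sets[[name]]
}

#' @rdname geneSetNames
#' @export
geneSetDescriptions <- function(object) {
    stopifnot(is(object, "GeneSetCollection"))
    object@descriptions
}

#' Preservation report accessors
#'
#' @param object a [PreservationReport-class].
#' @return \code{preservationTable}: the per-gene data.frame;
#'   \code{preservationMeans}: per-condition means; \code{preservationPvalues}:
#'   named permutation p-values (NA before testing).
#' @export
preservationTable <- function(object) {
    stopifnot(is(object, "PreservationReport"))
    object@table
}

#' @rdname preservationTable
#' @export
preservationMeans <- function(object) {
    stopifnot(is(object, "PreservationReport"))
    object@means
}

#' @rdname preservationTable
#' @export
preservationPvalues <- function(object) {
    stopifnot(is(object, "PreservationReport"))
    object@pValues
}

setMethod("show", "CountMatrix", function(object) {
    cond <- table(condition(object))
    cat("CountMatrix:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("conditions:",
        paste(sprintf("%s (n=%d)", names(cond), as.integer(cond)),
              collapse = ", "), "\n")
})

setMethod("show", "ExpressionMatrix", function(object) {
    cond <- table(condition(object))
    cat("ExpressionMatrix:", nrow(object), "genes x", ncol(object),
        "samples\n")
    cat("conditions:",
        paste(sprintf("%s (n=%d)", names(cond), as.integer(cond)),
              collapse = ", "), "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection with", length(object@sets), "set(s)\n")
    for (nm in utils::head(names(object@sets), 5))
        cat(sprintf("  %s: %d genes\n", nm, length(object@sets[[nm]])))
    if (length(object@sets) > 5) cat("  ...\n")
})

setMethod("show", "CorrelationResult", function(object) {
    cat("CorrelationResult:", length(object@geneIds), "genes,",
        object@nSamples, "samples\n")
    if (length(object@excluded))
        cat("excluded (zero variance):", length(object@excluded), "gene(s)\n")
})

setMethod("show", "AdjacencyNetwork", function(object) {
    s <- networkSummary(object)
    cat("AdjacencyNetwork:", s$nNodes, "genes,", s$nEdges,
        sprintf("edges (density %.3f)\n", s$density))
})

setMethod("show", "NodeStats", function(object) {
    cat("NodeStats for", length(object@geneIds), "genes\n")
    cat(sprintf("  mean k = %.2f; mean c = %.3f over %d defined\n",
        mean(object@k), mean(object@cc, na.rm = TRUE),
        sum(!is.na(object@cc))))
})

setMethod("show", "PreservationReport", function(object) {
    cat("PreservationReport over", nrow(object@table), "genes\n")
    print(object@means, row.names = FALSE)
    if (!all(is.na(object@pValues)))
        cat(sprintf(
            "permutation p (two-sided, %d perms): delta_k = %.4g, delta_c = %.4g\n",
            object@nPermutations, object@pValues[["delta_k"]],
            object@pValues[["delta_c"]]))
})
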