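#' @importFrom BiocGenerics counts
NULL

#' Condition labels of the samples
#'
#' @param object a [CountMatrix-class] or [ExpressionMatrix-class].
#' @return character vector of condition labels, named by sample ID.
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))

#' Node connectivity
#'
#' Connectivity \eqn{k_i = \sum_{j \ne i} a_{ij}} of every gene: the number
#' of genes it is connected to in the binary network.
#'
#' @param object an [AdjacencyNetwork-class] (computed) or
#'   [NodeStats-class] (extracted).
#' @return integer vector named by gene ID.
#' @export
setGeneric("connectivity", function(object) standardGeneric("connectivity"))

#' Node clustering coefficient
#'
#' Local clustering coefficient
#' \deqn{c_i = \frac{\sum_{j \ne i}\sum_{k \ne i} a_{ij} a_{jk} a_{ki}}
#'   {(\sum_{j \ne i} a_{ij})^2 - \sum_{j \ne i} a_{ij}^2}}
#' of every gene. For a binary adjacency matrix the denominator equals
#' \eqn{k_i (k_i - 1)}, so \eqn{c_i} is twice the number of triangles
#' through gene i divided by the number of ordered neighbour pairs.
#' Undefined (NA) when \eqn{k_i \le 1}.
#'
#' @param object an [AdjacencyNetwork-class] (computed) or
#'   [NodeStats-class] (extracted).
#' @return numeric vector named by gene ID, values in [0, 1] or NA.
#' @export
setGeneric("clusteringCoefficient",
    function(object) standardGeneric("clusteringCoefficient"))

#' Per-gene node statistics of a network
#'
#' @param object an [AdjacencyNetwork-class].
#' @return a [NodeStats-class] with connectivity and clustering coefficient.
#' @export
setGeneric("nodeStats", function(object) standardGeneric("nodeStats"))

#' Whole-network summary statistics
#'
#' @param object an [AdjacencyNetwork-class].
#' @return a named list: \code{nNodes}, \code{nEdges}, \code{density},
#'   \code{meanK}, \code{meanC} (over genes with defined clustering
#'   coefficient; NA if none), \code{nIsolated}.
#' @export
setGeneric("networkSummary", function(object) standardGeneric("networkSummary"))

#' Gene IDs of an object
#'
#' @param object a network-analysis object carrying gene identifiers.
#' @return character vector of gene IDs.
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
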