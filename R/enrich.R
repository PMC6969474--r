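#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Runs the BH step-up procedure at level \code{q}: with the p-values sorted
#' ascending, the largest rank k with \code{p_(k) <= (k/m) * q} and all
#' smaller ranks are rejected. Also reports the monotone q-values (as from
#' \code{p.adjust(..., "BH")}) and the implied p-value cutoff
#' \code{(k/m) * q} — the largest nominal p-value still rejected (0 when
#' nothing is rejected).
#'
#' @param pValues numeric vector of p-values in [0, 1].
#' @param q target FDR level in (0, 1).
#' @return list with \code{qValues}, logical \code{rejected},
#'   \code{nRejected} and \code{impliedCutoff}.
#' @examples
#' bhAdjust(c(0.001, 0.01, 0.03, 0.8), q = 0.05)
#' ## the implied cutoff for m tests with k rejections at level q is (k/m)*q
#' @export
bhAdjust <- function(pValues, q = 0.05) {
    if (length(pValues) == 0L)
        stop("empty p-value list")
    if (anyNA(pValues) || any(pValues < 0 | pValues > 1))
        stop("p-values must lie in [0, 1]")
    if (q <= 0 || q >= 1)
        stop("q must lie in (0, 1)")
    m <- length(pValues)
    o <- order(pValues)
    below <- which(pValues[o] <= seq_len(m) / m * q)
    k <- if (length(below)) max(below) else 0L
    rejected <- logical(m)
    if (k > 0L) rejected[o[seq_len(k)]] <- TRUE
    list(qValues = stats::p.adjust(pValues, method = "BH"),
         rejected = rejected,
         nRejected = as.integer(k),
         impliedCutoff = if (k > 0L) k / m * q else 0)
}

#' Implied BH p-value cutoff from summary counts
#'
#' The nominal p-value threshold that a BH step-up at level \code{q} with
#' \code{m} tests and \code{k} rejections corresponds to: \code{(k/m) * q}.
#' With 18,326 tested genes and 84 rejections at a 1\% FDR this is
#' about 4.6e-05.
#'
#' @param m number of tests.
#' @param k number of rejections.
#' @param q FDR level.
#' @return the implied p-value cutoff.
#' @export
bhImpliedCutoff <- function(m, k, q) {
    stopifnot(m >= 1, k >= 0, k <= m, q > 0, q < 1)
    k / m * q
}

#' Select differentially expressed genes at an FDR threshold
#'
#' Applies [bhAdjust()] at level \code{q} to the table's p-values and
#' optionally restricts the selection to genes flagged as annotated
#' (mirroring a selection of FDR-significant genes that carry usable
#' database annotations).
#'
#' @param de data.frame with columns \code{gene_id}, \code{p_value} and
#'   optionally logical \code{annotated}.
#' @param q FDR level (default 0.05).
#' @param requireAnnotation drop selected genes with
#'   \code{annotated == FALSE} (no-op if the column is absent).
#' @return character vector of selected gene IDs.
#' @export
selectDEGenes <- function(de, q = 0.05, requireAnnotation = TRUE) {
    stopifnot(is.data.frame(de),
              all(c("gene_id", "p_value") %in% colnames(de)))
    if (anyDuplicated(de$gene_id))
        stop("duplicated gene IDs in the DE table")
    adj <- bhAdjust(de$p_value, q)
    sel <- de$gene_id[adj$rejected]
    if (requireAnnotation && "annotated" %in% colnames(de))
        sel <- intersect(sel, de$gene_id[de$annotated %in% TRUE])
    as.character(sel)
}

#' Gene-set overrepresentation by the one-sided Fisher test
#'
#' For each gene set, counts the overlap x between the DE genes and the
#' set's members (both intersected with the background of N genes), and
#' computes the upper cumulative hypergeometric tail
#' \eqn{p = P(X \ge x)} with \eqn{X \sim \mathrm{Hypergeom}(N, K, n)} —
#' Fisher's exact test for overrepresentation. Sets with no member in the
#' background are excluded with a warning.
#'
#' @param deGenes character vector of DE gene IDs (must be a subset of
#'   \code{background}).
#' @param background character vector of all tested (expressed, annotated)
#'   gene IDs.
#' @param sets a [GeneSetCollection-class].
#' @param adjustAcrossSets also report BH q-values across the tested sets
#'   (off by default; the raw Fisher p is the primary output).
#' @return data.frame sorted by \code{p_fisher} with columns \code{set},
#'   \code{description}, \code{N}, \code{K}, \code{n}, \code{x},
#'   \code{p_fisher} (and \code{q_value} if requested).
#' @examples
#' sets <- makeGeneSetCollection(list(S = paste0("G", 1:5)))
#' fisherEnrichment(paste0("G", 1:4), paste0("G", 1:10), sets)
#' @export
fisherEnrichment <- function(deGenes, background, sets,
                             adjustAcrossSets = FALSE) {
    stopifnot(is(sets, "GeneSetCollection"))
    background <- unique(as.character(background))
    deGenes <- unique(as.character(deGenes))
    if (length(background) == 0L)
        stop("empty background")
    bad <- setdiff(deGenes, background)
    if (length(bad))
        stop("DE gene(s) absent from background: ",
             paste(utils::head(bad, 5), collapse = ", "))
    N <- length(background)
    n <- length(deGenes)
    rows <- lapply(geneSetNames(sets), function(nm) {
        members <- intersect(geneSetMembers(sets, nm), background)
        K <- length(members)
        if (K == 0L) {
            warning("gene set '", nm,
                    "' has no member in the background; excluded")
            return(NULL)
        }
        x <- length(intersect(deGenes, members))
        p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(set = nm,
                   description = geneSetDescriptions(sets)[[nm]],
                   N = N, K = K, n = n, x = x, p_fisher = p)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(set = character(), description = character(),
                          N = integer(), K = integer(), n = integer(),
                          x = integer(), p_fisher = numeric())
    out <- out[order(out$p_fisher, out$set), , drop = FALSE]
    rownames(out) <- NULL
    if (adjustAcrossSets && nrow(out))
        out$q_value <- stats::p.adjust(out$p_fisher, method = "BH")
    out
}
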