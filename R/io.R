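## TSV dialect used throughout: UTF-8, tab-delimited, '#' comment lines
## ignored, no quoting.
.readTsv <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      comment.char = "#", check.names = FALSE,
                      stringsAsFactors = FALSE)
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
}

#' Read a count matrix and its sample-to-condition map
#'
#' The counts file is a TSV with gene IDs in the first column and one column
#' of integer counts per sample; the sample map is a two-column TSV with
#' header \code{sample_id} and \code{condition}. Every sample in the counts
#' file must be mapped; extra map rows are ignored with a warning.
#'
#' @param countsPath path to the counts TSV.
#' @param sampleMapPath path to the sample map TSV.
#' @return a validated [CountMatrix-class].
#' @seealso [writeCounts()]
#' @export
readCounts <- function(countsPath, sampleMapPath) {
    tab <- .readTsv(countsPath)
    if (ncol(tab) < 2L)
        stop("malformed counts file (need gene ID column + samples): ",
             countsPath)
    ids <- as.character(tab[[1]])
    if (anyDuplicated(ids))
        stop("duplicated gene ID in ", countsPath, ": ",
             ids[duplicated(ids)][1])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (anyDuplicated(colnames(m)))
        stop("duplicated sample ID in ", countsPath)
    if (!is.numeric(m) || anyNA(m))
        stop("counts in ", countsPath, " must be numeric with no missing values")
    if (any(m < 0) || any(m != round(m)))
        stop("counts in ", countsPath, " must be non-negative integers")
    rownames(m) <- ids

    map <- .readTsv(sampleMapPath)
    if (!all(c("sample_id", "condition") %in% colnames(map)))
        stop("sample map ", sampleMapPath,
             " needs columns 'sample_id' and 'condition'")
    if (anyDuplicated(map$sample_id))
        stop("duplicated sample_id in ", sampleMapPath)
    missing <- setdiff(colnames(m), map$sample_id)
    if (length(missing))
        stop("sample(s) in ", countsPath, " absent from ", sampleMapPath,
             ": ", paste(missing, collapse = ", "))
    extra <- setdiff(map$sample_id, colnames(m))
    if (length(extra))
        warning("ignoring ", length(extra),
                " sample(s) in map but not in counts")
    cond <- stats::setNames(as.character(map$condition), map$sample_id)
    makeCountMatrix(m, cond[colnames(m)])
}

#' Write a count matrix (and optionally its sample map) as TSV
#'
#' @param object a [CountMatrix-class].
#' @param countsPath output path for the counts TSV (first column
#'   \code{gene_id}, one column per sample).
#' @param sampleMapPath optional output path for the sample map TSV.
#' @return invisibly, \code{countsPath}.
#' @export
writeCounts <- function(object, countsPath, sampleMapPath = NULL) {
    stopifnot(is(object, "CountMatrix"))
    df <- data.frame(gene_id = rownames(object), counts(object),
                     check.names = FALSE)
    .writeTsv(df, countsPath)
    if (!is.null(sampleMapPath))
        .writeTsv(data.frame(sample_id = colnames(object),
                             condition = unname(condition(object))),
                  sampleMapPath)
    invisible(countsPath)
}

#' Read gene sets from a GMT file
#'
#' One set per line: set name, description, then member gene IDs, all
#' tab-separated. Duplicate members within a set are dropped. Empty lines
#' are skipped; an empty file yields an empty collection.
#'
#' @param gmtPath path to the GMT file.
#' @return a [GeneSetCollection-class].
#' @export
readGeneSets <- function(gmtPath) {
    if (!file.exists(gmtPath))
        stop("file not found: ", gmtPath)
    lines <- readLines(gmtPath, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    sets <- list(); desc <- character()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3L)
            stop("malformed GMT line ", i, " in ", gmtPath,
                 ": fewer than 3 tab-separated fields")
        nm <- f[1]
        if (nm %in% names(sets))
            stop("duplicated set name in ", gmtPath, ": ", nm)
        sets[[nm]] <- unique(f[-(1:2)])
        desc[nm] <- f[2]
    }
    makeGeneSetCollection(sets, desc)
}

#' Write a gene set collection as GMT
#'
#' @param object a [GeneSetCollection-class].
#' @param gmtPath output path.
#' @return invisibly, \code{gmtPath}.
#' @export
writeGeneSets <- function(object, gmtPath) {
    stopifnot(is(object, "GeneSetCollection"))
    lines <- vapply(geneSetNames(object), function(nm) {
        paste(c(nm, geneSetDescriptions(object)[[nm]],
                geneSetMembers(object, nm)), collapse = "\t")
    }, character(1))
    writeLines(lines, gmtPath)
    invisible(gmtPath)
}

#' Read a per-gene differential-expression p-value table
#'
#' TSV with columns \code{gene_id} and \code{p_value}, plus an optional
#' logical \code{annotated} column flagging genes with usable annotations.
#'
#' @param path path to the TSV.
#' @return validated data.frame.
#' @export
readDETable <- function(path) {
    de <- .readTsv(path)
    if (!all(c("gene_id", "p_value") %in% colnames(de)))
        stop("DE table ", path, " needs columns 'gene_id' and 'p_value'")
    if (anyDuplicated(de$gene_id))
        stop("duplicated gene_id in ", path)
    if (anyNA(de$p_value) || any(de$p_value < 0 | de$p_value > 1))
        stop("p_value in ", path, " must lie in [0, 1]")
    if ("annotated" %in% colnames(de))
        de$annotated <- as.logical(de$annotated)
    de
}

#' Read a qPCR Ct table
#'
#' TSV with columns \code{sample_id}, \code{group}, \code{ct_target},
#' \code{ct_reference} and an optional \code{gene} column for multi-gene
#' tables.
#'
#' @param path path to the TSV.
#' @return validated data.frame.
#' @export
readCtTable <- function(path) {
    ct <- .readTsv(path)
    need <- c("sample_id", "group", "ct_target", "ct_reference")
    if (!all(need %in% colnames(ct)))
        stop("Ct table ", path, " needs columns: ",
             paste(need, collapse = ", "))
    if (!all(is.finite(ct$ct_target)) || !all(is.finite(ct$ct_reference)))
        stop("Ct values in ", path, " must be finite")
    ct
}
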