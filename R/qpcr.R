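## required columns of a Ct table
.checkCtTable <- function(ct) {
    need <- c("sample_id", "group", "ct_target", "ct_reference")
    if (!is.data.frame(ct) || !all(need %in% colnames(ct)))
        stop("Ct table needs columns: ", paste(need, collapse = ", "))
    if (anyNA(ct$ct_target) || anyNA(ct$ct_reference) ||
        !all(is.finite(ct$ct_target)) || !all(is.finite(ct$ct_reference)))
        stop("missing or non-finite Ct value")
    invisible(ct)
}

#' Per-sample delta-Ct normalization
#'
#' Normalizes the target gene's Ct to the reference (internal control) gene
#' measured in the same sample: \code{delta_ct = ct_target - ct_reference}.
#' Higher delta-Ct means lower relative expression of the target.
#'
#' @param ct a Ct table (see [readCtTable()] / [simulateQpcr()]).
#' @return the table with an added \code{delta_ct} column.
#' @export
deltaCt <- function(ct) {
    .checkCtTable(ct)
    ct$delta_ct <- ct$ct_target - ct$ct_reference
    ct
}

#' Relative expression by the 2^-ddCt method
#'
#' Centres each sample's delta-Ct on the control group's mean
#' (\code{ddct = delta_ct - mean(delta_ct | control)}) and converts to a
#' fold change \code{2^-ddct}, assuming a doubling of product per cycle.
#' By construction the control group's geometric-mean fold change is
#' exactly 1.
#'
#' @param dct a data.frame with columns \code{group} and \code{delta_ct}
#'   (e.g. the output of [deltaCt()]).
#' @param controlGroup label of the control (reference) group.
#' @return list with \code{perSample} (input plus \code{ddct} and
#'   \code{fold_change}) and \code{groupMeans} (per group: n, mean delta-Ct,
#'   mean log2 fold, geometric-mean fold).
#' @examples
#' tab <- simulateQpcr(6, deltaCtShift = 1, noiseSd = 0.3, seed = 2)
#' relativeExpression(deltaCt(tab), "control")$groupMeans
#' @export
relativeExpression <- function(dct, controlGroup) {
    stopifnot(is.data.frame(dct),
              all(c("group", "delta_ct") %in% colnames(dct)))
    inControl <- dct$group == controlGroup
    if (!any(inControl))
        stop("control group '", controlGroup, "' is empty")
    ctrlMean <- mean(dct$delta_ct[inControl])
    dct$ddct <- dct$delta_ct - ctrlMean
    dct$fold_change <- 2^(-dct$ddct)
    gm <- do.call(rbind, lapply(split(dct, dct$group), function(g) {
        data.frame(group = g$group[1], n = nrow(g),
                   mean_delta_ct = mean(g$delta_ct),
                   mean_log2_fold = -mean(g$ddct),
                   fold_geomean = 2^(-mean(g$ddct)))
    }))
    rownames(gm) <- NULL
    list(perSample = dct, groupMeans = gm)
}

#' Likelihood ratio test for a group effect on delta-Ct
#'
#' Fits two Gaussian linear models to the per-sample delta-Ct values — a
#' null model with a common mean and a full model with group-specific
#' means — and computes the likelihood ratio statistic
#' \code{LRT = n * ln(RSS0 / RSS1)}, referred to a chi-square distribution
#' with 1 degree of freedom.
#'
#' @param deltaCtValues numeric vector of per-sample delta-Ct values, or a
#'   data.frame with columns \code{delta_ct} and \code{group}.
#' @param groups group label per sample (2 levels, >= 2 samples each);
#'   ignored when \code{deltaCtValues} is a data.frame.
#' @return list with \code{statistic}, \code{p_value}, \code{df},
#'   \code{rss0}, \code{rss1} and the per-group means.
#' @examples
#' lrtGroupEffect(c(1, 1, 2, 3, 3, 4), rep(c("a", "b"), each = 3))
#' @export
lrtGroupEffect <- function(deltaCtValues, groups = NULL) {
    if (is.data.frame(deltaCtValues)) {
        stopifnot(all(c("delta_ct", "group") %in% colnames(deltaCtValues)))
        groups <- deltaCtValues$group
        deltaCtValues <- deltaCtValues$delta_ct
    }
    y <- as.numeric(deltaCtValues)
    g <- factor(groups)
    if (nlevels(g) != 2L)
        stop("exactly two groups are required")
    if (any(table(g) < 2L))
        stop("each group needs at least 2 samples")
    if (anyNA(y))
        stop("missing delta-Ct value")
    n <- length(y)
    fit0 <- stats::lm(y ~ 1)
    fit1 <- stats::lm(y ~ g)
    rss0 <- sum(stats::residuals(fit0)^2)
    rss1 <- sum(stats::residuals(fit1)^2)
    if (rss1 <= .Machine$double.eps * rss0)
        stop("zero residual variance under the full model; LRT undefined")
    lrt <- n * log(rss0 / rss1)
    list(statistic = lrt,
         p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
         df = 1L, rss0 = rss0, rss1 = rss1,
         groupMeans = tapply(y, g, mean))
}
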