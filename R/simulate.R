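#' Configure the synthetic two-condition expression simulator
#'
#' The generator emulates a two-diet bulk RNA-seq study of the testis
#' transcriptome: two conditions of \code{samplesPerCondition} samples each,
#' a large background of uncorrelated genes, and a designated focal gene set
#' (a spermatogenesis-like set) containing planted coexpression modules. Each
#' module m has a per-condition latent factor; within-module genes share a
#' target pairwise latent correlation \code{rho} in condition A, attenuated
#' to \code{rho * (1 - disruption)} in condition B. Counts are drawn from a
#' negative binomial observation model on top of the latent log-expression.
#'
#' @param nGenes total number of genes.
#' @param samplesPerCondition samples per condition (two conditions).
#' @param modules list of planted modules inside the focal set; each element
#'   is \code{c(size, rho)} or \code{list(size =, rho =)} with
#'   \code{rho} in [0, 1).
#' @param disruption attenuation delta in [0, 1] applied to every module's
#'   rho in condition B: \code{rho_B = rho * (1 - disruption)}.
#' @param focalSetSize size of the focal gene set (must hold all modules).
#' @param logMeanRange range (natural-log scale) of per-gene baseline mean
#'   counts, drawn uniformly; the same baseline is used in both conditions.
#' @param biologicalSd standard deviation of the latent log-expression
#'   signal (natural-log scale).
#' @param nbDispersion negative binomial dispersion phi
#'   (variance = mu + phi * mu^2).
#' @param libSizeSdLog sd of the per-sample log-normal library size factor.
#' @param seed integer RNG seed.
#' @return a validated configuration list of class \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nGenes = 200, focalSetSize = 60,
#'     modules = list(c(20, 0.8)), disruption = 0.85, seed = 1)
#' @export
simulationConfig <- function(nGenes = 18000L,
                             samplesPerCondition = 9L,
                             modules = list(c(40, 0.80), c(30, 0.75),
                                            c(25, 0.70)),
                             disruption = 0.85,
                             focalSetSize = 145L,
                             logMeanRange = c(2, 6),
                             biologicalSd = 1.0,
                             nbDispersion = 0.1,
                             libSizeSdLog = 0.1,
                             seed = 1L) {
    modules <- lapply(modules, function(m) {
        m <- unlist(m)
        if (length(m) != 2L)
            stop("each module must be (size, rho)")
        list(size = as.integer(m[[1]]), rho = as.numeric(m[[2]]))
    })
    cfg <- list(nGenes = as.integer(nGenes),
                samplesPerCondition = as.integer(samplesPerCondition),
                modules = modules,
                disruption = as.numeric(disruption),
                focalSetSize = as.integer(focalSetSize),
                logMeanRange = as.numeric(logMeanRange),
                biologicalSd = as.numeric(biologicalSd),
                nbDispersion = as.numeric(nbDispersion),
                libSizeSdLog = as.numeric(libSizeSdLog),
                seed = as.integer(seed))
    if (cfg$nGenes < 1L)
        stop("invalid config: nGenes must be positive")
    if (cfg$samplesPerCondition < 1L)
        stop("invalid config: samplesPerCondition must be positive")
    sizes <- vapply(cfg$modules, `[[`, integer(1), "size")
    rhos <- vapply(cfg$modules, `[[`, numeric(1), "rho")
    if (any(sizes < 1L))
        stop("invalid config: module sizes must be positive")
    if (any(rhos < 0 | rhos >= 1))
        stop("invalid config: module rho must lie in [0, 1)")
    if (cfg$disruption < 0 || cfg$disruption > 1)
        stop("invalid config: disruption must lie in [0, 1]")
    if (any(rhos * (1 - cfg$disruption) < 0 |
            rhos * (1 - cfg$disruption) >= 1))
        stop("invalid config: rho * (1 - disruption) must lie in [0, 1)")
    if (sum(sizes) > cfg$focalSetSize)
        stop("invalid config: sum of module sizes exceeds focalSetSize")
    if (cfg$focalSetSize > cfg$nGenes)
        stop("invalid config: focalSetSize exceeds nGenes")
    if (length(cfg$logMeanRange) != 2L ||
        cfg$logMeanRange[1] > cfg$logMeanRange[2])
        stop("invalid config: logMeanRange must be an increasing pair")
    if (cfg$biologicalSd <= 0)
        stop("invalid config: biologicalSd must be positive")
    if (cfg$nbDispersion <= 0)
        stop("invalid config: nbDispersion must be positive")
    if (cfg$libSizeSdLog < 0)
        stop("invalid config: libSizeSdLog must be non-negative")
    class(cfg) <- "SimulationConfig"
    cfg
}

## latent z matrix (genes x samples) for one condition, given per-module rho
.simulateLatent <- function(nGenes, nSamples, modules, rhos) {
    z <- matrix(stats::rnorm(nGenes * nSamples), nGenes, nSamples)
    offset <- 0L
    for (i in seq_along(modules)) {
        size <- modules[[i]]$size
        rows <- offset + seq_len(size)
        f <- stats::rnorm(nSamples)     # shared module factor, one per sample
        z[rows, ] <- sqrt(rhos[i]) * matrix(f, size, nSamples, byrow = TRUE) +
            sqrt(1 - rhos[i]) * z[rows, ]
        offset <- offset + size
    }
    z
}

#' Simulate two-condition counts with planted coexpression modules
#'
#' For each condition and module, a per-sample latent factor f ~ N(0, 1) is
#' drawn; module genes get latent values
#' \code{z = sqrt(rho) * f + sqrt(1 - rho) * eps} with eps ~ N(0, 1), so any
#' two module genes have latent correlation rho. Unassigned genes are pure
#' noise. Counts are negative binomial with mean
#' \code{sizeFactor * exp(mu_g + biologicalSd * z)} and dispersion phi. The
#' per-gene baseline mu_g is shared between conditions; only the module
#' correlation differs (attenuated by \code{disruption} in condition B).
#'
#' @param config a [simulationConfig()] object.
#' @param conditionLabels labels of the two conditions.
#' @return a list with elements \code{countsA} and \code{countsB}
#'   ([CountMatrix-class] per condition), \code{counts} (both conditions
#'   combined), \code{latentA}/\code{latentB} (the latent z matrices), and
#'   \code{truth} (module assignment per gene, per-condition module rho,
#'   focal set membership).
#' @examples
#' sim <- simulateExpression(simulationConfig(nGenes = 100,
#'     focalSetSize = 40, modules = list(c(15, 0.8)), seed = 7))
#' sim$counts
#' @export
simulateExpression <- function(config,
                               conditionLabels = c("control", "treated")) {
    if (!inherits(config, "SimulationConfig"))
        config <- do.call(simulationConfig, config)
    stopifnot(length(conditionLabels) == 2L,
              !anyDuplicated(conditionLabels))
    set.seed(config$seed)
    ng <- config$nGenes
    ns <- config$samplesPerCondition
    geneIds <- sprintf("G%06d", seq_len(ng))
    rhoA <- vapply(config$modules, `[[`, numeric(1), "rho")
    rhoB <- rhoA * (1 - config$disruption)

    mu <- stats::runif(ng, config$logMeanRange[1], config$logMeanRange[2])

    drawCondition <- function(rhos, prefix) {
        z <- .simulateLatent(ng, ns, config$modules, rhos)
        sf <- exp(stats::rnorm(ns, 0, config$libSizeSdLog))
        lambda <- exp(mu + config$biologicalSd * z) *
            matrix(sf, ng, ns, byrow = TRUE)
        cnt <- matrix(stats::rnbinom(ng * ns, mu = lambda,
                                     size = 1 / config$nbDispersion), ng, ns)
        dimnames(cnt) <- list(geneIds, sprintf("%s_s%d", prefix, seq_len(ns)))
        dimnames(z) <- dimnames(cnt)
        list(counts = cnt, z = z)
    }
    A <- drawCondition(rhoA, conditionLabels[1])
    B <- drawCondition(rhoB, conditionLabels[2])

    sizes <- vapply(config$modules, `[[`, integer(1), "size")
    assignment <- rep(NA_character_, ng)
    if (length(sizes))
        assignment[seq_len(sum(sizes))] <-
            rep(sprintf("M%d", seq_along(sizes)), sizes)
    names(assignment) <- geneIds
    truth <- list(
        moduleAssignment = assignment,
        rhoPerCondition = data.frame(
            module = if (length(sizes)) sprintf("M%d", seq_along(sizes))
                     else character(),
            size = sizes, rho_A = rhoA, rho_B = rhoB),
        focalSet = geneIds[seq_len(config$focalSetSize)],
        conditionLabels = conditionLabels)

    countsA <- makeCountMatrix(A$counts, rep(conditionLabels[1], ns))
    countsB <- makeCountMatrix(B$counts, rep(conditionLabels[2], ns))
    combined <- makeCountMatrix(cbind(A$counts, B$counts),
                                rep(conditionLabels, each = ns))
    list(countsA = countsA, countsB = countsB, counts = combined,
         latentA = A$z, latentB = B$z, truth = truth)
}

#' Simulate a per-gene differential-expression p-value table
#'
#' The first \code{nTrue} genes receive p-values from Beta(\code{altBetaA}, 1)
#' (right-skewed toward 0 for \code{altBetaA < 1}); the remaining genes are
#' Uniform(0, 1) nulls. Gene IDs follow the same \code{G000001...} scheme as
#' [simulateExpression()], so the true positives fall inside the focal gene
#' set when the two generators share a configuration.
#'
#' @param nGenes number of genes.
#' @param nTrue number of genes with a true signal (must not exceed
#'   \code{nGenes}).
#' @param altBetaA Beta shape parameter a in (0, 1] for the alternatives;
#'   \code{a = 1} makes them indistinguishable from the null.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{gene_id}, \code{p_value},
#'   \code{annotated} (all TRUE) and \code{true_signal}.
#' @export
simulateDEPvalues <- function(nGenes, nTrue, altBetaA = 0.1, seed = 1L) {
    nGenes <- as.integer(nGenes); nTrue <- as.integer(nTrue)
    if (nTrue > nGenes)
        stop("nTrue must not exceed nGenes")
    if (nTrue < 0L || nGenes < 1L)
        stop("nGenes must be positive and nTrue non-negative")
    if (altBetaA <= 0 || altBetaA > 1)
        stop("altBetaA must lie in (0, 1]")
    set.seed(as.integer(seed))
    p <- c(stats::rbeta(nTrue, altBetaA, 1),
           stats::runif(nGenes - nTrue))
    data.frame(gene_id = sprintf("G%06d", seq_len(nGenes)),
               p_value = p,
               annotated = TRUE,
               true_signal = seq_len(nGenes) <= nTrue)
}

#' Simulate a qPCR Ct table for one target gene in two groups
#'
#' Reference-gene Ct values are N(20, noiseSd); target Ct equals the
#' reference Ct plus a fixed baseline offset, an independent noise term, and
#' \code{deltaCtShift} extra cycles in the second group. A positive shift
#' therefore lowers the target's relative expression (fold change
#' \code{2^-deltaCtShift} in the noise-free limit).
#'
#' @param nPerGroup samples per group (at least 2).
#' @param deltaCtShift Ct cycles added to the target in the second group.
#' @param noiseSd standard deviation of the Ct noise (>= 0; 0 gives the
#'   exact noise-free limit).
#' @param seed integer RNG seed.
#' @param baseline target-minus-reference baseline Ct offset.
#' @param groups labels of the two groups; the first is the control.
#' @return data.frame with columns \code{sample_id}, \code{group},
#'   \code{ct_target}, \code{ct_reference}.
#' @export
simulateQpcr <- function(nPerGroup, deltaCtShift = 0, noiseSd = 0.5,
                         seed = 1L, baseline = 5,
                         groups = c("control", "treated")) {
    nPerGroup <- as.integer(nPerGroup)
    if (nPerGroup < 2L)
        stop("nPerGroup must be at least 2")
    if (noiseSd < 0)
        stop("noiseSd must be non-negative")
    stopifnot(length(groups) == 2L, !anyDuplicated(groups))
    set.seed(as.integer(seed))
    n <- 2L * nPerGroup
    group <- rep(groups, each = nPerGroup)
    ctRef <- stats::rnorm(n, 20, noiseSd)
    ctTar <- ctRef + baseline + deltaCtShift * (group == groups[2]) +
        stats::rnorm(n, 0, noiseSd)
    data.frame(
        sample_id = sprintf("%s_s%d", group,
                            rep(seq_len(nPerGroup), times = 2L)),
        group = group, ct_target = ctTar, ct_reference = ctRef)
}
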