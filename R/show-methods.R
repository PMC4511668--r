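#' @describeIn hostCounts host x taxon slot-count matrix of a population.
#' @param x object to access.
#' @export
setMethod("hostCounts", "PopulationState", function(x) x@counts)

#' Accessors for simulation objects
#'
#' \code{hostCounts} returns the host x taxon count matrix,
#' \code{generation} the generation index, \code{trajectory} the recorded
#' diversity data.frame, \code{finalState} the final population, and
#' \code{genealogy} the recorded host genealogy.
#'
#' @name hostCounts
#' @rdname hostCounts
NULL

#' @rdname hostCounts
#' @export
setMethod("hostCounts", "MicrobiomeSimulation",
          function(x) x@finalState@counts)

#' @rdname generation
#' @param x object to access.
#' @export
setMethod("generation", "PopulationState", function(x) x@generation)

#' @rdname generation
#' @export
setMethod("generation", "MicrobiomeSimulation",
          function(x) x@finalState@generation)

#' @rdname trajectory
#' @param x a [MicrobiomeSimulation-class].
#' @export
setMethod("trajectory", "MicrobiomeSimulation", function(x) x@trajectory)

#' @rdname finalState
#' @param x a [MicrobiomeSimulation-class].
#' @export
setMethod("finalState", "MicrobiomeSimulation", function(x) x@finalState)

#' @rdname genealogy
#' @param x a [MicrobiomeSimulation-class].
#' @export
setMethod("genealogy", "MicrobiomeSimulation", function(x) x@genealogy)

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig: N =", object@numHosts,
        "hosts, n =", object@slotsPerHost, "slots, m =", object@numTaxa,
        "taxa\n  x (parental) =", object@parentalFraction,
        ", y (pooled env) =", object@pooledEnvFraction,
        "\n  up to", object@maxGenerations, "generations, seed",
        object@seed, "\n")
})

setMethod("show", "PopulationState", function(object) {
    cat("PopulationState: generation", object@generation, "with",
        nrow(object@counts), "hosts x", ncol(object@counts), "taxa (",
        sum(colSums(object@counts) > 0), "taxa present )\n")
})

setMethod("show", "EnvironmentState", function(object) {
    cat("EnvironmentState over", length(object@fixedDistribution),
        "taxa; current pool entropy",
        round(scaledShannon(object@currentDistribution /
                                sum(object@currentDistribution)), 4), "\n")
})

setMethod("show", "GenealogyRecord", function(object) {
    cat("GenealogyRecord:", length(object@parents), "generations of",
        if (length(object@parents)) length(object@parents[[1L]]) else 0,
        "hosts\n")
})

setMethod("show", "MicrobiomeSimulation", function(object) {
    tr <- object@trajectory
    last <- tr[nrow(tr), ]
    cat("MicrobiomeSimulation (x =", object@config@parentalFraction,
        ", y =", object@config@pooledEnvFraction, ")\n",
        " ran", last$generation, "generations; stopped:",
        object@stoppedReason, "\n",
        sprintf("  final alpha = %.4f, beta = %.4f, gamma = %.4f\n",
                last$alpha_mean, last$beta, last$gamma))
})

setMethod("show", "LogNormalFit", function(object) {
    cat(sprintf(
        "LogNormalFit: mu = %.4f, sigma = %.4f (n = %d, logLik = %.2f)\n",
        object@mu, object@sigma, object@nObs, object@logLik))
})

setMethod("show", "DirichletMultinomialFit", function(object) {
    cat(sprintf(paste0(
        "DirichletMultinomialFit: m = %d taxa, sum(alpha) = %.3f, ",
        "theta = %.4f\n  logLik = %.2f, %s in %d iterations%s\n"),
        length(object@concentration), sum(object@concentration),
        object@theta, object@logLik,
        if (object@converged) "converged" else "NOT converged",
        object@iterations,
        if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "AbundanceTable", function(object) {
    cat("AbundanceTable:", nrow(object@values), "lineages x",
        ncol(object@values), "samples at rank", object@rank, "\n")
})

setMethod("show", "GridSpec", function(object) {
    cat("GridSpec:", length(object@xValues), "x values x",
        length(object@yValues), "y values,", object@replicates,
        "replicates per cell (base seed", object@baseSeed, ")\n")
})

setMethod("show", "GridResult", function(object) {
    cat("GridResult:", length(object@xValues), "x",
        length(object@yValues), "cells,", object@replicates,
        "replicates each\n  gamma range: [",
        round(min(object@gammaMean), 3), ",",
        round(max(object@gammaMean), 3), "]\n")
})
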