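#' @import methods
#' @importFrom stats rbinom rmultinom rgamma sd var dlnorm median setNames
#' @importFrom utils write.csv head tail
NULL

.checkProb <- function(p, what, tol = 1e-9) {
    if (!is.numeric(p) || length(p) < 1L)
        return(sprintf("%s must be a non-empty numeric vector", what))
    if (any(!is.finite(p)) || any(p < 0))
        return(sprintf("%s must be finite and non-negative", what))
    if (abs(sum(p) - 1) > tol)
        return(sprintf("%s must sum to 1 (got %.12f)", what, sum(p)))
    NULL
}

#' SimulationConfig: parameters of a neutral microbiome simulation
#'
#' Container for all parameters of a forward-time neutral simulation of
#' microbiome acquisition in a Wright-Fisher host population: \code{numHosts}
#' hosts (N), each with \code{slotsPerHost} microbe slots (n), drawing taxa
#' from an environmental pool of \code{numTaxa} taxa (m). Each slot of an
#' offspring microbiome is filled from the parent's microbiome with
#' probability \code{parentalFraction} (x, "mixed acquisition") and from the
#' environment otherwise; the environment offered to each new generation
#' mixes the pooled microbiomes of the previous host generation (weight
#' \code{pooledEnvFraction}, y, "mixed environment") with a fixed pool.
#'
#' @slot numHosts integer, host population size N (constant across
#'   generations).
#' @slot slotsPerHost integer, microbiome capacity n of each host.
#' @slot numTaxa integer, number of microbial taxa m in the environmental
#'   pool.
#' @slot parentalFraction numeric in [0,1], per-slot probability x of
#'   parental origin (x = 0 strict environmental acquisition, x = 1 strict
#'   parental acquisition).
#' @slot pooledEnvFraction numeric in [0,1], weight y of the pooled
#'   host-derived component in the environment (y = 0 fixed environment,
#'   y = 1 fully pooled environment).
#' @slot maxGenerations integer, hard cap on simulated generations.
#' @slot recordInterval integer, generations between diversity records.
#' @slot seed integer RNG seed used by [runSimulation()].
#' @slot stopOnStabilization logical, halt when the recorded gamma-diversity
#'   trajectory stabilizes (see [detectStabilization()]).
#' @slot stabilizationWindow integer, window length (in recorded points) for
#'   stabilization detection.
#' @slot stabilizationTolerance numeric, relative-change tolerance for
#'   stabilization detection.
#' @slot minGenerations integer, generations that must elapse before
#'   stabilization may halt the run.
#' @slot stopOnAbsorption logical, halt early once a single taxon remains
#'   population-wide, but only in regimes where that state is absorbing
#'   (x = 1 or y = 1).
#' @slot recordGenealogy logical, keep per-generation parent indices.
#' @slot fixedDistribution numeric length-m relative-abundance vector of the
#'   fixed environmental pool (default uniform, matching the initial
#'   seeding).
#'
#' @seealso [SimulationConfig()] for the user-facing constructor.
#' @export
setClass("SimulationConfig",
    representation(
        numHosts = "integer",
        slotsPerHost = "integer",
        numTaxa = "integer",
        parentalFraction = "numeric",
        pooledEnvFraction = "numeric",
        maxGenerations = "integer",
        recordInterval = "integer",
        seed = "integer",
        stopOnStabilization = "logical",
        stabilizationWindow = "integer",
        stabilizationTolerance = "numeric",
        minGenerations = "integer",
        stopOnAbsorption = "logical",
        recordGenealogy = "logical",
        fixedDistribution = "numeric"
    )
)

setValidity("SimulationConfig", function(object) {
    msgs <- character()
    for (s in c("numHosts", "slotsPerHost", "numTaxa", "maxGenerations",
                "recordInterval", "stabilizationWindow", "minGenerations")) {
        v <- slot(object, s)
        if (length(v) != 1L || is.na(v) || v < 1L)
            msgs <- c(msgs, sprintf("%s must be a single integer >= 1", s))
    }
    for (s in c("parentalFraction", "pooledEnvFraction")) {
        v <- slot(object, s)
        if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
            msgs <- c(msgs, sprintf("%s must be a single value in [0, 1]", s))
    }
    if (object@stabilizationTolerance <= 0)
        msgs <- c(msgs, "stabilizationTolerance must be positive")
    if (length(object@fixedDistribution) != object@numTaxa)
        msgs <- c(msgs, "fixedDistribution must have length numTaxa")
    else {
        bad <- .checkProb(object@fixedDistribution, "fixedDistribution")
        if (!is.null(bad)) msgs <- c(msgs, bad)
    }
    if (length(msgs)) msgs else TRUE
})

#' PopulationState: per-host taxon occupancies at one generation
#'
#' The microbiome of every host at a single generation, stored as a
#' host x taxon matrix of slot counts. Every row sums exactly to the
#' per-host slot capacity n.
#'
#' @slot counts integer host x taxon matrix of slot occupancies.
#' @slot generation non-negative integer generation index.
#' @slot parentIndex integer vector of each host's parent in the previous
#'   generation (1-based; length 0 at generation 0).
#'
#' @export
setClass("PopulationState",
    representation(
        counts = "matrix",
        generation = "integer",
        parentIndex = "integer"
    )
)

setValidity("PopulationState", function(object) {
    msgs <- character()
    cts <- object@counts
    if (!is.numeric(cts) || any(!is.finite(cts)) || any(cts < 0))
        msgs <- c(msgs, "counts must be a finite non-negative matrix")
    else {
        rs <- rowSums(cts)
        if (length(unique(rs)) > 1L)
            msgs <- c(msgs, "every host row must sum to the same slot total")
    }
    if (object@generation < 0L)
        msgs <- c(msgs, "generation must be non-negative")
    np <- length(object@parentIndex)
    if (np != 0L) {
        if (np != nrow(cts))
            msgs <- c(msgs, "parentIndex must have one entry per host")
        else if (any(object@parentIndex < 1L) ||
                 any(object@parentIndex > nrow(cts)))
            msgs <- c(msgs, "parentIndex entries must index hosts")
    }
    if (length(msgs)) msgs else TRUE
})

#' EnvironmentState: the environmental taxon pool
#'
#' Relative abundances of the fixed environmental pool and of the pool
#' actually offered to the next host generation (a y : 1 - y mixture of the
#' pooled previous-generation microbiomes and the fixed pool).
#'
#' @slot fixedDistribution numeric relative-abundance vector of the fixed
#'   pool; constant for the whole simulation.
#' @slot currentDistribution numeric relative-abundance vector offered to
#'   the next generation.
#'
#' @export
setClass("EnvironmentState",
    representation(
        fixedDistribution = "numeric",
        currentDistribution = "numeric"
    )
)

setValidity("EnvironmentState", function(object) {
    msgs <- c(
        .checkProb(object@fixedDistribution, "fixedDistribution"),
        .checkProb(object@currentDistribution, "currentDistribution")
    )
    if (length(object@fixedDistribution) !=
        length(object@currentDistribution))
        msgs <- c(msgs, "fixed and current distributions must share a length")
    if (length(msgs)) msgs else TRUE
})

#' GenealogyRecord: the Wright-Fisher host genealogy
#'
#' One integer parent-index vector per simulated generation after the first;
#' element i of vector t is the parent (in generation t - 1) of host i in
#' generation t.
#'
#' @slot parents list of integer vectors, each of length numHosts.
#'
#' @export
setClass("GenealogyRecord", representation(parents = "list"))

setValidity("GenealogyRecord", function(object) {
    ls <- lengths(object@parents)
    if (length(ls) && length(unique(ls)) > 1L)
        return("all parent vectors must have the same length (constant N)")
    if (length(ls) && any(vapply(object@parents, function(p)
            any(p < 1L | p > ls[[1L]]), logical(1L))))
        return("parent indices must lie in [1, numHosts]")
    TRUE
})

#' MicrobiomeSimulation: result of a full simulation run
#'
#' Returned by [runSimulation()]: the recorded diversity trajectory, the
#' final population and environment states, the host genealogy and the
#' configuration that produced them.
#'
#' @slot config the [SimulationConfig-class] used.
#' @slot trajectory data.frame with columns \code{generation},
#'   \code{alpha_mean}, \code{alpha_sd}, \code{beta}, \code{gamma}.
#' @slot finalState the final [PopulationState-class].
#' @slot environment the final [EnvironmentState-class].
#' @slot genealogy a [GenealogyRecord-class] (empty if not recorded).
#' @slot stoppedReason character: "max_generations", "stabilized" or
#'   "absorbed".
#'
#' @export
setClass("MicrobiomeSimulation",
    representation(
        config = "SimulationConfig",
        trajectory = "data.frame",
        finalState = "PopulationState",
        environment = "EnvironmentState",
        genealogy = "GenealogyRecord",
        stoppedReason = "character"
    )
)

#' LogNormalFit: maximum-likelihood log-normal fit
#'
#' @slot mu numeric, location of log-abundance (mean of logs).
#' @slot sigma positive numeric, scale of log-abundance (ML, 1/n
#'   denominator).
#' @slot nObs integer number of observations used.
#' @slot logLik numeric log-likelihood at the optimum.
#'
#' @export
setClass("LogNormalFit",
    representation(mu = "numeric", sigma = "numeric", nObs = "integer",
                   logLik = "numeric"))

setValidity("LogNormalFit", function(object) {
    if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
        object@sigma <= 0)
        return("sigma must be a single positive value")
    TRUE
})

#' DirichletMultinomialFit: maximum-likelihood Dirichlet-multinomial fit
#'
#' Concentration parameters alpha_k of a Dirichlet-multinomial distribution
#' fitted by the monotone digamma fixed-point iteration, plus the
#' overdispersion theta = 1 / (1 + sum(alpha)).
#'
#' @slot concentration positive numeric length-m concentration vector.
#' @slot theta numeric overdispersion in (0, 1).
#' @slot logLik numeric DM log-likelihood at the fitted parameters.
#' @slot converged logical, whether the fixed point met its tolerance.
#' @slot iterations integer iterations used.
#' @slot excludedTaxa integer indices of taxa absent from every sample,
#'   whose concentrations were floored at a tiny epsilon.
#' @slot degenerate logical, flags fits on degenerate inputs (for example a
#'   single taxon present across all samples) whose parameters are not
#'   meaningful maximum-likelihood estimates.
#'
#' @export
setClass("DirichletMultinomialFit",
    representation(concentration = "numeric", theta = "numeric",
                   logLik = "numeric", converged = "logical",
                   iterations = "integer", excludedTaxa = "integer",
                   degenerate = "logical"))

setValidity("DirichletMultinomialFit", function(object) {
    msgs <- character()
    if (any(object@concentration <= 0))
        msgs <- c(msgs, "all concentration entries must be positive")
    if (length(object@theta) != 1L || object@theta <= 0 || object@theta >= 1)
        msgs <- c(msgs, "theta must lie in (0, 1)")
    if (length(msgs)) msgs else TRUE
})

#' AbundanceTable: a labeled taxon x sample relative-abundance matrix
#'
#' In-memory representation of an HMP-style community-profile table: rows
#' are taxonomic lineages (rank-prefixed path strings such as
#' \code{"k__Bacteria|p__Firmicutes|...|g__Lactobacillus"}), columns are
#' samples, values are relative abundances.
#'
#' @slot lineages character vector of lineage strings (one per row).
#' @slot sampleIds character vector of sample identifiers (one per column).
#' @slot values numeric taxon x sample matrix of relative abundances.
#' @slot rank character, the taxonomic rank the rows currently represent
#'   ("mixed" for a multi-rank table as read from disk).
#'
#' @export
setClass("AbundanceTable",
    representation(lineages = "character", sampleIds = "character",
                   values = "matrix", rank = "character"))

setValidity("AbundanceTable", function(object) {
    msgs <- character()
    v <- object@values
    if (nrow(v) != length(object@lineages))
        msgs <- c(msgs, "one lineage per row required")
    if (ncol(v) != length(object@sampleIds))
        msgs <- c(msgs, "one sample id per column required")
    if (any(!is.finite(v)) || any(v < 0))
        msgs <- c(msgs, "values must be finite and non-negative")
    if (anyDuplicated(object@sampleIds))
        msgs <- c(msgs, "sample ids must be unique")
    if (length(msgs)) msgs else TRUE
})

#' GridSpec: a replicated sweep over the acquisition x environment plane
#'
#' @slot xValues ordered numeric parental-fraction values in [0, 1].
#' @slot yValues ordered numeric pooled-environment values in [0, 1].
#' @slot replicates integer independent simulations per cell.
#' @slot baseConfig the [SimulationConfig-class] shared by all cells (its x,
#'   y and seed are overridden per cell/replicate).
#' @slot baseSeed integer seed base; replicate seeds are
#'   \code{baseSeed + (cell - 1) * replicates + (replicate - 1)}.
#'
#' @export
setClass("GridSpec",
    representation(xValues = "numeric", yValues = "numeric",
                   replicates = "integer", baseConfig = "SimulationConfig",
                   baseSeed = "integer"))

setValidity("GridSpec", function(object) {
    msgs <- character()
    if (any(object@xValues < 0 | object@xValues > 1) ||
        any(object@yValues < 0 | object@yValues > 1))
        msgs <- c(msgs, "grid values must lie in [0, 1]")
    if (object@replicates < 1L)
        msgs <- c(msgs, "replicates must be >= 1")
    if (length(msgs)) msgs else TRUE
})

#' GridResult: aggregated diversities over a parameter grid
#'
#' Per-cell mean and standard deviation, across replicates, of the
#' end-of-run alpha-, beta- and gamma-diversity, plus the mean number of
#' generations each cell actually ran.
#'
#' @slot xValues,yValues the grid axes.
#' @slot replicates integer replicates per cell.
#' @slot alphaMean,alphaSd,betaMean,betaSd,gammaMean,gammaSd numeric
#'   |x| x |y| matrices.
#' @slot generations numeric |x| x |y| matrix of mean generations run.
#'
#' @export
setClass("GridResult",
    representation(xValues = "numeric", yValues = "numeric",
                   replicates = "integer",
                   alphaMean = "matrix", alphaSd = "matrix",
                   betaMean = "matrix", betaSd = "matrix",
                   gammaMean = "matrix", gammaSd = "matrix",
                   generations = "matrix"))

setValidity("GridResult", function(object) {
    dims <- c(length(object@xValues), length(object@yValues))
    ok <- vapply(c("alphaMean", "alphaSd", "betaMean", "betaSd",
                   "gammaMean", "gammaSd", "generations"),
                 function(s) identical(dim(slot(object, s)), as.integer(dims)),
                 logical(1L))
    if (!all(ok)) "all matrices must be |xValues| x |yValues|" else TRUE
})
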