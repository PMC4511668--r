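#' Create a simulation configuration
#'
#' Defaults are the reference regime of the model: N = 500 hosts, n = 1000
#' microbiome slots per host, m = 150 environmental taxa, a uniform fixed
#' environmental pool matching the uniform initial seeding, and runs of at
#' least 1e4 generations with halting once the gamma-diversity trajectory
#' stabilizes.
#'
#' @param numHosts host population size N.
#' @param slotsPerHost microbiome capacity n of each host.
#' @param numTaxa number m of taxa in the environmental pool.
#' @param parentalFraction per-slot probability x of parental acquisition.
#' @param pooledEnvFraction weight y of the pooled (host-derived) component
#'   of the environment.
#' @param maxGenerations hard cap on generations.
#' @param recordInterval generations between diversity records.
#' @param seed RNG seed for [runSimulation()].
#' @param stopOnStabilization halt when recorded gamma stabilizes.
#' @param stabilizationWindow window (recorded points) for
#'   [detectStabilization()].
#' @param stabilizationTolerance relative tolerance for
#'   [detectStabilization()].
#' @param minGenerations generations before stabilization may halt the run.
#' @param stopOnAbsorption halt once one taxon remains, in regimes where
#'   that state is absorbing (x = 1 or y = 1).
#' @param recordGenealogy keep the per-generation parent indices.
#' @param fixedDistribution fixed environmental pool (default uniform over
#'   \code{numTaxa}).
#'
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' cfg <- SimulationConfig(numHosts = 20, slotsPerHost = 50, numTaxa = 10,
#'                         parentalFraction = 0.5, maxGenerations = 100)
#' cfg
#' @export
SimulationConfig <- function(numHosts = 500L, slotsPerHost = 1000L,
        numTaxa = 150L, parentalFraction = 0, pooledEnvFraction = 0,
        maxGenerations = 10000L, recordInterval = 100L, seed = 1L,
        stopOnStabilization = TRUE, stabilizationWindow = 500L,
        stabilizationTolerance = 1e-4, minGenerations = 1000L,
        stopOnAbsorption = TRUE, recordGenealogy = TRUE,
        fixedDistribution = NULL) {
    if (is.null(fixedDistribution))
        fixedDistribution <- rep(1 / numTaxa, numTaxa)
    if (any(!is.finite(fixedDistribution)) || any(fixedDistribution < 0) ||
        sum(fixedDistribution) <= 0)
        stop("fixedDistribution must be non-negative with positive total")
    new("SimulationConfig",
        numHosts = as.integer(numHosts),
        slotsPerHost = as.integer(slotsPerHost),
        numTaxa = as.integer(numTaxa),
        parentalFraction = as.numeric(parentalFraction),
        pooledEnvFraction = as.numeric(pooledEnvFraction),
        maxGenerations = as.integer(maxGenerations),
        recordInterval = as.integer(recordInterval),
        seed = as.integer(seed),
        stopOnStabilization = isTRUE(stopOnStabilization),
        stabilizationWindow = as.integer(stabilizationWindow),
        stabilizationTolerance = as.numeric(stabilizationTolerance),
        minGenerations = as.integer(minGenerations),
        stopOnAbsorption = isTRUE(stopOnAbsorption),
        recordGenealogy = isTRUE(recordGenealogy),
        fixedDistribution = fixedDistribution / sum(fixedDistribution))
}

#' Seed the initial host population
#'
#' Each host's n slots are drawn multinomially with equal probability 1/m
#' per taxon (uniform seeding), so the population starts with an even taxon
#' pool. Uses the current RNG state; [runSimulation()] seeds it from the
#' config.
#'
#' @param config a [SimulationConfig-class].
#' @return a [PopulationState-class] at generation 0.
#' @examples
#' set.seed(1)
#' pop <- initializePopulation(SimulationConfig(numHosts = 5,
#'     slotsPerHost = 20, numTaxa = 4))
#' rowSums(hostCounts(pop))
#' @export
initializePopulation <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    p <- rep(1 / config@numTaxa, config@numTaxa)
    counts <- t(rmultinom(config@numHosts, config@slotsPerHost, p))
    colnames(counts) <- paste0("taxon_", seq_len(config@numTaxa) - 1L)
    new("PopulationState", counts = counts, generation = 0L,
        parentIndex = integer(0))
}

#' Compose the environmental pool offered to the next generation
#'
#' Returns \code{y * pooled + (1 - y) * fixed}, where \code{pooled} is the
#' column-sum of the previous generation's host x taxon counts, normalized
#' to relative abundances. With y = 0 this is the fixed environment (FE),
#' with y = 1 the fully pooled environment (PE).
#'
#' @param prevPopulation the previous-generation [PopulationState-class].
#' @param fixedDistribution relative abundances of the fixed pool.
#' @param pooledEnvFraction weight y in [0, 1] of the pooled component.
#' @return a relative-abundance vector summing to 1.
#' @examples
#' set.seed(1)
#' pop <- initializePopulation(SimulationConfig(numHosts = 3,
#'     slotsPerHost = 10, numTaxa = 2))
#' composeEnvironment(pop, c(0.5, 0.5), 0.5)
#' @export
composeEnvironment <- function(prevPopulation, fixedDistribution,
                               pooledEnvFraction) {
    stopifnot(is(prevPopulation, "PopulationState"))
    if (pooledEnvFraction < 0 || pooledEnvFraction > 1)
        stop("pooledEnvFraction must lie in [0, 1]")
    bad <- .checkProb(fixedDistribution, "fixedDistribution", tol = 1e-6)
    if (!is.null(bad)) stop(bad)
    pooled <- colSums(prevPopulation@counts)
    tot <- sum(pooled)
    if (tot <= 0) stop("population has no microbes; cannot pool")
    env <- pooledEnvFraction * (pooled / tot) +
        (1 - pooledEnvFraction) * fixedDistribution
    unname(env / sum(env))
}

#' Sample one offspring microbiome
#'
#' Fills \code{slots} microbiome slots: each slot independently comes from
#' the parent's microbiome with probability x and from the environmental
#' pool otherwise, the taxon then chosen with probability equal to its
#' relative abundance in the chosen source. Implemented as
#' k ~ Binomial(slots, x) parental slots followed by two multinomial draws,
#' which is distributionally identical to the per-slot choice.
#'
#' @param parentCounts the parent's taxon count vector.
#' @param envDistribution environmental relative abundances (sums to 1).
#' @param parentalFraction per-slot parental probability x in [0, 1].
#' @param slots number of slots to fill.
#' @return an integer taxon count vector summing to \code{slots}.
#' @examples
#' set.seed(1)
#' sampleOffspringMicrobiome(c(5L, 5L), c(0.5, 0.5), 0.5, 10L)
#' @export
sampleOffspringMicrobiome <- function(parentCounts, envDistribution,
                                      parentalFraction, slots) {
    if (parentalFraction < 0 || parentalFraction > 1)
        stop("parentalFraction must lie in [0, 1]")
    bad <- .checkProb(envDistribution, "envDistribution", tol = 1e-6)
    if (!is.null(bad)) stop(bad)
    k <- rbinom(1L, slots, parentalFraction)
    out <- integer(length(parentCounts))
    if (k > 0L)
        out <- out + drop(rmultinom(1L, k, parentCounts))
    if (slots - k > 0L)
        out <- out + drop(rmultinom(1L, slots - k, envDistribution))
    out
}

#' Advance the simulation by one host generation
#'
#' The environment offered to the offspring is recomputed from the incoming
#' population first (see [composeEnvironment()]); each of the N offspring
#' then independently draws a uniform-random parent from the current
#' generation and a microbiome via [sampleOffspringMicrobiome()].
#'
#' @param population the current [PopulationState-class].
#' @param environment the current [EnvironmentState-class].
#' @param config the [SimulationConfig-class].
#' @return a list with elements \code{population} (new
#'   [PopulationState-class], generation incremented, parents recorded) and
#'   \code{environment} (the [EnvironmentState-class] with its
#'   \code{currentDistribution} updated).
#' @export
stepGeneration <- function(population, environment, config) {
    N <- config@numHosts
    n <- config@slotsPerHost
    x <- config@parentalFraction
    env <- composeEnvironment(population, environment@fixedDistribution,
                              config@pooledEnvFraction)
    parents <- sample.int(N, N, replace = TRUE)
    cts <- population@counts
    if (x == 0) {
        # all slots environmental: one batched multinomial, identical law
        newCounts <- t(rmultinom(N, n, env))
    } else {
        newCounts <- matrix(0L, nrow = N, ncol = ncol(cts))
        ks <- rbinom(N, n, x)
        for (i in seq_len(N)) {
            k <- ks[[i]]
            row <- integer(ncol(cts))
            if (k > 0L)
                row <- row + drop(rmultinom(1L, k, cts[parents[[i]], ]))
            if (n - k > 0L)
                row <- row + drop(rmultinom(1L, n - k, env))
            newCounts[i, ] <- row
        }
    }
    colnames(newCounts) <- colnames(cts)
    list(
        population = new("PopulationState", counts = newCounts,
            generation = population@generation + 1L, parentIndex = parents),
        environment = new("EnvironmentState",
            fixedDistribution = environment@fixedDistribution,
            currentDistribution = env)
    )
}

.recordDiversity <- function(population) {
    rel <- population@counts / rowSums(population@counts)
    a <- alphaDiversity(rel, richnessMode = "observed")
    c(generation = population@generation,
      alpha_mean = unname(a[["mean"]]), alpha_sd = unname(a[["sd"]]),
      beta = betaDiversity(rel),
      gamma = gammaDiversity(rel, richnessMode = "observed"))
}

#' Run a full neutral microbiome simulation
#'
#' Seeds the RNG from \code{config@seed}, initializes a uniform population,
#' and iterates [stepGeneration()] until \code{maxGenerations}, until the
#' recorded gamma-diversity trajectory stabilizes (if
#' \code{stopOnStabilization}), or until a single taxon remains
#' population-wide in a regime where that state is absorbing
#' (\code{stopOnAbsorption} and x = 1 or y = 1). Diversity is recorded at
#' generation 0 and every \code{recordInterval} generations thereafter,
#' plus at the final generation. Identical seeds give bitwise-identical
#' results.
#'
#' @param config a [SimulationConfig-class].
#' @return a [MicrobiomeSimulation-class] object.
#' @examples
#' sim <- runSimulation(SimulationConfig(numHosts = 10, slotsPerHost = 30,
#'     numTaxa = 5, parentalFraction = 0.5, maxGenerations = 50,
#'     recordInterval = 10, seed = 42, stopOnStabilization = FALSE))
#' trajectory(sim)
#' @export
runSimulation <- function(config) {
    validObject(config)
    set.seed(config@seed)
    pop <- initializePopulation(config)
    env <- new("EnvironmentState",
               fixedDistribution = config@fixedDistribution,
               currentDistribution = config@fixedDistribution)
    absorbing <- config@parentalFraction == 1 ||
        config@pooledEnvFraction == 1
    parents <- if (config@recordGenealogy)
        vector("list", config@maxGenerations) else list()
    records <- list(.recordDiversity(pop))
    gammas <- records[[1L]][["gamma"]]
    reason <- "max_generations"
    g <- 0L
    while (g < config@maxGenerations) {
        stepped <- stepGeneration(pop, env, config)
        pop <- stepped$population
        env <- stepped$environment
        g <- g + 1L
        if (config@recordGenealogy)
            parents[[g]] <- pop@parentIndex
        recorded <- FALSE
        if (g %% config@recordInterval == 0L || g == config@maxGenerations) {
            rec <- .recordDiversity(pop)
            records[[length(records) + 1L]] <- rec
            gammas <- c(gammas, rec[["gamma"]])
            recorded <- TRUE
        }
        if (config@stopOnAbsorption && absorbing &&
            sum(colSums(pop@counts) > 0) == 1L) {
            reason <- "absorbed"
            break
        }
        if (config@stopOnStabilization && recorded &&
            g >= config@minGenerations &&
            detectStabilization(gammas, config@stabilizationWindow,
                                config@stabilizationTolerance)) {
            reason <- "stabilized"
            break
        }
    }
    if (records[[length(records)]][["generation"]] != g)
        records[[length(records) + 1L]] <- .recordDiversity(pop)
    traj <- as.data.frame(do.call(rbind, records))
    new("MicrobiomeSimulation", config = config, trajectory = traj,
        finalState = pop, environment = env,
        genealogy = new("GenealogyRecord",
                        parents = parents[seq_len(if (config@recordGenealogy)
                            g else 0L)]),
        stoppedReason = reason)
}

#' Simulate a bare Wright-Fisher host genealogy
#'
#' Draws the parent indices of a constant-size asexual Wright-Fisher host
#' population without simulating microbiomes; useful for genealogical
#' properties such as the ~2N-generation expectation of the time to the
#' most recent common ancestor.
#'
#' @param numHosts host population size N.
#' @param generations number of generations to simulate.
#' @return a [GenealogyRecord-class].
#' @examples
#' set.seed(1)
#' mrcaGeneration(simulateGenealogy(10, 100))
#' @export
simulateGenealogy <- function(numHosts, generations) {
    numHosts <- as.integer(numHosts)
    new("GenealogyRecord",
        parents = replicate(as.integer(generations),
                            sample.int(numHosts, numHosts, replace = TRUE),
                            simplify = FALSE))
}

#' Generations back to the most recent common ancestor
#'
#' Traces every extant host's lineage backwards through the recorded
#' genealogy and returns the number of generations back from the final
#' generation at which all hosts first share a single ancestor, or
#' \code{NA} if coalescence does not occur within the recorded history.
#'
#' @param x a [GenealogyRecord-class] or [MicrobiomeSimulation-class].
#' @return integer depth of the MRCA (1 = all hosts share a parent in the
#'   last step), or \code{NA_integer_}.
#' @examples
#' g <- new("GenealogyRecord", parents = list(c(1L, 1L, 2L), c(2L, 2L, 2L)))
#' mrcaGeneration(g)
#' @rdname mrcaGeneration
#' @export
setMethod("mrcaGeneration", "GenealogyRecord", function(x) {
    ngen <- length(x@parents)
    if (ngen == 0L) stop("empty genealogy")
    N <- length(x@parents[[1L]])
    if (N == 1L) return(1L)
    anc <- seq_len(N)
    for (d in seq_len(ngen)) {
        anc <- x@parents[[ngen - d + 1L]][anc]
        if (all(anc == anc[[1L]])) return(d)
        anc <- unique(anc)
    }
    NA_integer_
})

#' @rdname mrcaGeneration
#' @export
setMethod("mrcaGeneration", "MicrobiomeSimulation",
          function(x) mrcaGeneration(x@genealogy))
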