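# Independent oracles used across the suite.

# Brute-force mean pairwise Bray-Curtis over all unordered row pairs,
# written as the explicit double loop over the definition.
bruteBeta <- function(mat) {
    rel <- mat / rowSums(mat)
    n <- nrow(rel)
    tot <- 0
    for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
            tot <- tot + sum(abs(rel[i, ] - rel[j, ])) / 2
        }
    }
    tot / (n * (n - 1L) / 2)
}

# Direct evaluation of the scaled Shannon definition (no shared code path).
bruteScaledShannon <- function(p, R = sum(p > 0)) {
    if (R <= 1) return(0)
    p <- p[p > 0]
    s <- 0
    for (pi in p) s <- s - pi * log(pi)
    s / log(R)
}

# Small fast configuration for structural tests.
tinyConfig <- function(...) {
    args <- list(numHosts = 8L, slotsPerHost = 20L, numTaxa = 5L,
                 maxGenerations = 40L, recordInterval = 10L, seed = 123L,
                 stopOnStabilization = FALSE, recordGenealogy = TRUE)
    mod <- list(...)
    args[names(mod)] <- mod
    do.call(SimulationConfig, args)
}

finalTaxa <- function(sim) sum(colSums(hostCounts(sim)) > 0)
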