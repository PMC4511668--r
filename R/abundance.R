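#' Population-wide relative taxon abundances
#'
#' Column sums of the host x taxon count matrix normalized to sum 1: the
#' relative abundance of each taxon across the entire host population.
#' This is the emergent abundance distribution that becomes skewed under
#' high parental contribution and is the default input to the log-normal
#' and Dirichlet-multinomial fits.
#'
#' @param x a [PopulationState-class], [MicrobiomeSimulation-class], or
#'   host x taxon matrix.
#' @return a relative-abundance vector summing to 1.
#' @examples
#' set.seed(1)
#' pop <- initializePopulation(SimulationConfig(numHosts = 4,
#'     slotsPerHost = 25, numTaxa = 5))
#' populationAbundance(pop)
#' @rdname populationAbundance
#' @export
setMethod("populationAbundance", "matrix", function(x) {
    cs <- colSums(x)
    cs / sum(cs)
})

#' @rdname populationAbundance
#' @export
setMethod("populationAbundance", "PopulationState",
          function(x) populationAbundance(x@counts))

#' @rdname populationAbundance
#' @export
setMethod("populationAbundance", "MicrobiomeSimulation",
          function(x) populationAbundance(x@finalState))

#' Maximum-likelihood log-normal fit
#'
#' Closed-form ML estimates of a log-normal on strictly positive
#' abundances: \code{mu} is the mean of the logs and \code{sigma} the ML
#' (1/n denominator) standard deviation of the logs. Zeros must be
#' excluded upstream (the fit describes the nonzero part of a skewed
#' abundance distribution); nonpositive input is rejected.
#'
#' @param abundances strictly positive numeric values.
#' @return a [LogNormalFit-class].
#' @examples
#' set.seed(1)
#' fitLognormal(rlnorm(500, meanlog = -5, sdlog = 1))
#' @export
fitLognormal <- function(abundances) {
    if (!is.numeric(abundances) || length(abundances) < 2L)
        stop("need at least two abundance values")
    if (any(!is.finite(abundances)) || any(abundances <= 0))
        stop("log-normal fitting requires strictly positive abundances; ",
             "exclude zeros upstream")
    lx <- log(abundances)
    mu <- mean(lx)
    sigma <- sqrt(mean((lx - mu)^2))
    if (sigma <= 0)
        stop("degenerate fit: all abundances identical (sigma = 0 boundary)")
    new("LogNormalFit", mu = mu, sigma = sigma,
        nObs = length(abundances),
        logLik = sum(dlnorm(abundances, mu, sigma, log = TRUE)))
}

.dmLogLik <- function(counts, alpha) {
    a0 <- sum(alpha)
    n <- rowSums(counts)
    const <- sum(lgamma(n + 1)) - sum(lgamma(counts + 1))
    const + sum(lgamma(a0) - lgamma(n + a0)) +
        sum(lgamma(sweep(counts, 2L, alpha, "+")) -
            matrix(lgamma(alpha), nrow(counts), ncol(counts), byrow = TRUE))
}

.dmMomentInit <- function(counts) {
    props <- counts / rowSums(counts)
    pbar <- colMeans(props)
    v <- apply(props, 2L, var)
    keep <- pbar > 0 & pbar < 1 & v > 0
    if (!any(keep)) return(NULL)
    # per-taxon method-of-moments precision, pooled by the median
    s <- pbar[keep] * (1 - pbar[keep]) / v[keep] - 1
    s <- stats::median(s[s > 0])
    if (!length(s) || !is.finite(s) || s <= 0) s <- 1
    pmax(s * pbar, 1e-10)
}

#' Maximum-likelihood Dirichlet-multinomial fit
#'
#' Fits the concentration vector of a Dirichlet-multinomial distribution
#' to a sample x taxon count matrix by the digamma fixed-point iteration
#' \deqn{\alpha_k \leftarrow \alpha_k
#'   \frac{\sum_i [\psi(x_{ik} + \alpha_k) - \psi(\alpha_k)]}
#'        {\sum_i [\psi(n_i + \alpha_0) - \psi(\alpha_0)]},}
#' a minorize-maximize scheme whose log-likelihood is non-decreasing across
#' iterations. Initialization is by method of moments. Taxa absent from
#' every sample are floored at a tiny concentration and flagged in
#' \code{excludedTaxa}. Degenerate inputs (fewer than two taxa ever
#' observed, or zero between-sample variation) are flagged rather than
#' fitted silently; non-convergence within the iteration budget is
#' reported with a warning.
#'
#' @param countSamples sample x taxon matrix of non-negative integer
#'   counts, at least two rows, each with positive total.
#' @param maxIterations iteration cap (default 1e4).
#' @param tol convergence threshold on the largest absolute parameter
#'   change (default 1e-8).
#' @return a [DirichletMultinomialFit-class].
#' @examples
#' set.seed(1)
#' tab <- rDirichletMultinomial(50, depth = 200, concentration = rep(2, 5))
#' fitDirichletMultinomial(tab)
#' @export
fitDirichletMultinomial <- function(countSamples, maxIterations = 10000L,
                                    tol = 1e-8) {
    counts <- as.matrix(countSamples)
    if (nrow(counts) < 2L)
        stop("need at least two samples")
    if (any(counts < 0) || any(!is.finite(counts)))
        stop("counts must be finite and non-negative")
    if (any(rowSums(counts) < 1))
        stop("every sample must contain at least one count")
    m <- ncol(counts)
    absent <- which(colSums(counts) == 0)
    alpha <- .dmMomentInit(counts)
    if (is.null(alpha)) {
        # no between-sample variation to estimate a precision from
        pbar <- colMeans(counts / rowSums(counts))
        alpha <- pmax(pbar, 1e-10)
        fit <- new("DirichletMultinomialFit", concentration = alpha,
                   theta = 1 / (1 + sum(alpha)),
                   logLik = .dmLogLik(counts, alpha),
                   converged = FALSE, iterations = 0L,
                   excludedTaxa = as.integer(absent), degenerate = TRUE)
        warning("degenerate Dirichlet-multinomial input ",
                "(no usable between-sample variation); fit flagged")
        return(fit)
    }
    n <- rowSums(counts)
    iter <- 0L
    converged <- FALSE
    while (iter < maxIterations) {
        iter <- iter + 1L
        a0 <- sum(alpha)
        denom <- sum(digamma(n + a0) - digamma(a0))
        num <- colSums(digamma(sweep(counts, 2L, alpha, "+"))) -
            nrow(counts) * digamma(alpha)
        alphaNew <- pmax(alpha * num / denom, 1e-10)
        delta <- max(abs(alphaNew - alpha))
        alpha <- alphaNew
        if (delta < tol) {
            converged <- TRUE
            break
        }
    }
    if (!converged)
        warning("Dirichlet-multinomial fit did not converge within ",
                maxIterations, " iterations (last step ", signif(tol, 3), "+)")
    new("DirichletMultinomialFit", concentration = unname(alpha),
        theta = 1 / (1 + sum(alpha)),
        logLik = .dmLogLik(counts, alpha),
        converged = converged, iterations = iter,
        excludedTaxa = as.integer(absent), degenerate = FALSE)
}

#' Draw samples from a Dirichlet-multinomial distribution
#'
#' Each sample draws a composition from Dirichlet(\code{concentration})
#' (via normalized gammas) and then \code{depth} counts multinomially from
#' it.
#'
#' @param numSamples number of samples (rows).
#' @param depth total counts per sample.
#' @param concentration positive concentration vector.
#' @return a numSamples x m integer count matrix.
#' @examples
#' set.seed(1)
#' rDirichletMultinomial(3, 20, c(1, 1, 5))
#' @export
rDirichletMultinomial <- function(numSamples, depth, concentration) {
    stopifnot(all(concentration > 0), numSamples >= 1, depth >= 1)
    m <- length(concentration)
    out <- matrix(0L, numSamples, m)
    for (i in seq_len(numSamples)) {
        g <- rgamma(m, shape = concentration, rate = 1)
        if (sum(g) <= 0) g[which.max(concentration)] <- 1
        out[i, ] <- drop(rmultinom(1L, depth, g / sum(g)))
    }
    out
}

#' Reconstruct diversities from a fitted Dirichlet-multinomial
#'
#' Re-simulates sample x taxon tables from the fitted concentration vector
#' (Dirichlet composition, then multinomial counts at the given depth),
#' computes alpha-, beta- and gamma-diversity on each table, and averages
#' over replicates. This is the model-based re-estimation used to check
#' how much of the simulated diversity structure a Dirichlet-multinomial
#' summary retains.
#'
#' @param fit a [DirichletMultinomialFit-class].
#' @param numSamples communities per replicate table.
#' @param depth counts per community.
#' @param replicates number of replicate tables averaged (default 10).
#' @return named numeric vector \code{c(alpha_mean, beta, gamma)};
#'   \code{beta} is \code{NA} when \code{numSamples} is 1.
#' @examples
#' set.seed(1)
#' tab <- rDirichletMultinomial(50, 200, rep(2, 5))
#' fit <- fitDirichletMultinomial(tab)
#' reconstructDiversitiesFromDM(fit, numSamples = 50, depth = 200)
#' @export
reconstructDiversitiesFromDM <- function(fit, numSamples, depth,
                                         replicates = 10L) {
    stopifnot(is(fit, "DirichletMultinomialFit"))
    res <- vapply(seq_len(replicates), function(r) {
        tab <- rDirichletMultinomial(numSamples, depth, fit@concentration)
        a <- alphaDiversity(tab)[["mean"]]
        b <- if (numSamples > 1L) betaDiversity(tab) else NA_real_
        g <- gammaDiversity(tab)
        c(a, b, g)
    }, numeric(3L))
    out <- rowMeans(res)
    names(out) <- c("alpha_mean", "beta", "gamma")
    out
}
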