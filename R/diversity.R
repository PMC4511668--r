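#' Scaled Shannon-Wiener diversity index
#'
#' Computes \eqn{-\sum_{i: p_i > 0} p_i \ln p_i / \ln R}, the Shannon
#' entropy of a relative-abundance vector scaled by the log of the taxon
#' richness R, so that the index lies in [0, 1] with 1 at a perfectly even
#' community. R is either the number of taxa with nonzero abundance
#' (\code{"observed"}, default) or an externally supplied pool size
#' (\code{"global"}). With R <= 1 the ratio is 0/0 and the index is defined
#' as 0; terms with \eqn{p_i = 0} contribute nothing.
#'
#' @param relAbundances non-negative numeric vector summing to 1.
#' @param richnessMode \code{"observed"} or \code{"global"}.
#' @param globalRichness required pool size when
#'   \code{richnessMode = "global"}.
#' @return a number in [0, 1].
#' @examples
#' scaledShannon(rep(0.2, 5))            # maximally even: 1
#' scaledShannon(c(1, 0, 0))             # single taxon: 0
#' scaledShannon(c(0.5, 0.25, 0.25))
#' @export
scaledShannon <- function(relAbundances,
                          richnessMode = c("observed", "global"),
                          globalRichness = NULL) {
    richnessMode <- match.arg(richnessMode)
    bad <- .checkProb(relAbundances, "relAbundances", tol = 1e-6)
    if (!is.null(bad)) stop(bad)
    R <- if (richnessMode == "observed") {
        sum(relAbundances > 0)
    } else {
        if (is.null(globalRichness))
            stop("global richness mode requires globalRichness")
        as.integer(globalRichness)
    }
    if (R <= 1L) return(0)
    p <- relAbundances[relAbundances > 0]
    -sum(p * log(p)) / log(R)
}

.normalizeRows <- function(mat) {
    mat <- as.matrix(mat)
    if (nrow(mat) < 1L) stop("matrix must have at least one row")
    rs <- rowSums(mat)
    if (any(rs <= 0)) stop("every row must have positive total abundance")
    mat / rs
}

#' Alpha-diversity: mean within-community scaled Shannon index
#'
#' Row-normalizes a community x taxon matrix, computes [scaledShannon()]
#' per row, and summarizes across rows. The dispersion reported is the
#' standard deviation by default; \code{dispersion = "se"} divides by
#' \code{sqrt(#rows)}.
#'
#' @param x a community x taxon matrix of counts or relative abundances, a
#'   [PopulationState-class], or an [AbundanceTable-class] (samples become
#'   rows).
#' @param richnessMode,globalRichness passed to [scaledShannon()].
#' @param dispersion \code{"sd"} (default) or \code{"se"}.
#' @param ... passed on between methods.
#' @return named numeric vector \code{c(mean = , sd = )} (the second
#'   element is named \code{se} when requested).
#' @examples
#' alphaDiversity(rbind(c(1, 0), c(0.5, 0.5)))
#' @rdname alphaDiversity
#' @export
setMethod("alphaDiversity", "matrix", function(x,
        richnessMode = c("observed", "global"), globalRichness = NULL,
        dispersion = c("sd", "se"), ...) {
    richnessMode <- match.arg(richnessMode)
    dispersion <- match.arg(dispersion)
    rel <- .normalizeRows(x)
    vals <- apply(rel, 1L, scaledShannon, richnessMode = richnessMode,
                  globalRichness = globalRichness)
    disp <- if (nrow(rel) > 1L) sd(vals) else 0
    if (dispersion == "se") disp <- disp / sqrt(nrow(rel))
    out <- c(mean(vals), disp)
    names(out) <- c("mean", dispersion)
    out
})

#' @rdname alphaDiversity
#' @export
setMethod("alphaDiversity", "PopulationState",
          function(x, ...) alphaDiversity(x@counts, ...))

#' @rdname alphaDiversity
#' @export
setMethod("alphaDiversity", "AbundanceTable",
          function(x, ...) alphaDiversity(t(x@values), ...))

#' Gamma-diversity: scaled Shannon index of the pooled community
#'
#' Pools all rows (column sums), normalizes to relative abundances, and
#' applies [scaledShannon()].
#'
#' @inheritParams alphaDiversity
#' @return a number in [0, 1].
#' @examples
#' gammaDiversity(rbind(c(1, 0), c(0, 1)))   # pooled 50/50: 1
#' @rdname gammaDiversity
#' @export
setMethod("gammaDiversity", "matrix", function(x,
        richnessMode = c("observed", "global"), globalRichness = NULL, ...) {
    richnessMode <- match.arg(richnessMode)
    x <- .normalizeRows(x)
    pooled <- colSums(x)
    scaledShannon(pooled / sum(pooled), richnessMode = richnessMode,
                  globalRichness = globalRichness)
})

#' @rdname gammaDiversity
#' @export
setMethod("gammaDiversity", "PopulationState",
          function(x, ...) gammaDiversity(x@counts, ...))

#' @rdname gammaDiversity
#' @export
setMethod("gammaDiversity", "AbundanceTable",
          function(x, ...) gammaDiversity(t(x@values), ...))

.brayPairs <- function(relMat) {
    # relMat rows sum to 1, so Bray-Curtis reduces to sum|p_i - p_j| / 2
    vegan::vegdist(relMat, method = "bray")
}

#' Beta-diversity: mean pairwise Bray-Curtis dissimilarity
#'
#' Row-normalizes the matrix and averages the Bray-Curtis dissimilarity
#' \eqn{\sum_k |p_{ik} - p_{jk}| / 2} over all unordered pairs of rows.
#' With fewer than two rows the quantity is undefined and \code{NA} is
#' returned with a warning (deliberately distinct from 0).
#'
#' @inheritParams alphaDiversity
#' @return a number in [0, 1], or \code{NA_real_} for a single community.
#' @examples
#' betaDiversity(rbind(c(1, 0), c(0.5, 0.5)))  # 0.5
#' @rdname betaDiversity
#' @export
setMethod("betaDiversity", "matrix", function(x, ...) {
    rel <- .normalizeRows(x)
    if (nrow(rel) < 2L) {
        warning("beta-diversity undefined for fewer than 2 communities")
        return(NA_real_)
    }
    mean(.brayPairs(rel))
})

#' @rdname betaDiversity
#' @export
setMethod("betaDiversity", "PopulationState",
          function(x, ...) betaDiversity(x@counts, ...))

#' @rdname betaDiversity
#' @export
setMethod("betaDiversity", "AbundanceTable",
          function(x, ...) betaDiversity(t(x@values), ...))

#' Detect stabilization of a gamma-diversity trajectory
#'
#' Operationalizes "halt once the diversity trajectory has stabilized": the
#' series is considered stable when it holds at least \code{2 * window}
#' points and the means of the last and second-to-last windows differ by
#' less than \code{tolerance} in relative terms.
#'
#' @param series ordered numeric series of recorded values.
#' @param window window length in points (>= 2).
#' @param tolerance relative-change threshold.
#' @return \code{TRUE} or \code{FALSE}.
#' @examples
#' detectStabilization(rep(0.8, 20), window = 5)
#' detectStabilization(seq(0, 1, length.out = 20), window = 5)
#' @export
detectStabilization <- function(series, window = 500L, tolerance = 1e-4) {
    window <- as.integer(window)
    if (window < 2L) stop("window must be >= 2")
    npts <- length(series)
    if (npts < 2L * window) return(FALSE)
    m1 <- mean(series[(npts - window + 1L):npts])
    m0 <- mean(series[(npts - 2L * window + 1L):(npts - window)])
    abs(m1 - m0) / max(abs(m0), 1e-12) < tolerance
}
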