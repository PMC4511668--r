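#' @rdname hostCounts
#' @export
setGeneric("hostCounts", function(x) standardGeneric("hostCounts"))

#' Generation index of a population state or finished simulation
#'
#' @param x a [PopulationState-class] or [MicrobiomeSimulation-class].
#' @return non-negative integer generation index.
#' @rdname generation
#' @export
setGeneric("generation", function(x) standardGeneric("generation"))

#' Recorded diversity trajectory of a simulation
#'
#' @param x a [MicrobiomeSimulation-class].
#' @return data.frame with columns \code{generation}, \code{alpha_mean},
#'   \code{alpha_sd}, \code{beta}, \code{gamma}.
#' @rdname trajectory
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' Final population state of a simulation
#'
#' @param x a [MicrobiomeSimulation-class].
#' @return the final [PopulationState-class].
#' @rdname finalState
#' @export
setGeneric("finalState", function(x) standardGeneric("finalState"))

#' Recorded host genealogy of a simulation
#'
#' @param x a [MicrobiomeSimulation-class].
#' @return a [GenealogyRecord-class].
#' @rdname genealogy
#' @export
setGeneric("genealogy", function(x) standardGeneric("genealogy"))

#' @rdname alphaDiversity
#' @export
setGeneric("alphaDiversity", function(x, ...) standardGeneric("alphaDiversity"))

#' @rdname gammaDiversity
#' @export
setGeneric("gammaDiversity", function(x, ...) standardGeneric("gammaDiversity"))

#' @rdname betaDiversity
#' @export
setGeneric("betaDiversity", function(x, ...) standardGeneric("betaDiversity"))

#' @rdname populationAbundance
#' @export
setGeneric("populationAbundance",
           function(x) standardGeneric("populationAbundance"))

#' @rdname mrcaGeneration
#' @export
setGeneric("mrcaGeneration", function(x) standardGeneric("mrcaGeneration"))
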