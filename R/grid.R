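#' Preset parameter-grid axis values
#'
#' The three canonical axes for sweeping the parental-acquisition fraction
#' x and the pooled-environment fraction y: a linear grid (0 to 1 in steps
#' of 0.1), a power grid concentrated near 0
#' (\{0\} and \{0.5^j, j = 10..0\}), and a power grid concentrated near 1
#' (\{1 - 0.5^j, j = 0..20\}, which contains the 0.984 = 1 - 0.5^6 and
#' 0.999 levels used for "high parental contribution" regimes).
#'
#' @param name \code{"linear"}, \code{"power_small"} or
#'   \code{"power_large"}.
#' @return ordered numeric vector of axis values in [0, 1].
#' @examples
#' presetGridValues("linear")
#' presetGridValues("power_large")[7]   # 1 - 0.5^6 = 0.984375
#' @export
presetGridValues <- function(name = c("linear", "power_small",
                                      "power_large")) {
    name <- match.arg(name)
    switch(name,
        linear = seq(0, 1, by = 0.1),
        power_small = c(0, 0.5^(10:0)),
        power_large = 1 - 0.5^(0:20))
}

#' Construct a grid specification
#'
#' @param xValues,yValues axis values in [0, 1]; either explicit numeric
#'   vectors or a preset name accepted by [presetGridValues()].
#' @param replicates independent simulations per cell (the reference
#'   protocol uses 10).
#' @param baseConfig shared [SimulationConfig-class]; its x, y and seed
#'   are overridden per cell and replicate.
#' @param baseSeed integer seed base; replicate r of cell c runs with seed
#'   \code{baseSeed + (c - 1) * replicates + (r - 1)}, so cells are
#'   order-insensitive and independently reproducible.
#' @return a [GridSpec-class].
#' @export
GridSpec <- function(xValues = "linear", yValues = "linear",
                     replicates = 10L, baseConfig = SimulationConfig(),
                     baseSeed = 1L) {
    if (is.character(xValues)) xValues <- presetGridValues(xValues)
    if (is.character(yValues)) yValues <- presetGridValues(yValues)
    new("GridSpec", xValues = as.numeric(xValues),
        yValues = as.numeric(yValues), replicates = as.integer(replicates),
        baseConfig = baseConfig, baseSeed = as.integer(baseSeed))
}

.cellConfig <- function(base, x, y, seed) {
    cfg <- base
    cfg@parentalFraction <- x
    cfg@pooledEnvFraction <- y
    cfg@seed <- as.integer(seed)
    cfg
}

#' Run a replicated parameter sweep
#'
#' Runs \code{replicates} independent simulations for every (x, y) cell of
#' the grid and aggregates the end-of-run alpha-, beta- and gamma-
#' diversities (mean and sd across replicates). Replicate seeds are derived
#' deterministically from the base seed and the cell/replicate indices, so
#' results are bit-identical across repeated invocations and insensitive
#' to evaluation order.
#'
#' @param grid a [GridSpec-class].
#' @param verbose print per-cell progress to stderr.
#' @return a [GridResult-class].
#' @examples
#' cfg <- SimulationConfig(numHosts = 8, slotsPerHost = 20, numTaxa = 5,
#'     maxGenerations = 30, recordInterval = 10,
#'     stopOnStabilization = FALSE, recordGenealogy = FALSE)
#' res <- runGrid(GridSpec(c(0, 1), c(0, 1), replicates = 2,
#'     baseConfig = cfg, baseSeed = 7))
#' res@gammaMean
#' @export
runGrid <- function(grid, verbose = FALSE) {
    stopifnot(is(grid, "GridSpec"))
    validObject(grid)
    nx <- length(grid@xValues)
    ny <- length(grid@yValues)
    dims <- c(nx, ny)
    mk <- function() matrix(NA_real_, nx, ny,
                            dimnames = list(paste0("x_", grid@xValues),
                                            paste0("y_", grid@yValues)))
    out <- list(alphaMean = mk(), alphaSd = mk(), betaMean = mk(),
                betaSd = mk(), gammaMean = mk(), gammaSd = mk(),
                generations = mk())
    for (ix in seq_len(nx)) {
        for (iy in seq_len(ny)) {
            cell <- (ix - 1L) * ny + iy
            finals <- vapply(seq_len(grid@replicates), function(r) {
                seed <- grid@baseSeed + (cell - 1L) * grid@replicates +
                    (r - 1L)
                cfg <- .cellConfig(grid@baseConfig, grid@xValues[[ix]],
                                   grid@yValues[[iy]], seed)
                sim <- tryCatch(runSimulation(cfg), error = function(e)
                    stop("grid cell (x=", grid@xValues[[ix]], ", y=",
                         grid@yValues[[iy]], "), replicate ", r, ": ",
                         conditionMessage(e)))
                tr <- sim@trajectory
                last <- tr[nrow(tr), ]
                c(last$alpha_mean, last$beta, last$gamma, last$generation)
            }, numeric(4L))
            sdOr0 <- function(v) if (length(v) > 1L) sd(v) else 0
            out$alphaMean[ix, iy] <- mean(finals[1L, ])
            out$alphaSd[ix, iy] <- sdOr0(finals[1L, ])
            out$betaMean[ix, iy] <- mean(finals[2L, ])
            out$betaSd[ix, iy] <- sdOr0(finals[2L, ])
            out$gammaMean[ix, iy] <- mean(finals[3L, ])
            out$gammaSd[ix, iy] <- sdOr0(finals[3L, ])
            out$generations[ix, iy] <- mean(finals[4L, ])
            if (verbose)
                message(sprintf("cell x=%g y=%g done (gamma=%.3f)",
                                grid@xValues[[ix]], grid@yValues[[iy]],
                                out$gammaMean[ix, iy]))
        }
    }
    new("GridResult", xValues = grid@xValues, yValues = grid@yValues,
        replicates = grid@replicates, alphaMean = out$alphaMean,
        alphaSd = out$alphaSd, betaMean = out$betaMean,
        betaSd = out$betaSd, gammaMean = out$gammaMean,
        gammaSd = out$gammaSd, generations = out$generations)
}

#' Write grid result matrices to CSV
#'
#' Writes seven CSV matrices (alpha/beta/gamma means and sds, plus mean
#' generations run), rows labeled by x values and columns by y values.
#' File contents are deterministic for fixed inputs.
#'
#' @param result a [GridResult-class].
#' @param outDir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
writeGridTables <- function(result, outDir) {
    stopifnot(is(result, "GridResult"))
    if (!dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    slots <- c(alpha_mean = "alphaMean", alpha_sd = "alphaSd",
               beta_mean = "betaMean", beta_sd = "betaSd",
               gamma_mean = "gammaMean", gamma_sd = "gammaSd",
               generations = "generations")
    paths <- character(0)
    for (nm in names(slots)) {
        p <- file.path(outDir, paste0(nm, ".csv"))
        write.csv(slot(result, slots[[nm]]), p)
        paths <- c(paths, p)
    }
    invisible(paths)
}

#' Write a simulation trajectory to CSV
#'
#' Header: \code{generation,alpha_mean,alpha_sd,beta,gamma}.
#'
#' @param sim a [MicrobiomeSimulation-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeTrajectory <- function(sim, path) {
    stopifnot(is(sim, "MicrobiomeSimulation"))
    write.csv(sim@trajectory, path, row.names = FALSE)
    invisible(path)
}

#' Write the final host x taxon count matrix to CSV
#'
#' Host ids as rows, \code{taxon_0..taxon_{m-1}} as columns.
#'
#' @param sim a [MicrobiomeSimulation-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeFinalState <- function(sim, path) {
    stopifnot(is(sim, "MicrobiomeSimulation"))
    cts <- sim@finalState@counts
    rownames(cts) <- paste0("host_", seq_len(nrow(cts)) - 1L)
    write.csv(cts, path)
    invisible(path)
}

#' Read a flat key-value simulation config file
#'
#' Parses a flat \code{key: value} text file (one pair per line, \code{#}
#' comments allowed) whose keys mirror the [SimulationConfig()] arguments,
#' and returns the corresponding config. Values given in
#' \code{overrides} take precedence over file values (the CLI uses this
#' for flag overrides).
#'
#' @param path path to the key-value file.
#' @param overrides named list of argument overrides.
#' @return a [SimulationConfig-class].
#' @export
readSimulationConfigFile <- function(path, overrides = list()) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    kv <- regmatches(lines, regexec("^([A-Za-z][A-Za-z0-9_]*)\\s*:\\s*(.+)$",
                                    lines))
    bad <- lengths(kv) != 3L
    if (any(bad))
        stop("unparseable config line(s): ",
             paste(head(lines[bad], 3L), collapse = "; "))
    args <- stats::setNames(lapply(kv, function(x) {
        v <- trimws(x[[3L]])
        if (v %in% c("true", "TRUE", "True")) TRUE
        else if (v %in% c("false", "FALSE", "False")) FALSE
        else if (grepl("^-?[0-9.eE+-]+$", v)) as.numeric(v)
        else v
    }), vapply(kv, `[[`, character(1L), 2L))
    args[names(overrides)] <- overrides
    known <- names(formals(SimulationConfig))
    unknown <- setdiff(names(args), known)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    do.call(SimulationConfig, args)
}
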