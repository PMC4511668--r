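.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
            "species")
.RANK_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")

.splitLineage <- function(lineage, delim) {
    strsplit(lineage, delim, fixed = TRUE)
}

.detectDelim <- function(lineages) {
    if (any(grepl("|", lineages, fixed = TRUE))) "|"
    else if (any(grepl(";", lineages, fixed = TRUE))) ";"
    else "|"
}

.componentRank <- function(component) {
    hit <- which(vapply(.RANK_PREFIXES, function(p)
        startsWith(component, p), logical(1L)))
    if (length(hit)) hit[[1L]] else NA_integer_
}

# rank index (1 = kingdom .. 7 = species) of the deepest component;
# falls back to positional depth when components carry no rank prefixes
.lineageRankIndex <- function(parts) {
    r <- .componentRank(parts[[length(parts)]])
    if (is.na(r)) length(parts) else r
}

#' Construct an AbundanceTable
#'
#' @param values numeric taxon x sample matrix of relative abundances.
#' @param lineages character lineage strings, one per row.
#' @param sampleIds character sample ids, one per column.
#' @param rank taxonomic rank of the rows ("mixed" for multi-rank tables).
#' @return an [AbundanceTable-class].
#' @examples
#' AbundanceTable(matrix(c(0.6, 0.4), 2, 1),
#'     c("k__Bacteria|p__A", "k__Bacteria|p__B"), "sample1")
#' @export
AbundanceTable <- function(values, lineages, sampleIds, rank = "mixed") {
    values <- as.matrix(values)
    dimnames(values) <- list(lineages, sampleIds)
    new("AbundanceTable", lineages = as.character(lineages),
        sampleIds = as.character(sampleIds), values = values,
        rank = rank)
}

#' @describeIn AbundanceTable lineage strings of the rows.
#' @param x an [AbundanceTable-class].
#' @export
lineages <- function(x) x@lineages

#' @describeIn AbundanceTable sample identifiers of the columns.
#' @export
sampleIds <- function(x) x@sampleIds

#' @describeIn AbundanceTable the taxon x sample abundance matrix.
#' @export
abundanceValues <- function(x) x@values

#' @describeIn AbundanceTable the rank the rows currently represent.
#' @export
tableRank <- function(x) x@rank

#' Read an HMP-style community-profile table
#'
#' Parses a tab-delimited table whose first column holds rank-prefixed
#' taxonomic lineage strings (pipe- or semicolon-delimited components,
#' auto-detected) and whose remaining columns hold numeric relative
#' abundances per sample. All ranks present in the file are retained;
#' malformed numeric cells are rejected with their row and column
#' coordinates.
#'
#' @param path path to the tab-delimited file.
#' @return an [AbundanceTable-class] with \code{rank} set to the common
#'   row rank, or "mixed".
#' @seealso [writeProfileTable()], [generateSyntheticProfile()]
#' @export
readProfileTable <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2L)
        stop("profile table needs a header line and at least one data row")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    header <- fields[[1L]]
    if (length(header) < 2L)
        stop("header must name a lineage column and at least one sample")
    if (any(!is.na(suppressWarnings(as.numeric(header[-1L])))))
        stop("missing header: first line contains numeric values")
    ncols <- length(header)
    body <- fields[-1L]
    ragged <- which(lengths(body) != ncols)
    if (length(ragged))
        stop("ragged rows (wrong field count) at data row(s): ",
             paste(head(ragged, 5L), collapse = ", "))
    lineage <- vapply(body, `[[`, character(1L), 1L)
    values <- matrix(NA_real_, length(body), ncols - 1L)
    for (j in seq_len(ncols - 1L)) {
        col <- vapply(body, `[[`, character(1L), j + 1L)
        num <- suppressWarnings(as.numeric(col))
        bad <- which(is.na(num) & !(col %in% c("NA", "")))
        if (length(bad))
            stop(sprintf("malformed numeric cell at data row %d, column %s",
                         bad[[1L]], header[[j + 1L]]))
        values[, j] <- num
    }
    if (anyNA(values))
        stop("missing values are not allowed in profile tables")
    if (any(values < 0))
        stop("negative abundances are not allowed")
    delim <- .detectDelim(lineage)
    depths <- vapply(.splitLineage(lineage, delim), .lineageRankIndex,
                     integer(1L))
    rank <- if (length(unique(depths)) == 1L) .RANKS[[depths[[1L]]]]
            else "mixed"
    AbundanceTable(values, lineage, header[-1L], rank = rank)
}

#' Write a community-profile table
#'
#' Tab-delimited writer matching [readProfileTable()] (round-trip safe).
#'
#' @param table an [AbundanceTable-class].
#' @param path output path.
#' @param lineageHeader name of the first (lineage) column.
#' @return the path, invisibly.
#' @export
writeProfileTable <- function(table, path, lineageHeader = "Lineage") {
    stopifnot(is(table, "AbundanceTable"))
    rows <- vapply(seq_along(table@lineages), function(i)
        paste(c(table@lineages[[i]],
                sprintf("%.12g", table@values[i, ])), collapse = "\t"),
        character(1L))
    writeLines(c(paste(c(lineageHeader, table@sampleIds), collapse = "\t"),
                 rows), path)
    invisible(path)
}

# TRUE when some lineage is a proper prefix of another (a nested dialect
# where the file carries rows for every rank, each rank summing to 1)
.hasPrefixPairs <- function(lineages, delim) {
    pref <- paste0(lineages, delim)
    any(vapply(pref, function(p) any(startsWith(lineages, p)), logical(1L)))
}

# nested dialect: ancestor rows exist AND the shallowest rank carries the
# full per-sample mass (each rank repeats the total, as in HMP profiles);
# otherwise rows are leaves and ancestor-looking rows are unclassified tails
.isNested <- function(values, lineages, depths, delim) {
    if (!.hasPrefixPairs(lineages, delim)) return(FALSE)
    ds <- sort(unique(depths))
    mass <- vapply(ds, function(d)
        colSums(values[depths == d, , drop = FALSE]), numeric(ncol(values)))
    mass <- matrix(mass, ncol = length(ds))
    all(mass[, 1L] + 1e-6 >= apply(mass, 1L, max))
}

# drop components below rank r (1 = kingdom .. 7 = species); components
# without a rank prefix are ranked by position
.truncateToRank <- function(parts, r, delim) {
    cr <- vapply(seq_along(parts), function(i) {
        k <- .componentRank(parts[[i]])
        if (is.na(k)) i else k
    }, integer(1L))
    paste(parts[cr <= r], collapse = delim)
}

#' Collapse a profile table to one taxonomic rank
#'
#' For a leaf-dialect table (no lineage is a prefix of another), rows at or
#' below the requested rank are truncated to their rank-level prefix and
#' summed; rows ending above the rank are aggregated into an explicit
#' \code{"unclassified"} bucket. For a nested dialect (rows at every rank,
#' as in HMP community profiles), the rows sitting exactly at the rank are
#' selected and any per-sample mass not covered by them becomes the
#' \code{"unclassified"} bucket. Columns are renormalized to sum 1.
#'
#' @param table an [AbundanceTable-class].
#' @param rank one of \code{"kingdom"}, \code{"phylum"}, \code{"class"},
#'   \code{"order"}, \code{"family"}, \code{"genus"}, \code{"species"}.
#' @param dropUnclassified drop the unclassified bucket (then renormalize)
#'   instead of keeping it as a row.
#' @return an [AbundanceTable-class] at the requested rank.
#' @examples
#' tab <- AbundanceTable(matrix(c(0.3, 0.2, 0.5), 3, 1),
#'     c("k__B|g__X|s__x1", "k__B|g__X|s__x2", "k__B|g__Y|s__y1"), "s1")
#' abundanceValues(collapseToRank(tab, "genus"))
#' @export
collapseToRank <- function(table, rank = "genus",
                           dropUnclassified = FALSE) {
    stopifnot(is(table, "AbundanceTable"))
    rank <- match.arg(rank, .RANKS)
    r <- match(rank, .RANKS)
    delim <- .detectDelim(table@lineages)
    parts <- .splitLineage(table@lineages, delim)
    depths <- vapply(parts, .lineageRankIndex, integer(1L))
    if (!any(depths >= r))
        stop("rank '", rank, "' absent from all lineages")
    nested <- .isNested(table@values, table@lineages, depths, delim)
    if (nested) {
        sel <- which(depths == r)
        vals <- table@values[sel, , drop = FALSE]
        lin <- table@lineages[sel]
        # total per-sample mass: the shallowest represented rank carries it
        topDepth <- min(depths)
        total <- colSums(table@values[depths == topDepth, , drop = FALSE])
        uncls <- pmax(total - colSums(vals), 0)
    } else {
        atOrBelow <- which(depths >= r)
        key <- vapply(parts[atOrBelow], .truncateToRank, character(1L),
                      r = r, delim = delim)
        vals <- rowsum(table@values[atOrBelow, , drop = FALSE], key,
                       reorder = FALSE)
        lin <- rownames(vals)
        above <- which(depths < r)
        uncls <- if (length(above))
            colSums(table@values[above, , drop = FALSE])
        else rep(0, ncol(table@values))
    }
    if (!dropUnclassified && any(uncls > 1e-9)) {
        vals <- rbind(vals, uncls)
        lin <- c(lin, "unclassified")
    }
    cs <- colSums(vals)
    if (any(cs <= 0))
        stop("sample(s) with zero abundance after collapsing: ",
             paste(head(table@sampleIds[cs <= 0], 5L), collapse = ", "))
    vals <- sweep(vals, 2L, cs, "/")
    AbundanceTable(unname(vals), lin, table@sampleIds, rank = rank)
}

#' Remove replicate samples from the same subject
#'
#' Keeps at most one sample per subject (the first in the table's stable
#' column order) and reports how many were removed via a message and the
#' \code{"removedSamples"} attribute.
#'
#' @param table an [AbundanceTable-class].
#' @param sampleToSubject named character vector mapping every sample id
#'   to a subject id.
#' @return the deduplicated [AbundanceTable-class].
#' @export
deduplicateSubjects <- function(table, sampleToSubject) {
    stopifnot(is(table, "AbundanceTable"))
    unmapped <- setdiff(table@sampleIds, names(sampleToSubject))
    if (length(unmapped))
        stop("unmapped sample id(s): ", paste(head(unmapped, 5L),
                                              collapse = ", "))
    subj <- sampleToSubject[table@sampleIds]
    keep <- !duplicated(subj)
    removed <- sum(!keep)
    out <- AbundanceTable(table@values[, keep, drop = FALSE],
                          table@lineages, table@sampleIds[keep],
                          rank = table@rank)
    message(removed, " replicate sample(s) removed (",
            sum(keep), " retained)")
    attr(out, "removedSamples") <- removed
    out
}

#' Per-body-site diversity summary
#'
#' Computes the mean and dispersion of within-sample (alpha) scaled
#' Shannon diversity, the gamma diversity of the pooled samples, and the
#' mean and sd of pairwise Bray-Curtis dissimilarities (beta), for one set
#' of samples from one body site. With a single sample, beta is reported
#' as \code{NA} (undefined).
#'
#' @param table an [AbundanceTable-class], typically genus-collapsed.
#' @param site label for the output row.
#' @param samples optional character vector of sample ids to use (default:
#'   all columns).
#' @param richnessMode passed to the diversity functions.
#' @param dispersion \code{"sd"} (default) or \code{"se"} for the alpha
#'   dispersion column.
#' @return one-row data.frame with columns \code{site}, \code{alpha_mean},
#'   \code{alpha_sd}, \code{gamma}, \code{beta_mean}, \code{beta_sd},
#'   \code{n_samples}.
#' @export
siteDiversitySummary <- function(table, site = "all", samples = NULL,
                                 richnessMode = c("observed", "global"),
                                 dispersion = c("sd", "se")) {
    stopifnot(is(table, "AbundanceTable"))
    richnessMode <- match.arg(richnessMode)
    dispersion <- match.arg(dispersion)
    if (!is.null(samples)) {
        missing <- setdiff(samples, table@sampleIds)
        if (length(missing))
            stop("unknown sample id(s): ", paste(head(missing, 5L),
                                                 collapse = ", "))
        idx <- match(samples, table@sampleIds)
    } else idx <- seq_along(table@sampleIds)
    if (!length(idx)) stop("no samples for site '", site, "'")
    mat <- t(table@values[, idx, drop = FALSE])
    globalR <- if (richnessMode == "global") ncol(mat) else NULL
    a <- alphaDiversity(mat, richnessMode = richnessMode,
                        globalRichness = globalR, dispersion = dispersion)
    g <- gammaDiversity(mat, richnessMode = richnessMode,
                        globalRichness = globalR)
    if (nrow(mat) > 1L) {
        pairs <- .brayPairs(.normalizeRows(mat))
        bMean <- mean(pairs)
        bSd <- if (length(pairs) > 1L) sd(pairs) else 0
    } else {
        bMean <- NA_real_
        bSd <- NA_real_
    }
    data.frame(site = site, alpha_mean = unname(a[[1L]]),
               alpha_sd = unname(a[[2L]]), gamma = g,
               beta_mean = bMean, beta_sd = bSd,
               n_samples = nrow(mat), stringsAsFactors = FALSE)
}

#' Diversity summaries for every body site
#'
#' Applies [siteDiversitySummary()] to each site of a sample-to-site
#' mapping and stacks the rows.
#'
#' @param table an [AbundanceTable-class] (genus-collapsed for the
#'   canonical analysis).
#' @param sampleToSite named character vector mapping sample ids to site
#'   labels; samples absent from the table are ignored.
#' @inheritParams siteDiversitySummary
#' @return data.frame with one row per site.
#' @export
bodySiteSummaries <- function(table, sampleToSite,
                              richnessMode = c("observed", "global"),
                              dispersion = c("sd", "se")) {
    richnessMode <- match.arg(richnessMode)
    dispersion <- match.arg(dispersion)
    sampleToSite <- sampleToSite[names(sampleToSite) %in% table@sampleIds]
    sites <- unique(unname(sampleToSite))
    do.call(rbind, lapply(sites, function(s)
        siteDiversitySummary(table, site = s,
            samples = names(sampleToSite)[sampleToSite == s],
            richnessMode = richnessMode, dispersion = dispersion)))
}

#' Generate a synthetic HMP-dialect community profile
#'
#' Builds a multi-site, multi-rank relative-abundance table in the dialect
#' read by [readProfileTable()], emulating the structure of genus-level
#' human-microbiome community profiles: each site carries its own set of
#' genera (under site-specific higher ranks), and each sample's genus
#' composition is drawn from a Dirichlet distribution, so between-sample
#' variation has Dirichlet-multinomial structure. Ancestor rows (kingdom
#' through family) are included so every rank's rows sum to 1 per sample,
#' as in the nested HMP dialect.
#'
#' @param numSites number of body sites.
#' @param generaPerSite genera per site.
#' @param samplesPerSite samples per site.
#' @param concentration Dirichlet concentration: a scalar (symmetric) or a
#'   length-\code{generaPerSite} vector. The default 0.1 produces the
#'   skewed, high-beta compositions typical of genus-level human
#'   microbiome data.
#' @param replicatesPerSubject samples per subject (values > 1 create the
#'   replicate structure that [deduplicateSubjects()] removes).
#' @param seed optional integer seed; when given, output is deterministic
#'   and the caller's RNG state is restored afterwards.
#' @return list with elements \code{table} (an [AbundanceTable-class]),
#'   \code{sampleToSubject} and \code{sampleToSite} (named character
#'   vectors).
#' @examples
#' fx <- generateSyntheticProfile(numSites = 2, generaPerSite = 5,
#'     samplesPerSite = 4, seed = 1)
#' tableRank(fx$table)
#' @export
generateSyntheticProfile <- function(numSites = 6L, generaPerSite = 50L,
        samplesPerSite = 60L, concentration = 0.1,
        replicatesPerSubject = 1L, seed = NULL) {
    stopifnot(numSites >= 1L, generaPerSite >= 1L, samplesPerSite >= 1L,
              replicatesPerSubject >= 1L, all(concentration > 0))
    if (!is.null(seed)) {
        if (!exists(".Random.seed", envir = globalenv()))
            set.seed(NULL)
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
        set.seed(seed)
    }
    conc <- if (length(concentration) == 1L)
        rep(concentration, generaPerSite) else concentration
    stopifnot(length(conc) == generaPerSite)
    siteNames <- sprintf("site%02d", seq_len(numSites))
    allLineages <- character(0)
    blocks <- list()
    sampleIds <- character(0)
    sampleToSite <- character(0)
    sampleToSubject <- character(0)
    for (s in seq_len(numSites)) {
        stem <- sprintf("k__Bacteria|p__P%02d|c__C%02d|o__O%02d|f__F%02d",
                        s, s, s, s)
        genera <- sprintf("%s|g__G%02d_%03d", stem, s,
                          seq_len(generaPerSite))
        ids <- sprintf("%s_smp%03d", siteNames[[s]],
                       seq_len(samplesPerSite))
        # Dirichlet compositions: normalized gamma draws per sample
        gmat <- matrix(rgamma(generaPerSite * samplesPerSite, shape = conc),
                       nrow = generaPerSite)
        zero <- colSums(gmat) <= 0
        if (any(zero)) gmat[1L, zero] <- 1
        comp <- sweep(gmat, 2L, colSums(gmat), "/")
        blocks[[s]] <- list(genera = genera, stem = stem, comp = comp,
                            ids = ids)
        allLineages <- c(allLineages, genera)
        sampleIds <- c(sampleIds, ids)
        sampleToSite <- c(sampleToSite,
                          stats::setNames(rep(siteNames[[s]],
                                              samplesPerSite), ids))
        subj <- sprintf("%s_subj%03d", siteNames[[s]],
                        ceiling(seq_len(samplesPerSite) /
                                    replicatesPerSubject))
        sampleToSubject <- c(sampleToSubject, stats::setNames(subj, ids))
    }
    nGenus <- length(allLineages)
    genusVals <- matrix(0, nGenus, length(sampleIds))
    colOff <- 0L
    rowOff <- 0L
    for (s in seq_len(numSites)) {
        b <- blocks[[s]]
        genusVals[rowOff + seq_len(generaPerSite),
                  colOff + seq_len(samplesPerSite)] <- b$comp
        colOff <- colOff + samplesPerSite
        rowOff <- rowOff + generaPerSite
    }
    # ancestor rows: kingdom..family, each rank summing to 1 per sample
    ancLineages <- character(0)
    ancVals <- NULL
    for (depth in 1:5) {
        key <- vapply(.splitLineage(allLineages, "|"), function(p)
            paste(p[seq_len(depth)], collapse = "|"), character(1L))
        agg <- rowsum(genusVals, key, reorder = FALSE)
        ancLineages <- c(ancLineages, rownames(agg))
        ancVals <- rbind(ancVals, agg)
    }
    tab <- AbundanceTable(unname(rbind(ancVals, genusVals)),
                          c(ancLineages, allLineages), sampleIds,
                          rank = "mixed")
    list(table = tab, sampleToSubject = sampleToSubject,
         sampleToSite = sampleToSite)
}
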