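fixture <- generateSyntheticProfile(numSites = 3, generaPerSite = 8,
                                    samplesPerSite = 6,
                                    replicatesPerSubject = 2, seed = 42)

test_that("profile tables round-trip through read and write", {
    p <- withr::local_tempfile(fileext = ".tsv")
    writeProfileTable(fixture$table, p)
    t1 <- readProfileTable(p)
    expect_identical(lineages(t1), lineages(fixture$table))
    expect_identical(sampleIds(t1), sampleIds(fixture$table))
    expect_equal(abundanceValues(t1), abundanceValues(fixture$table),
                 tolerance = 1e-10)
    # write -> read -> write -> read is exact
    p2 <- withr::local_tempfile(fileext = ".tsv")
    writeProfileTable(t1, p2)
    expect_identical(abundanceValues(readProfileTable(p2)),
                     abundanceValues(t1))
})

test_that("reader detects ranks and rejects malformed tables", {
    p <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("Lineage\ts1\ts2",
                 "k__B|p__F|c__C|o__O|f__L|g__Lacto\t0.6\t0.2",
                 "k__B|p__F|c__C|o__O|f__L|g__Strep\t0.4\t0.8"), p)
    tab <- readProfileTable(p)
    expect_identical(tableRank(tab), "genus")
    # semicolon dialect parses too
    writeLines(c("Lineage\ts1", "k__B;p__F;g__X\t1.0"), p)
    expect_identical(tableRank(readProfileTable(p)), "genus")
    # malformed numeric cell is located
    writeLines(c("Lineage\ts1\ts2", "k__B\t0.5\toops"), p)
    expect_error(readProfileTable(p), "row 1, column s2")
    # ragged row
    writeLines(c("Lineage\ts1\ts2", "k__B\t0.5"), p)
    expect_error(readProfileTable(p), "ragged")
    # numeric header means the header is missing
    writeLines(c("k__B\t0.5\t0.5", "k__C\t0.5\t0.5"), p)
    expect_error(readProfileTable(p), "missing header")
    # negative values rejected
    writeLines(c("Lineage\ts1", "k__B\t-0.1"), p)
    expect_error(readProfileTable(p), "negative")
})

test_that("synthetic profiles satisfy the nested-dialect contract", {
    vals <- abundanceValues(fixture$table)
    delim <- "|"
    depths <- vapply(strsplit(lineages(fixture$table), delim, fixed = TRUE),
                     length, integer(1L))
    # every rank level sums to 1 in every sample
    for (d in sort(unique(depths))) {
        expect_equal(unname(colSums(vals[depths == d, , drop = FALSE])),
                     rep(1, ncol(vals)), tolerance = 1e-9)
    }
    # deterministic under seed, and the caller's RNG state is untouched
    set.seed(1); before <- runif(1)
    fx2 <- generateSyntheticProfile(numSites = 3, generaPerSite = 8,
                                    samplesPerSite = 6,
                                    replicatesPerSubject = 2, seed = 42)
    set.seed(1); after <- runif(1)
    expect_identical(abundanceValues(fx2$table),
                     abundanceValues(fixture$table))
    expect_identical(before, after)
})

test_that("rank collapse sums descendants and renormalizes", {
    # leaf dialect: two species of one genus at 0.3 and 0.2 make 0.5
    tab <- AbundanceTable(matrix(c(0.3, 0.2, 0.5), 3, 1),
                          c("k__B|g__X|s__x1", "k__B|g__X|s__x2",
                            "k__B|g__Y|s__y1"), "s1")
    gen <- collapseToRank(tab, "genus")
    expect_identical(tableRank(gen), "genus")
    v <- abundanceValues(gen)
    expect_equal(unname(v[match("k__B|g__X", lineages(gen)), 1]), 0.5)
    expect_equal(sum(v), 1)
    # collapsing to kingdom with one kingdom: single row of 1s
    kg <- collapseToRank(tab, "kingdom")
    expect_equal(unname(abundanceValues(kg)), matrix(1, 1, 1))
    # a table already at genus rank is unchanged up to ordering
    g2 <- collapseToRank(gen, "genus")
    ord <- match(lineages(gen), lineages(g2))
    expect_equal(abundanceValues(g2)[ord, , drop = FALSE],
                 abundanceValues(gen), ignore_attr = TRUE)
    # requesting an absent rank errors
    expect_error(collapseToRank(kg, "species"), "absent")
})

test_that("rank collapse conserves per-sample mass on the nested fixture", {
    gen <- collapseToRank(fixture$table, "genus")
    vals <- abundanceValues(fixture$table)
    depths <- vapply(strsplit(lineages(fixture$table), "|", fixed = TRUE),
                     length, integer(1L))
    # genus rows of the fixture sum to 1, so collapse is mass-preserving
    direct <- vals[depths == 6L, , drop = FALSE]
    expect_equal(unname(colSums(abundanceValues(gen))),
                 rep(1, ncol(vals)))
    expect_equal(nrow(abundanceValues(gen)), nrow(direct))
    # family-level collapse groups each site's genera into one family
    fam <- collapseToRank(fixture$table, "family")
    expect_equal(nrow(abundanceValues(fam)), 3L)
    # leaf-dialect rows above the rank fall into the unclassified bucket
    mixed <- AbundanceTable(matrix(c(0.7, 0.3), 2, 1),
                            c("k__B|g__X", "k__B"), "s1")
    gcol <- collapseToRank(mixed, "genus")
    expect_true("unclassified" %in% lineages(gcol))
    expect_equal(unname(abundanceValues(gcol)[
        lineages(gcol) == "unclassified", 1]), 0.3)
    gdrop <- collapseToRank(mixed, "genus", dropUnclassified = TRUE)
    expect_false("unclassified" %in% lineages(gdrop))
    expect_equal(sum(abundanceValues(gdrop)), 1)
})

test_that("subject deduplication keeps one stable sample per subject", {
    tab <- fixture$table
    # no duplicates: identity
    ident <- setNames(sampleIds(tab), sampleIds(tab))
    expect_message(t0 <- deduplicateSubjects(tab, ident), "0 replicate")
    expect_identical(sampleIds(t0), sampleIds(tab))
    # fixture has 2 replicates per subject: half the columns survive
    expect_message(t1 <- deduplicateSubjects(tab, fixture$sampleToSubject),
                   "9 replicate")
    expect_identical(ncol(abundanceValues(t1)),
                     ncol(abundanceValues(tab)) %/% 2L)
    # first sample of each subject is the one retained
    expect_true(all(grepl("smp00[135]$", sampleIds(t1))))
    expect_error(deduplicateSubjects(tab, fixture$sampleToSubject[-1]),
                 "unmapped")
})

test_that("site summaries match direct diversity computation", {
    gen <- collapseToRank(fixture$table, "genus")
    ids <- names(fixture$sampleToSite)[fixture$sampleToSite == "site01"]
    summ <- siteDiversitySummary(gen, site = "site01", samples = ids)
    mat <- t(abundanceValues(gen)[, match(ids, sampleIds(gen)),
                                  drop = FALSE])
    expect_equal(summ$alpha_mean, alphaDiversity(mat)[["mean"]])
    expect_equal(summ$gamma, gammaDiversity(mat))
    expect_equal(summ$beta_mean, betaDiversity(mat))
    expect_equal(summ$beta_mean, bruteBeta(mat))
    expect_identical(summ$n_samples, length(ids))
    # all identical samples: beta 0, alpha sd 0
    same <- AbundanceTable(matrix(rep(c(0.7, 0.3), 3), 2, 3),
                           c("k__B|g__X", "k__B|g__Y"),
                           c("a", "b", "c"), rank = "genus")
    s2 <- siteDiversitySummary(same, "flat")
    expect_equal(s2$beta_mean, 0)
    expect_equal(s2$alpha_sd, 0)
    # single sample: beta undefined
    s3 <- siteDiversitySummary(same, "one", samples = "a")
    expect_true(is.na(s3$beta_mean))
    # bodySiteSummaries stacks one row per site
    all6 <- bodySiteSummaries(gen, fixture$sampleToSite)
    expect_identical(nrow(all6), 3L)
    expect_identical(names(all6),
                     c("site", "alpha_mean", "alpha_sd", "gamma",
                       "beta_mean", "beta_sd", "n_samples"))
})

test_that("extreme generator regimes give the analytic limits", {
    # concentration -> infinity proxy: all samples identical, beta ~ 0
    fxBig <- generateSyntheticProfile(numSites = 1, generaPerSite = 10,
                                      samplesPerSite = 8,
                                      concentration = 1e6, seed = 7)
    gen <- collapseToRank(fxBig$table, "genus")
    expect_lt(siteDiversitySummary(gen, "x")$beta_mean, 0.02)
    # one genus per site: alpha = 0 for every sample
    fxOne <- generateSyntheticProfile(numSites = 2, generaPerSite = 1,
                                      samplesPerSite = 4, seed = 8)
    gOne <- collapseToRank(fxOne$table, "genus")
    a <- siteDiversitySummary(gOne, "y",
        samples = names(fxOne$sampleToSite)[fxOne$sampleToSite == "site01"])
    expect_equal(a$alpha_mean, 0)
})
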