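test_that("AsvExperiment validates counts, ids and metadata", {
    ae <- makeTinyExperiment()
    expect_s4_class(ae, "AsvExperiment")
    expect_identical(unname(sampleTotals(ae)), c(20, 40))

    bad <- tinyCounts(); bad[2, 1] <- -1L
    expect_error(AsvExperiment(bad, tinyTaxonomy(), tinyMeta()),
                 "ASV2.*s1")
    expect_error(AsvExperiment(tinyCounts(), tinyTaxonomy()[1:2, ],
                               tinyMeta()), "missing taxonomy")
    tax <- tinyTaxonomy(); tax$asv_id[2] <- "ASV1"
    expect_error(AsvExperiment(tinyCounts(), tax, tinyMeta()), "duplicate")
    meta <- tinyMeta(); meta$date[2] <- "12/01/2015"
    expect_error(AsvExperiment(tinyCounts(), tinyTaxonomy(), meta),
                 "unparseable date.*s2")
})

test_that("duplicate dates within a fraction are flagged, not fatal", {
    meta <- tinyMeta(dates = c("2015-01-05", "2015-01-05"))
    expect_warning(AsvExperiment(tinyCounts(), tinyTaxonomy(), meta),
                   "duplicate sampling date")
})

test_that("dense and sparse dialects round-trip to the same object", {
    ae <- makeTinyExperiment()
    d <- withr::local_tempdir()
    paths <- function(stem) file.path(d, paste0(stem, c(".tsv", "_tax.tsv",
                                                        "_meta.csv")))
    pd <- paths("dense"); ps <- paths("sparse")
    writeAsvTable(ae, pd[1], pd[2], pd[3])
    writeAsvTable(ae, ps[1], ps[2], ps[3], sparse = TRUE)
    dense <- readAsvTable(pd[1], pd[2], pd[3])
    sp <- readAsvTable(ps[1], ps[2], ps[3])
    expect_identical(counts(dense), counts(ae))
    expect_identical(counts(sp)[rownames(ae), colnames(ae)], counts(ae))
    expect_identical(taxonomy(dense), taxonomy(ae))
    expect_equal(sampleDates(dense), sampleDates(ae))

    writeLines(c("asv_id\tsample_id\tcount", "A\ts1\t-3"),
               file.path(d, "neg.tsv"))
    expect_error(readAsvTable(file.path(d, "neg.tsv"), pd[2], pd[3]),
                 "A.*s1")
    expect_error(readAsvTable(file.path(d, "nope.tsv"), pd[2], pd[3]),
                 "not found")
})

test_that("extra taxonomy/metadata rows are dropped with a warning", {
    tax <- rbind(tinyTaxonomy(), tinyTaxonomy("ASV9", TRUE))
    expect_warning(ae <- AsvExperiment(tinyCounts(), tax, tinyMeta()),
                   "without counts")
    expect_identical(nrow(ae), 3L)
})

test_that("the read-depth filter is inclusive at the threshold", {
    m <- matrix(c(999L, 1000L, 5000L), nrow = 1,
                dimnames = list("ASV1", c("a", "b", "c")))
    ae <- makeExperiment(m)
    kept <- suppressMessages(filterSamples(ae, sampleFilterPolicy(1000)))
    expect_identical(colnames(kept), c("b", "c"))
    expect_identical(attr(kept, "removed"), "a")

    ident <- filterSamples(ae, sampleFilterPolicy(0))
    expect_identical(colnames(ident), colnames(ae))
    # idempotence
    again <- suppressMessages(filterSamples(kept, sampleFilterPolicy(1000)))
    expect_identical(counts(again), counts(kept))
    expect_error(filterSamples(ae, sampleFilterPolicy(10000)),
                 "all samples")
})

test_that("a low-depth synthetic sample disappears downstream", {
    sim <- simulateAsvExperiment(simConfig(seed = 7, years = 1))
    ae <- sim$experiment
    m <- counts(ae)
    victim <- colnames(m)[1]
    scaled <- as.integer(round(m[, 1] * 500 / sum(m[, 1])))
    m[, 1] <- scaled   # forced to ~500 reads, below the 1000 filter
    ae2 <- AsvExperiment(m, taxonomy(ae),
                         data.frame(sample_id = colnames(m),
                                    date = sampleDates(ae),
                                    size_fraction = sizeFraction(ae),
                                    station = "synthetic"))
    kept <- suppressMessages(filterSamples(ae2))
    expect_false(victim %in% colnames(kept))
    expect_false(victim %in% detectBlooms(kept)$sample_id)
})

test_that("size-fraction subsets partition the sample set", {
    sim <- cachedSim()
    ae <- sim$experiment
    g <- subsetFraction(ae, "gt3um")
    s <- subsetFraction(ae, "0.2-3um")
    expect_identical(ncol(g) + ncol(s), ncol(ae))
    expect_setequal(c(colnames(g), colnames(s)), colnames(ae))
    expect_identical(rownames(g), rownames(ae))  # all-zero rows retained
    expect_error(subsetFraction(ae, "10um"), "gt3um")
    only <- makeTinyExperiment()
    expect_error(subsetFraction(only, "0.2-3um"), "no samples")
})
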