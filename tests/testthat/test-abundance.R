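test_that("relative abundance divides by the declared group", {
    m <- matrix(c(5L, 15L), nrow = 2, dimnames = list(c("A", "B"), "s1"))
    ae <- makeExperiment(m)
    expect_equal(relativeAbundance(ae, "A")["A", "s1"], 0.25)
    # group = taxon itself
    expect_equal(unname(relativeAbundance(ae, "A", "A")[1, 1]), 1)
    # taxa must be nested in the group
    expect_error(relativeAbundance(ae, "Total", "A"), "nested")
})

test_that("per-sample RA over all ASVs vs Total sums to one", {
    set.seed(11)
    m <- matrix(rpois(200, 20), 20,
                dimnames = list(sprintf("A%02d", 1:20), sprintf("s%d", 1:10)))
    ae <- makeExperiment(m)
    ra <- relativeAbundance(ae, rownames(ae), "Total")
    expect_equal(unname(colSums(ra)), rep(1, 10), tolerance = 1e-12)
})

test_that("zero-group samples are undefined, never zero", {
    m <- matrix(c(0L, 10L, 5L, 20L), nrow = 2,
                dimnames = list(c("F1", "N1"), c("s1", "s2")))
    ae <- makeExperiment(m, fungal = c(TRUE, FALSE))
    ra <- relativeAbundance(ae, "F1", "Fungi")
    expect_true(is.na(ra["F1", "s1"]))
    expect_equal(ra["F1", "s2"], 1)
})

test_that("CRA reproduces forced arithmetic and its ratio-of-means form", {
    # s1: i = 10 of G = 20, total 100; s2: i = 10 of G = 50, total 200
    m <- matrix(c(10L, 10L, 80L, 10L, 40L, 150L), nrow = 3,
                dimnames = list(c("i", "g2", "bg"), c("s1", "s2")))
    ae <- makeExperiment(m, fungal = c(TRUE, TRUE, FALSE))
    rec <- cumulativeRelativeAbundance(ae, "i", "Fungi")
    expect_equal(rec$cra, 1 / 3, tolerance = 1e-12)
    expect_identical(rec$n_samples, 2L)
    # taxon = group
    expect_equal(cumulativeRelativeAbundance(ae, "Fungi", "Fungi")$cra, 1)
    expect_error(craTable(ae, "i", group = "Chytridiomycota"),
                 "cannot resolve|absent")
})

test_that("fungal CRA records within Fungi form a partition summing to 1", {
    sim <- cachedSim()
    ae <- sim$experiment
    cra <- craTable(ae, group = "Fungi")
    expect_equal(sum(cra$cra), 1, tolerance = 1e-12)
})

test_that("RA and CRA are invariant under per-sample count rescaling", {
    set.seed(4)
    m <- matrix(rpois(60, 15) + 1L, 6,
                dimnames = list(sprintf("A%d", 1:6), sprintf("s%d", 1:10)))
    ae1 <- makeExperiment(m, fungal = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
    m2 <- sweep(m, 2, sample(1:5, 10, TRUE), "*")
    storage.mode(m2) <- "integer"
    ae2 <- makeExperiment(m2, fungal = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
    # values identical; the stored denominators of course scale
    expect_equal(relativeAbundance(ae1, "Fungi")[, ],
                 relativeAbundance(ae2, "Fungi")[, ], tolerance = 1e-12)
    expect_equal(craTable(ae1, group = "Fungi")$cra,
                 craTable(ae2, group = "Fungi")$cra, tolerance = 1e-12)
})

test_that("major-taxon selection returns the minimal covering prefix", {
    rec <- data.frame(taxon_id = c("a", "b", "c", "d"), group = "Fungi",
                      cra = c(0.5, 0.3, 0.15, 0.05), n_samples = 10L)
    mj <- selectMajorTaxa(rec, 0.9)
    expect_identical(mj$taxon_id, c("a", "b", "c"))
    expect_equal(mj$coverage[3], 0.95)
    expect_identical(nrow(selectMajorTaxa(rec, 1.0)), 4L)
    expect_error(selectMajorTaxa(rec[1:2, ], 0.9), "0.8")
})

test_that("major sets are minimal on random CRA partitions", {
    set.seed(21)
    for (rep in 1:20) {
        cras <- rexp(15); cras <- cras / sum(cras)
        rec <- data.frame(taxon_id = sprintf("t%02d", 1:15), group = "G",
                          cra = cras, n_samples = 5L)
        thr <- runif(1, 0.3, 0.99)
        mj <- selectMajorTaxa(rec, thr)
        expect_gte(sum(mj$cra), thr - 1e-12)
        if (nrow(mj) > 1)
            expect_lt(sum(mj$cra[-nrow(mj)]), thr)
    }
})

test_that("planted dominant ASVs are recovered as the major set", {
    # equal-depth samples: CRA reduces to pooled count fractions;
    # the fifth dominant taxon is needed to cross 90% coverage
    big <- c(250L, 200L, 180L, 150L, 140L)    # 92% of fungal reads
    small <- rep(16L, 5)
    m <- cbind(s1 = c(big, small), s2 = c(big, small))
    rownames(m) <- sprintf("A%02d", 1:10)
    ae <- makeExperiment(m)
    mj <- selectMajorTaxa(craTable(ae, group = "Fungi"), 0.9)
    expect_setequal(mj$taxon_id, sprintf("A%02d", 1:5))
})
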