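test_that("a pure annual sinusoid peaks within 2% of 365 days", {
    # slight sampling irregularity, as in any field calendar; perfectly even
    # spacing makes every alias of the true frequency tie in power
    set.seed(1)
    t <- sort(seq(0, 1825, length.out = 120) + runif(120, -3, 3))
    p <- lombScargle(t, sin(2 * pi * t / 365))
    expect_lt(abs(peakPeriod(p) - 365) / 365, 0.02)
    expect_lt(pValue(p), 0.01)
})

test_that("power equals the least-squares sinusoid-fit oracle everywhere", {
    set.seed(5)
    for (rep in 1:5) {
        n <- sample(20:60, 1)
        t <- sort(runif(n, 0, 300))
        t <- t + seq_along(t) * 1e-3          # enforce strict increase
        y <- rnorm(n) + 0.3 * sin(2 * pi * t / 40)
        pg <- lombScargle(t, y, min_period = 4, max_period = 150)
        freqs <- 1 / pg@periods
        oracle <- vapply(freqs, function(f) lsOraclePower(t, y, f),
                         numeric(1))
        expect_equal(pg@power, oracle, tolerance = 1e-8)
    }
})

test_that("standard normalisation is shift- and scale-invariant", {
    set.seed(9)
    t <- sort(runif(40, 0, 500))
    y <- rnorm(40)
    a <- lombScargle(t, y, max_period = 400)
    b <- lombScargle(t, 5 + 3.7 * y, max_period = 400)
    expect_equal(a@power, b@power, tolerance = 1e-10)
    expect_equal(peakPeriod(a), peakPeriod(b))
})

test_that("white noise rarely yields significant annual peaks", {
    set.seed(1234)
    n <- 60
    t <- sort(runif(n, 0, 1500)) + seq_len(n) * 1e-3
    hits <- 0L
    for (i in 1:200) {
        p <- lombScargle(t, rnorm(n))
        if (pValue(p) <= 0.01) hits <- hits + 1L
    }
    expect_gte(200L - hits, 190L)   # p > alpha in at least 95% of replicates
})

test_that("degenerate periodogram inputs are refused", {
    expect_error(lombScargle(1:3, c(1, 2, 1)), "4 points")
    expect_error(lombScargle(1:10, rep(2, 10)), "zero variance")
    expect_error(lombScargle(c(1, 2, 2, 3), c(1, 2, 3, 4)), "increasing")
})

test_that("presence windows merge short gaps and match a linear scan", {
    d <- as.Date("2015-06-01") + c(0, 7, 14, 21)
    w <- presenceWindows(d, c(0, 0.01, 0.02, 0), epsilon = 0.005)
    expect_identical(nrow(w), 1L)
    expect_identical(w$n_samples, 2L)
    expect_identical(nrow(presenceWindows(d, c(0, 0.01, 0.02, 0),
                                          epsilon = 0.5)), 0L)
    # scan oracle on random sparse series
    set.seed(12)
    for (rep in 1:10) {
        n <- 50
        dates <- as.Date("2014-01-01") + sort(sample(0:600, n))
        v <- ifelse(runif(n) < 0.2, runif(n, 0.001, 0.1), 0)
        gap <- sample(c(7, 21, 45), 1)
        w <- presenceWindows(dates, v, 0.001, gap)
        # oracle: walk the present samples, breaking on gap > merge gap
        pres <- dates[v >= 0.001]
        if (!length(pres)) { expect_identical(nrow(w), 0L); next }
        brk <- c(TRUE, diff(as.numeric(pres)) > gap)
        expect_identical(nrow(w), sum(brk))
        expect_identical(w$start, pres[brk])
        expect_identical(w$end, pres[c(brk[-1], TRUE)])
    }
})

test_that("the three archetypes are labelled from their defining patterns", {
    d0 <- as.Date("2013-05-01")
    dates <- d0 + seq(0, 1460, by = 10)
    off <- as.numeric(dates - d0)
    # annual bloom, same day-of-year +/- 10 d, 4 years
    set.seed(2)
    centers <- 250 + 365.25 * (0:3) + rnorm(4, 0, 5)
    annual <- 0.1 * rowSums(exp(-outer(off, centers, "-")^2 / (2 * 8^2)))
    expect_identical(classifyRhythm(dates, annual)$label, "rhythmic")
    # a single never-repeated window
    once <- 0.05 * exp(-(off - 500)^2 / (2 * 6^2))
    expect_identical(classifyRhythm(dates, once)$label, "ephemeral")
    # a handful of spikes at uniform random dates
    spikes <- off[c(9, 30, 55, 90, 120)]
    chaos <- 0.08 * rowSums(exp(-outer(off, spikes, "-")^2 / (2 * 3^2)))
    expect_identical(classifyRhythm(dates, chaos)$label, "chaotic")
    expect_error(classifyRhythm(dates, rep(0, length(dates))), "absent")
})

test_that("table-level classification recovers the synthetic archetypes", {
    sim <- cachedSim()
    g <- subsetFraction(suppressMessages(filterSamples(sim$experiment)),
                        "gt3um")
    cl <- classifyTable(g, sim$truth$asv_info$asv_id)
    acc <- mean(cl$label == sim$truth$asv_info$archetype)
    expect_gte(acc, 0.9)
})
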