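test_that("the calendar alternates fortnightly and winter regimes", {
    cal <- makeCalendar(simConfig(seed = 3, years = 1))
    expect_true(all(diff(as.numeric(cal)) > 0))
    mon <- as.integer(format(cal, "%m"))
    gaps <- diff(as.numeric(cal))
    winter <- mon[-length(mon)] %in% 1:3 & mon[-1] %in% 1:3
    expect_lte(median(gaps[winter]), 4)
    expect_gte(median(gaps[!winter]), 13)
})

test_that("a jitter-free calendar is exactly periodic within each regime", {
    cal <- makeCalendar(simConfig(seed = 3, years = 1, jitter_days = 0))
    mon <- as.integer(format(cal, "%m"))
    gaps <- diff(as.numeric(cal))
    # the interval is set by the regime of the left endpoint
    winter <- mon[-length(mon)] %in% 1:3
    expect_true(all(gaps[winter] %in% c(3, 4)))   # 3.5-day regime, day grid
    expect_true(all(gaps[!winter] %in% c(13, 14, 15)))  # rounding of 14
})

test_that("simulation is byte-identical under a fixed seed", {
    cfg <- simConfig(seed = 99, years = 1)
    s1 <- simulateAsvExperiment(cfg)
    s2 <- simulateAsvExperiment(cfg)
    expect_identical(counts(s1$experiment), counts(s2$experiment))
    expect_identical(s1$truth$latent_ra, s2$truth$latent_ra)
    expect_identical(makeCalendar(cfg), unique(sampleDates(s1$experiment)))
    s3 <- simulateAsvExperiment(simConfig(seed = 100, years = 1))
    expect_false(identical(counts(s1$experiment), counts(s3$experiment)))
})

test_that("counts respect multinomial conservation and latent closure", {
    sim <- simulateAsvExperiment(simConfig(seed = 5, years = 1))
    expect_identical(unname(sampleTotals(sim$experiment)),
                     as.numeric(sim$truth$sample_truth$depth))
    expect_true(all(sim$truth$sample_truth$fungal_ra < 1))
    expect_equal(unname(colSums(sim$truth$latent_ra)),
                 sim$truth$sample_truth$fungal_ra, tolerance = 1e-12)
})

test_that("observed RA tracks latent RA within binomial error at peaks", {
    cfg <- simConfig(seed = 6, years = 2, n_rhythmic = 1, n_chaotic = 0,
                     n_ephemeral = 0, rhythmic_peak_ra = c(0.3, 0.3),
                     fraction_mix = c(0.9, 0.9))
    sim <- simulateAsvExperiment(cfg)
    ae <- sim$experiment
    lat <- sim$truth$latent_ra["ASV001", ]
    peaks <- names(lat)[lat > 0.1]
    ra <- relativeAbundance(ae, "ASV001", "Total")[1, peaks]
    depth <- sampleTotals(ae)[peaks]
    se <- sqrt(lat[peaks] * (1 - lat[peaks]) / depth)
    expect_true(all(abs(ra - lat[peaks]) <= 3 * se + 1e-9))
})

test_that("with only rhythmic ASVs, blooms recover the planted samples", {
    cfg <- simConfig(seed = 31, years = 2, n_chaotic = 0, n_ephemeral = 0,
                     depth_log_sd = 0, rhythmic_peak_ra = c(0.1, 0.3))
    sim <- simulateAsvExperiment(cfg)
    ev <- detectBlooms(sim$experiment, 0.05)
    truth <- sim$truth$sample_truth
    # away from the exact threshold the sets must coincide
    clear <- abs(truth$fungal_ra - 0.05) > 0.01
    expect_setequal(ev$sample_id[ev$sample_id %in% truth$sample_id[clear]],
                    truth$sample_id[clear & truth$fungal_ra >= 0.05])
})

test_that("unreachable latent abundance is refused with advice", {
    cfg <- simConfig(seed = 1, years = 1, n_rhythmic = 0, n_chaotic = 0,
                     n_ephemeral = 1, ephemeral_ra = c(0.98, 0.98),
                     fraction_mix = c(0.999, 0.999))
    expect_error(simulateAsvExperiment(cfg), "reduce")
})

test_that("a background crash inflates fungal RA without fungal growth", {
    base <- simConfig(seed = 13, years = 1)
    crash <- simConfig(seed = 13, years = 1, background_crash =
                           list(start = "2013-07-01", end = "2013-08-15",
                                factor = 0.05))
    s1 <- simulateAsvExperiment(base)
    s2 <- simulateAsvExperiment(crash)
    win <- s1$truth$sample_truth$date >= as.Date("2013-07-01") &
           s1$truth$sample_truth$date <= as.Date("2013-08-15")
    # outside the window nothing changes; inside, the realised fungal RA
    # rises although the fungal signal itself is unchanged
    expect_identical(s1$truth$latent_ra[, !win], s2$truth$latent_ra[, !win])
    expect_true(all(s2$truth$sample_truth$fungal_ra[win] >=
                        s1$truth$sample_truth$fungal_ra[win]))
    expect_gt(mean(s2$truth$sample_truth$fungal_ra[win]),
              mean(s1$truth$sample_truth$fungal_ra[win]))
    raw <- relativeAbundance(s2$experiment, "Fungi")[1, ]
    ra1 <- relativeAbundance(s1$experiment, "Fungi")[1, ]
    expect_gt(mean(raw[s1$truth$sample_truth$sample_id[win]], na.rm = TRUE),
              mean(ra1[s1$truth$sample_truth$sample_id[win]], na.rm = TRUE))
})
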