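# Small in-code fixtures and independent oracles shared across test files.

tinyCounts <- function() {
    matrix(c(5L, 10L, 5L, 10L, 20L, 10L), nrow = 3,
           dimnames = list(c("ASV1", "ASV2", "ASV3"), c("s1", "s2")))
}

tinyTaxonomy <- function(ids = c("ASV1", "ASV2", "ASV3"),
                         fungal = c(TRUE, TRUE, FALSE)) {
    data.frame(asv_id = ids, domain = "Eukaryota",
               supergroup = "Opisthokonta",
               division = ifelse(fungal, "Fungi", "Metazoa"),
               class = ifelse(fungal, "Ascomycota", "unassigned"),
               order = "unassigned", family = "unassigned",
               genus = "unassigned", species = "unassigned",
               is_fungal = fungal)
}

tinyMeta <- function(ids = c("s1", "s2"),
                     dates = c("2015-01-05", "2015-01-12"),
                     fraction = "gt3um") {
    data.frame(sample_id = ids, date = dates, size_fraction = fraction,
               station = "SOLA")
}

makeTinyExperiment <- function() {
    AsvExperiment(tinyCounts(), tinyTaxonomy(), tinyMeta())
}

# build an AsvExperiment from a bare counts matrix, marking `fungal` rows
makeExperiment <- function(counts, fungal = rep(TRUE, nrow(counts)),
                           dates = NULL, fraction = "gt3um") {
    if (is.null(dates))
        dates <- format(as.Date("2015-01-01") + 7 * seq_len(ncol(counts)))
    AsvExperiment(counts, tinyTaxonomy(rownames(counts), fungal),
                  tinyMeta(colnames(counts), dates,
                           rep(fraction, length.out = ncol(counts))))
}

randomExperiment <- function(n_asv = 12, n_samp = 8, fungal_frac = 0.5,
                             lambda = 30) {
    m <- matrix(rpois(n_asv * n_samp, lambda), n_asv,
                dimnames = list(sprintf("ASV%02d", seq_len(n_asv)),
                                sprintf("s%02d", seq_len(n_samp))))
    makeExperiment(m, fungal = seq_len(n_asv) <= ceiling(fungal_frac * n_asv))
}

# default-config simulation, computed once per test run
cachedSim <- local({
    cache <- new.env()
    function() {
        if (is.null(cache$sim))
            cache$sim <- simulateAsvExperiment(simConfig(seed = 42))
        cache$sim
    }
})

# independent Lomb-Scargle oracle: variance explained by the least-squares
# sinusoid fit at one frequency (QR-based lm.fit, no tau trick)
lsOraclePower <- function(times, values, freq) {
    y <- values - mean(values)
    w <- 2 * pi * freq
    X <- cbind(cos(w * times), sin(w * times))
    rss <- sum(lm.fit(X, y)$residuals^2)
    ss <- sum(y^2)
    (ss - rss) / (2 * ss / (length(y) - 1))
}

# brute-force dominance oracle: smallest subset of ASVs covering p of reads
bruteDominance <- function(counts, p) {
    n <- length(counts)
    target <- p * sum(counts) - 1e-9
    for (k in seq_len(n)) {
        combos <- combn(n, k)
        if (any(colSums(matrix(counts[combos], nrow = k)) >= target))
            return(k)
    }
    n
}
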