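#' Season of a sampling date
#'
#' Calendar-quarter seasons: winter = January-March, spring = April-June,
#' summer = July-September, autumn = October-December.
#'
#' @param dates `Date` vector.
#' @return factor with levels winter, spring, summer, autumn.
#' @export
seasonOf <- function(dates) {
    q <- (as.integer(format(dates, "%m")) - 1) %/% 3 + 1
    factor(c("winter", "spring", "summer", "autumn")[q],
           levels = c("winter", "spring", "summer", "autumn"))
}

#' Fungal alpha diversity per sample
#'
#' Shannon (natural log by default) and Gini-Simpson indices of the fungal
#' community, computed on counts normalised within Fungi (each fungal ASV's
#' reads divided by the sample's fungal reads). Only samples with at least
#' `min_fungal_reads` fungal reads qualify; the number excluded is reported
#' via `message()`. Index evaluation is delegated to
#' [vegan::diversity()].
#'
#' @param x a filtered [AsvExperiment].
#' @param min_fungal_reads minimum fungal reads per sample (default 50).
#' @param base logarithm base for Shannon (default `exp(1)`, nats).
#' @return `data.frame` with columns `sample_id`, `date`, `size_fraction`,
#'   `season`, `month`, `shannon`, `gini_simpson`, `n_fungal_reads`.
#' @examples
#' ae <- simulateAsvExperiment(simConfig(seed = 1, years = 1))$experiment
#' head(alphaDiversity(ae))
#' @export
alphaDiversity <- function(x, min_fungal_reads = 50, base = exp(1)) {
    stopifnot(is(x, "AsvExperiment"))
    fungal <- counts(x)[isFungal(x), , drop = FALSE]
    n <- colSums(fungal)
    keep <- n >= min_fungal_reads
    if (!any(keep))
        stop("no sample reaches ", min_fungal_reads, " fungal reads")
    if (any(!keep))
        message("alphaDiversity: ", sum(!keep),
                " sample(s) below ", min_fungal_reads, " fungal reads excluded")
    m <- t(fungal[, keep, drop = FALSE])
    data.frame(sample_id = colnames(x)[keep],
               date = sampleDates(x)[keep],
               size_fraction = sizeFraction(x)[keep],
               season = seasonOf(sampleDates(x)[keep]),
               month = factor(month.abb[as.integer(
                   format(sampleDates(x)[keep], "%m"))], levels = month.abb),
               shannon = as.numeric(vegan::diversity(m, "shannon",
                                                     base = base)),
               gini_simpson = as.numeric(vegan::diversity(m, "simpson")),
               n_fungal_reads = as.integer(n[keep]), row.names = NULL)
}

#' Expected rarefied richness
#'
#' Expected number of ASVs observed when subsampling `d` reads without
#' replacement from a sample: E\[S_d\] = sum_i (1 - C(N - N_i, d) / C(N, d)),
#' evaluated through [vegan::rarefy()]'s numerically stable implementation.
#'
#' @param sample_counts per-ASV read counts of one sample.
#' @param depths increasing integer depths, each at most the total reads.
#' @return named numeric vector of expected richness per depth.
#' @examples
#' rarefactionCurve(c(50, 30, 15, 5), c(1, 10, 100))
#' @export
rarefactionCurve <- function(sample_counts, depths) {
    N <- sum(sample_counts)
    if (any(depths > N))
        stop("depth exceeds total reads (", N, ")")
    stopifnot(all(depths >= 1), all(depths == round(depths)))
    # vegan warns when no singleton counts are present (a heuristic for
    # non-count data); inputs here are validated integer counts
    out <- vapply(depths, function(d)
        as.numeric(suppressWarnings(
            vegan::rarefy(sample_counts, sample = d))), numeric(1))
    setNames(out, depths)
}

#' Rank-based comparison of diversity between groups
#'
#' Tie-corrected Kruskal-Wallis test (via [stats::kruskal.test()]) followed
#' by Dunn's post hoc pairwise z tests computed from the joint rank sums
#' with the usual tie correction, two-sided, with Benjamini-Hochberg
#' adjustment across the family of pairwise comparisons.
#'
#' @param values numeric vector (e.g. a diversity index).
#' @param groups factor of the same length (month, season or fraction).
#' @return list with `H` (tie-corrected statistic), `df`, `p_value`, and
#'   `pairwise`, a `data.frame` of (`group_a`, `group_b`, `z`, `p`,
#'   `p_adj`).
#' @examples
#' rec <- data.frame(v = c(1, 2, 3, 10, 11, 12), g = rep(c("a", "b"), each = 3))
#' compareGroups(rec$v, rec$g)$p_value
#' @export
compareGroups <- function(values, groups) {
    groups <- droplevels(factor(groups))
    stopifnot(length(values) == length(groups))
    cnt <- table(groups)
    if (length(cnt) < 2) stop("need at least 2 groups")
    if (any(cnt < 2))
        stop("group(s) with fewer than 2 observations: ",
             paste(names(cnt)[cnt < 2], collapse = ", "))
    kw <- kruskal.test(values, groups)

    N <- length(values)
    r <- rank(values)
    tie <- table(r)
    tieCorr <- sum(tie^3 - tie) / (12 * (N - 1))
    meanRank <- tapply(r, groups, mean)
    lv <- levels(groups)
    pairs <- combn(lv, 2)
    z <- apply(pairs, 2, function(p) {
        se <- sqrt((N * (N + 1) / 12 - tieCorr) *
                   (1 / cnt[[p[1]]] + 1 / cnt[[p[2]]]))
        (meanRank[[p[1]]] - meanRank[[p[2]]]) / se
    })
    praw <- 2 * pnorm(-abs(z))
    pairwise <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                           z = z, p = praw,
                           p_adj = p.adjust(praw, "BH"), row.names = NULL)
    list(H = unname(kw$statistic), df = unname(kw$parameter),
         p_value = kw$p.value, pairwise = pairwise)
}
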