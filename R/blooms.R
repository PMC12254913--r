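#' Detect operational fungal blooms
#'
#' A bloom is a sample in which Fungi make up at least `threshold` of the
#' group-Total (eukaryotic) reads — inclusive, so a sample at exactly 5 % is
#' a bloom under the default. Each event carries its within-bloom dominance
#' profile (minimal number of ASVs covering each requested fraction of the
#' fungal reads). Samples whose total reads are zero have undefined fungal
#' RA and are never flagged.
#'
#' @param x a filtered [AsvExperiment].
#' @param threshold bloom threshold on RA(Fungi, Total) (default 0.05).
#' @param levels dominance coverage levels (default `c(0.5, 0.9)`).
#' @return `data.frame` of events sorted by date with columns `sample_id`,
#'   `date`, `size_fraction`, `ra_fungi` and one `m_<level>` column per
#'   coverage level; zero rows when no sample blooms.
#' @examples
#' ae <- simulateAsvExperiment(simConfig(seed = 1, years = 2))$experiment
#' head(detectBlooms(ae))
#' @export
detectBlooms <- function(x, threshold = 0.05, levels = c(0.5, 0.9)) {
    stopifnot(is(x, "AsvExperiment"), threshold >= 0, threshold <= 1)
    m <- counts(x)
    fungal <- m[isFungal(x), , drop = FALSE]
    nFungi <- colSums(fungal)
    ra <- nFungi / colSums(m)
    hit <- !is.na(ra) & ra >= threshold & nFungi >= 1
    idx <- which(hit)
    dom <- t(vapply(idx, function(j)
        dominanceProfile(fungal[, j], levels), numeric(length(levels))))
    out <- data.frame(sample_id = colnames(x)[idx],
                      date = unname(sampleDates(x)[idx]),
                      size_fraction = unname(sizeFraction(x)[idx]),
                      ra_fungi = unname(ra[idx]), row.names = NULL)
    if (length(idx)) {
        colnames(dom) <- sprintf("m_%g", levels)
        out <- cbind(out, dom)
    } else {
        for (p in levels) out[[sprintf("m_%g", p)]] <- numeric(0)
    }
    out[order(out$date, out$sample_id), , drop = FALSE]
}

#' Minimal number of ASVs covering a fraction of fungal reads
#'
#' For each coverage level p, m(p) is the smallest k such that the k most
#' abundant fungal ASVs in the sample account for at least p of the fungal
#' reads. Ranking is by raw count, ties broken by ascending ASV id; because
#' the optimal subset of any size is the top-k set, this greedy prefix is
#' the exact minimum over all ASV subsets.
#'
#' @param fungal_counts named numeric vector of per-ASV fungal reads in one
#'   sample (must contain at least one read).
#' @param levels coverage fractions in (0, 1\].
#' @return named integer vector m(p) per level, non-decreasing in p.
#' @examples
#' dominanceProfile(c(a = 60, b = 30, c = 10))  # m(0.5) = 1, m(0.9) = 2
#' @export
dominanceProfile <- function(fungal_counts, levels = c(0.5, 0.9)) {
    tot <- sum(fungal_counts)
    if (tot <= 0) stop("zero fungal reads: dominance undefined")
    stopifnot(all(levels > 0), all(levels <= 1))
    nm <- names(fungal_counts)
    if (is.null(nm)) nm <- as.character(seq_along(fungal_counts))
    ord <- order(-fungal_counts, nm)
    cum <- cumsum(fungal_counts[ord])
    vapply(setNames(levels, sprintf("%g", levels)), function(p)
        as.numeric(which(cum >= p * tot - 1e-9)[1]), numeric(1))
}

#' Fraction of each calendar month's samples that are blooms
#'
#' Pools all years: for each month, the number of bloom samples divided by
#' the number of samples collected in that month. Months with no samples are
#' `NA` (undefined, not zero).
#'
#' @param events bloom events from [detectBlooms()] on the same table.
#' @param x the [AsvExperiment] the events were derived from.
#' @return named numeric vector of length 12 (`month.abb`).
#' @export
bloomFractionByMonth <- function(events, x) {
    stopifnot(is(x, "AsvExperiment"))
    mon <- function(d) as.integer(format(d, "%m"))
    nSamp <- tabulate(mon(sampleDates(x)), 12)
    nBloom <- tabulate(mon(events$date), 12)
    frac <- ifelse(nSamp > 0, nBloom / nSamp, NA_real_)
    setNames(frac, month.abb)
}

#' Persistence of above-threshold fungal abundance
#'
#' Scans a dated fraction series for runs of consecutive sampling points all
#' strictly above `threshold`. Two successive points extend a run only when
#' they are separated by at most `max_gap_days` — points either side of a
#' long sampling gap are not "consecutive" in any meaningful sense. The
#' default gap of 8 days covers both the twice-weekly winter and the weekly
#' sampling regimes.
#'
#' @param dates strictly increasing `Date` (or numeric day) vector.
#' @param values fractions, same length as `dates`.
#' @param threshold run membership requires `value > threshold`
#'   (default 0.10).
#' @param max_gap_days maximum spacing for two points to count as
#'   consecutive (default 8).
#' @return list with `threshold`, `max_gap_days`, `max_run` (longest run
#'   length in points, 0 if none above threshold) and `runs`, a
#'   `data.frame` with `start`, `end`, `length`.
#' @examples
#' d <- as.Date("2016-01-01") + c(0, 3, 6)
#' bloomPersistence(d, c(0.2, 0.05, 0.15))$max_run  # 1: no adjacent pair
#' @export
bloomPersistence <- function(dates, values, threshold = 0.10,
                             max_gap_days = 8) {
    if (length(dates) < 1) stop("need at least one point")
    stopifnot(length(dates) == length(values))
    t <- as.numeric(dates)
    if (any(diff(t) <= 0)) stop("dates must be strictly increasing")
    above <- !is.na(values) & values > threshold
    runs <- data.frame(start = dates[0], end = dates[0], length = integer(0))
    i <- 1
    n <- length(values)
    while (i <= n) {
        if (above[i]) {
            j <- i
            while (j < n && above[j + 1] && (t[j + 1] - t[j]) <= max_gap_days)
                j <- j + 1
            runs <- rbind(runs, data.frame(start = dates[i], end = dates[j],
                                           length = as.integer(j - i + 1)))
            i <- j + 1
        } else i <- i + 1
    }
    list(threshold = threshold, max_gap_days = max_gap_days,
         max_run = if (nrow(runs)) as.integer(max(runs$length)) else 0L,
         runs = runs)
}
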