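#' Presence windows of a sparse trajectory
#'
#' Maximal runs of samples whose value reaches the presence threshold
#' `epsilon`, with runs separated by at most `merge_gap_days` merged into
#' one window. A window is one "appearance" of the ASV; an ephemeral ASV
#' has exactly one.
#'
#' @param dates increasing `Date` (or numeric day) vector.
#' @param values series values (RA among all eukaryotes).
#' @param epsilon presence threshold (default 0.001 of eukaryotic reads).
#' @param merge_gap_days gaps of at most this many days between presence
#'   runs are bridged (default 21).
#' @return `data.frame` with columns `start`, `end`, `n_samples`; zero rows
#'   when the taxon never reaches `epsilon`.
#' @examples
#' d <- as.Date("2015-06-01") + c(0, 7, 14, 21)
#' presenceWindows(d, c(0, 0.01, 0.02, 0), epsilon = 0.005)
#' @export
presenceWindows <- function(dates, values, epsilon = 0.001,
                            merge_gap_days = 21) {
    stopifnot(length(dates) == length(values))
    if (any(diff(as.numeric(dates)) <= 0))
        stop("dates must be strictly increasing")
    present <- which(!is.na(values) & values >= epsilon)
    if (!length(present))
        return(data.frame(start = dates[0], end = dates[0],
                          n_samples = integer(0)))
    d <- dates[present]
    newWindow <- c(TRUE, diff(as.numeric(d)) > merge_gap_days)
    grp <- cumsum(newWindow)
    data.frame(start = d[!duplicated(grp)],
               end = d[rev(!duplicated(rev(grp)))],
               n_samples = as.integer(table(grp)), row.names = NULL)
}

#' Decision thresholds for the rhythm classifier
#'
#' Tunable rule set used by [classifyRhythm()]. `epsilon` and
#' `merge_gap_days` parameterise the presence windows; `alpha` and
#' `annual_band` the spectral evidence (peak period in days within the
#' annual band at significance `alpha`); `recurrence_tol`, `min_years` and
#' `min_aligned_frac` the calendar-recurrence evidence (presence within
#' +/- `recurrence_tol` days of a common day-of-year in at least
#' `min_years` distinct years, with the aligned windows making up at least
#' `min_aligned_frac` of all presence windows so that a chaotic taxon whose
#' scattered spikes happen to align in a few years is not called rhythmic).
#'
#' @param alpha periodogram significance level (default 0.01).
#' @param annual_band accepted peak-period band in days
#'   (default `c(300, 430)`).
#' @param recurrence_tol day-of-year tolerance (default 45).
#' @param min_years distinct years required (default 3).
#' @param min_aligned_frac minimum fraction of windows that must align
#'   (default 0.75).
#' @param epsilon,merge_gap_days see [presenceWindows()].
#' @return named list of rules.
#' @export
rhythmRules <- function(alpha = 0.01, annual_band = c(300, 430),
                        recurrence_tol = 45, min_years = 3,
                        min_aligned_frac = 0.75,
                        epsilon = 0.001, merge_gap_days = 21) {
    list(alpha = alpha, annual_band = annual_band,
         recurrence_tol = recurrence_tol, min_years = min_years,
         min_aligned_frac = min_aligned_frac,
         epsilon = epsilon, merge_gap_days = merge_gap_days)
}

#' Classify a trajectory as rhythmic, chaotic or ephemeral
#'
#' Codifies the three dynamic archetypes of sparse plankton ASV series:
#' \describe{
#'   \item{ephemeral}{exactly one presence window — the taxon appeared once
#'     (possibly over several consecutive sampling days) and never again.}
#'   \item{rhythmic}{at least two presence windows, backed by either
#'     spectral evidence (periodogram peak inside the annual band with
#'     p-value at most `alpha`) or calendar recurrence (presence near a
#'     common day-of-year in at least `min_years` distinct years, the
#'     aligned windows making up at least `min_aligned_frac` of all
#'     windows).}
#'   \item{chaotic}{repeated appearances with neither form of regularity.}
#' }
#' The input series should be relative abundance among all eukaryotes;
#' missing sampling dates are simply absent points.
#'
#' @param dates increasing `Date` vector of sampling days.
#' @param values RA among eukaryotes at those dates.
#' @param periodogram optional precomputed [lombScargle()] result for this
#'   series; computed with defaults when `NULL` (requires >= 4 points and a
#'   non-constant series).
#' @param rules a [rhythmRules()] list.
#' @return list with `label` (one of `"rhythmic"`, `"chaotic"`,
#'   `"ephemeral"`) and `diagnostics` (windows, spectral and recurrence
#'   evidence, thresholds used).
#' @export
classifyRhythm <- function(dates, values, periodogram = NULL,
                           rules = rhythmRules()) {
    win <- presenceWindows(dates, values, rules$epsilon,
                           rules$merge_gap_days)
    if (nrow(win) == 0) stop("absent taxon: no presence windows")

    spectral <- FALSE
    pk <- NA_real_; pv <- NA_real_
    if (nrow(win) >= 2) {
        if (is.null(periodogram) && length(values) >= 4 &&
            var(values) > 0)
            periodogram <- lombScargle(
                as.numeric(dates) - as.numeric(dates)[1], values,
                alpha = rules$alpha)
        if (!is.null(periodogram)) {
            pk <- peakPeriod(periodogram)
            pv <- pValue(periodogram)
            spectral <- pv <= rules$alpha &&
                pk >= rules$annual_band[1] && pk <= rules$annual_band[2]
        }
    }

    rec <- .recurrenceEvidence(win, rules)

    label <- if (nrow(win) == 1) "ephemeral"
             else if (spectral || rec$recurrent) "rhythmic"
             else "chaotic"
    list(label = label,
         diagnostics = list(
             n_windows = nrow(win), windows = win,
             peak_period = pk, p_value = pv, spectral = spectral,
             recurrent = rec$recurrent, aligned_years = rec$years,
             aligned_fraction = rec$frac, rules = rules))
}

# Calendar-recurrence evidence: window midpoints reduced to (year,
# day-of-year); tested against each midpoint's day-of-year as the candidate
# anchor, with circular distance on the 365-day calendar.
.recurrenceEvidence <- function(win, rules) {
    mid <- win$start + floor(as.numeric(win$end - win$start) / 2)
    yr <- as.integer(format(mid, "%Y"))
    doy <- as.integer(format(mid, "%j"))
    best <- list(recurrent = FALSE, years = 0L, frac = 0)
    if (nrow(win) < rules$min_years) return(best)
    for (anchor in doy) {
        d <- abs(doy - anchor)
        d <- pmin(d, 365 - d)
        aligned <- d <= rules$recurrence_tol
        nyears <- length(unique(yr[aligned]))
        frac <- mean(aligned)
        if (nyears >= rules$min_years && frac >= rules$min_aligned_frac &&
            nyears > best$years) {
            best <- list(recurrent = TRUE, years = nyears, frac = frac)
        }
    }
    best
}

#' Classify every selected ASV of a table
#'
#' Convenience wrapper: extracts each ASV's Total-normalised trajectory
#' within one size fraction and runs [classifyRhythm()]. ASVs that never
#' reach the presence threshold are labelled `"absent"`.
#'
#' @param x an [AsvExperiment] (typically one size fraction).
#' @param asv_ids ASVs to classify (default: all fungal ASVs).
#' @param rules a [rhythmRules()] list.
#' @param min_period,max_period,oversampling,alpha periodogram settings
#'   (defaults 2 d, 900 d, 1, 0.01).
#' @return `data.frame` with `asv_id`, `label`, `n_windows`,
#'   `peak_period`, `p_value`.
#' @export
classifyTable <- function(x, asv_ids = rownames(x)[isFungal(x)],
                          rules = rhythmRules(),
                          min_period = 2, max_period = 900,
                          oversampling = 1, alpha = 0.01) {
    stopifnot(is(x, "AsvExperiment"))
    ord <- order(sampleDates(x))
    x <- x[, ord]
    dates <- sampleDates(x)
    if (anyDuplicated(dates))
        stop("duplicate dates; classify one size fraction at a time")
    ra <- relativeAbundance(x, asv_ids, "Total")
    t0 <- as.numeric(dates) - as.numeric(dates)[1]
    rows <- lapply(asv_ids, function(id) {
        v <- ra[id, ]
        ok <- !is.na(v)
        if (!any(ok) || max(v[ok]) < rules$epsilon)
            return(data.frame(asv_id = id, label = "absent",
                              n_windows = 0L, peak_period = NA_real_,
                              p_value = NA_real_))
        per <- if (sum(ok) >= 4 && var(v[ok]) > 0)
            lombScargle(t0[ok], v[ok], min_period, max_period,
                        oversampling, alpha) else NULL
        cl <- classifyRhythm(dates[ok], v[ok], per, rules)
        data.frame(asv_id = id, label = cl$label,
                   n_windows = cl$diagnostics$n_windows,
                   peak_period = cl$diagnostics$peak_period,
                   p_value = cl$diagnostics$p_value)
    })
    do.call(rbind, rows)
}
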