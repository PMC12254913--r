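#' Lomb-Scargle periodogram for an irregularly sampled series
#'
#' Classical Lomb-Scargle estimator with the phase offset tau defined by
#' tan(2 w tau) = sum(sin 2 w t) / sum(cos 2 w t), which makes the cosine
#' and sine basis orthogonal at each trial frequency. Power uses the
#' "standard" normalisation: the variance explained by the best-fitting
#' sinusoid at that frequency divided by twice the sample variance
#' (denominator n - 1), so a noise-free sinusoid approaches (n - 1) / 2.
#' The trial frequency grid spans \[1/max_period, 1/min_period\] with
#' spacing 1 / (oversampling x time span).
#'
#' The peak significance is the classical multiple-comparison estimate
#' p = 1 - (1 - exp(-P_peak))^M with M the number of grid frequencies
#' (`mEstimate = "grid"`, the default at oversampling 1) or the
#' Horne-Baliunas estimate M = -6.362 + 1.193 n + 0.00098 n^2
#' (`mEstimate = "horne"`).
#'
#' @param times numeric days since series start, strictly increasing,
#'   length >= 4.
#' @param values series values (e.g. relative abundances); must not be
#'   constant.
#' @param min_period,max_period period search range in days (defaults 2 and
#'   900).
#' @param oversampling frequency oversampling factor (default 1).
#' @param alpha significance level carried into the result (default 0.01).
#' @param mEstimate `"grid"` or `"horne"` (independent-frequency count used
#'   in the p-value).
#' @return a [PeriodogramResult-class] object.
#' @examples
#' t <- seq(0, 1825, length.out = 120)
#' p <- lombScargle(t, sin(2 * pi * t / 365))
#' peakPeriod(p)
#' @export
lombScargle <- function(times, values, min_period = 2, max_period = 900,
                        oversampling = 1, alpha = 0.01,
                        mEstimate = c("grid", "horne")) {
    mEstimate <- match.arg(mEstimate)
    n <- length(times)
    if (n < 4) stop("need at least 4 points")
    stopifnot(length(values) == n, min_period > 0, max_period > min_period)
    if (any(diff(times) <= 0)) stop("times must be strictly increasing")
    y <- values - mean(values)
    ss <- sum(y^2)
    if (ss == 0) stop("zero variance: constant series")
    sigma2 <- ss / (n - 1)

    span <- times[n] - times[1]
    df <- 1 / (oversampling * span)
    freqs <- seq(1 / max_period, 1 / min_period, by = df)
    omega <- 2 * pi * freqs

    # nfreq x n trig matrices; sizes here are modest (<= ~1e6 cells)
    wt <- outer(omega, times)
    tau <- atan2(rowSums(sin(2 * wt)), rowSums(cos(2 * wt))) / (2 * omega)
    arg <- wt - omega * tau
    C <- cos(arg)
    S <- sin(arg)
    power <- ((C %*% y)^2 / rowSums(C^2) +
              (S %*% y)^2 / rowSums(S^2))[, 1] / (2 * sigma2)

    k <- which.max(power)
    M <- if (mEstimate == "grid") length(freqs) else
        -6.362 + 1.193 * n + 0.00098 * n^2
    # 1 - (1 - exp(-P))^M, guarded for tiny tail probabilities
    pval <- -expm1(M * log1p(-min(exp(-power[k]), 1 - 1e-16)))
    pval <- min(max(pval, 0), 1)

    new("PeriodogramResult",
        periods = 1 / freqs, power = as.numeric(power),
        peakPeriod = 1 / freqs[k], peakPower = power[k], pValue = pval,
        params = list(min_period = min_period, max_period = max_period,
                      oversampling = oversampling, alpha = alpha,
                      mEstimate = mEstimate, M = M, n = n))
}

#' Periodogram of an irregularly sampled trajectory
#'
#' Holds the period grid (days), the standard-normalised power values, the
#' peak location and its multiple-comparison p-value, plus the parameters
#' used. Produced by [lombScargle()].
#'
#' @slot periods numeric period grid in days (descending).
#' @slot power non-negative power at each grid period.
#' @slot peakPeriod,peakPower location and height of the maximum.
#' @slot pValue peak significance in \[0, 1\].
#' @slot params list of the settings used.
#' @aliases peakPeriod peakPower pValue
#' @export
setClass("PeriodogramResult",
         representation(periods = "numeric", power = "numeric",
                        peakPeriod = "numeric", peakPower = "numeric",
                        pValue = "numeric", params = "list"))

setValidity("PeriodogramResult", function(object) {
    msg <- character()
    if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
    if (length(object@power) &&
        abs(object@peakPower - max(object@power)) > 1e-12)
        msg <- c(msg, "peakPower must equal max(power)")
    if (object@pValue < 0 || object@pValue > 1)
        msg <- c(msg, "pValue must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @rdname PeriodogramResult-class
#' @param x a `PeriodogramResult`.
#' @export
setGeneric("peakPeriod", function(x) standardGeneric("peakPeriod"))
#' @rdname PeriodogramResult-class
#' @export
setGeneric("peakPower", function(x) standardGeneric("peakPower"))
#' @rdname PeriodogramResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname PeriodogramResult-class
#' @export
setMethod("peakPeriod", "PeriodogramResult", function(x) x@peakPeriod)
#' @rdname PeriodogramResult-class
#' @export
setMethod("peakPower", "PeriodogramResult", function(x) x@peakPower)
#' @rdname PeriodogramResult-class
#' @export
setMethod("pValue", "PeriodogramResult", function(x) x@pValue)

setMethod("show", "PeriodogramResult", function(object) {
    cat("PeriodogramResult:", length(object@power), "frequencies,",
        "periods", sprintf("%.3g", min(object@periods)), "-",
        sprintf("%.3g", max(object@periods)), "d\n")
    cat(sprintf("  peak: period %.4g d, power %.4g, p = %.3g\n",
                object@peakPeriod, object@peakPower, object@pValue))
})
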