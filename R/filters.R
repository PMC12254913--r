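#' Sample filtering policy
#'
#' The two read-depth filters applied before analysis: samples with fewer
#' than `min_total_reads` total reads are discarded outright (default 1000,
#' inclusive — a sample with exactly 1000 reads is kept), and alpha-diversity
#' calculations additionally require `min_fungal_reads_for_diversity` fungal
#' reads (default 50).
#'
#' @param min_total_reads integer >= 0.
#' @param min_fungal_reads_for_diversity integer >= 0.
#' @return a named list of class `SampleFilterPolicy`.
#' @export
sampleFilterPolicy <- function(min_total_reads = 1000,
                               min_fungal_reads_for_diversity = 50) {
    stopifnot(min_total_reads >= 0, min_fungal_reads_for_diversity >= 0)
    structure(list(min_total_reads = as.integer(min_total_reads),
                   min_fungal_reads_for_diversity =
                       as.integer(min_fungal_reads_for_diversity)),
              class = "SampleFilterPolicy")
}

#' Discard low-depth samples
#'
#' Removes samples whose total read count is below
#' `policy$min_total_reads`. The removed sample ids are attached as the
#' `"removed"` attribute and reported via `message()`.
#'
#' @param x an [AsvExperiment].
#' @param policy a [sampleFilterPolicy()].
#' @return the filtered `AsvExperiment` (idempotent).
#' @export
filterSamples <- function(x, policy = sampleFilterPolicy()) {
    stopifnot(is(x, "AsvExperiment"))
    keep <- sampleTotals(x) >= policy$min_total_reads
    if (!any(keep))
        stop("all samples fall below ", policy$min_total_reads, " reads")
    dropped <- colnames(x)[!keep]
    if (length(dropped))
        message("filterSamples: removed ", length(dropped), " sample(s): ",
                paste(dropped, collapse = ", "))
    out <- x[, keep]
    attr(out, "removed") <- dropped
    out
}

#' Subset one size fraction
#'
#' Keeps only the samples of the requested size fraction. ASV rows are kept
#' even when all-zero within the fraction, so ASV ids remain stable across
#' fractions.
#'
#' @param x an [AsvExperiment].
#' @param fraction `"gt3um"` or `"0.2-3um"`.
#' @return an `AsvExperiment` with only that fraction's samples.
#' @export
subsetFraction <- function(x, fraction) {
    stopifnot(is(x, "AsvExperiment"))
    if (!fraction %in% .FRACTIONS)
        stop("unknown size fraction '", fraction, "'; valid: ",
             paste(.FRACTIONS, collapse = ", "))
    keep <- sizeFraction(x) == fraction
    if (!any(keep))
        stop("no samples in size fraction '", fraction, "'")
    x[, keep]
}
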