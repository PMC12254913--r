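#' ASV count table with taxonomy and dated sample metadata
#'
#' `AsvExperiment` extends [SummarizedExperiment::SummarizedExperiment] and is
#' the hub object of the package. The single `"counts"` assay holds raw,
#' non-negative integer read counts (ASVs in rows, samples in columns); raw
#' counts are the only stored abundance representation, and every relative
#' quantity is derived from them on demand. `rowData` carries an eight-rank
#' PR2-style lineage (`domain`, `supergroup`, `division`, `class`, `order`,
#' `family`, `genus`, `species`; any rank may be `"unassigned"`) plus the
#' logical `is_fungal` flag used for all fungal/non-fungal splits. `colData`
#' carries `date` (class `Date`, no time of day), `size_fraction` (one of
#' `"gt3um"`, `"0.2-3um"`) and `station`.
#'
#' @param counts integer-valued matrix of read counts with ASV ids as row
#'   names and sample ids as column names.
#' @param taxonomy `data.frame` with one row per ASV (row names or an
#'   `asv_id` column), the eight rank columns, and logical `is_fungal`. If
#'   `is_fungal` is absent it is derived as `division == "Fungi"`.
#' @param samples `data.frame` with one row per sample (row names or a
#'   `sample_id` column) and columns `date`, `size_fraction`, `station`.
#'
#' @return A validated `AsvExperiment`.
#' @examples
#' counts <- matrix(c(5L, 10L, 5L, 10L, 20L, 10L), nrow = 3,
#'                  dimnames = list(c("ASV1", "ASV2", "ASV3"), c("s1", "s2")))
#' tax <- data.frame(row.names = rownames(counts),
#'                   domain = "Eukaryota", supergroup = "Opisthokonta",
#'                   division = c("Fungi", "Fungi", "Metazoa"),
#'                   class = "unassigned", order = "unassigned",
#'                   family = "unassigned", genus = "unassigned",
#'                   species = "unassigned",
#'                   is_fungal = c(TRUE, TRUE, FALSE))
#' meta <- data.frame(row.names = colnames(counts),
#'                    date = as.Date(c("2015-01-05", "2015-01-12")),
#'                    size_fraction = "gt3um", station = "SOLA")
#' ae <- AsvExperiment(counts, tax, meta)
#' sampleTotals(ae)
#' @export
#' @import SummarizedExperiment
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
AsvExperiment <- function(counts, taxonomy, samples) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have ASV row names and sample column names")
    taxonomy <- .normaliseIdFrame(taxonomy, "asv_id")
    samples <- .normaliseIdFrame(samples, "sample_id")

    missing_tax <- setdiff(rownames(counts), rownames(taxonomy))
    if (length(missing_tax))
        stop("missing taxonomy for counted ASV(s): ",
             paste(head(missing_tax, 5), collapse = ", "))
    missing_meta <- setdiff(colnames(counts), rownames(samples))
    if (length(missing_meta))
        stop("missing sample metadata for: ",
             paste(head(missing_meta, 5), collapse = ", "))

    extra_tax <- setdiff(rownames(taxonomy), rownames(counts))
    if (length(extra_tax)) {
        warning(length(extra_tax), " taxonomy row(s) without counts dropped")
        taxonomy <- taxonomy[rownames(counts), , drop = FALSE]
    }
    extra_meta <- setdiff(rownames(samples), colnames(counts))
    if (length(extra_meta)) {
        warning(length(extra_meta), " metadata row(s) without counts dropped")
        samples <- samples[colnames(counts), , drop = FALSE]
    }
    taxonomy <- taxonomy[rownames(counts), , drop = FALSE]
    samples <- samples[colnames(counts), , drop = FALSE]

    if (!"is_fungal" %in% names(taxonomy)) {
        if (!"division" %in% names(taxonomy))
            stop("taxonomy needs an is_fungal column or a division rank")
        taxonomy$is_fungal <- taxonomy$division == "Fungi"
    }
    taxonomy$is_fungal <- as.logical(taxonomy$is_fungal)

    samples$date <- .parseDates(samples$date, rownames(samples))
    samples$size_fraction <- as.character(samples$size_fraction)
    if (!"station" %in% names(samples)) samples$station <- NA_character_

    for (fr in unique(samples$size_fraction)) {
        d <- samples$date[samples$size_fraction == fr]
        if (anyDuplicated(d))
            warning("duplicate sampling date(s) within size fraction ", fr)
    }

    storage.mode(counts) <- "integer"
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(taxonomy),
        colData = S4Vectors::DataFrame(samples))
    new("AsvExperiment", se)
}

#' @export
setClass("AsvExperiment", contains = "SummarizedExperiment")

.RANKS <- c("domain", "supergroup", "division", "class", "order",
            "family", "genus", "species")
.FRACTIONS <- c("gt3um", "0.2-3um")

setValidity("AsvExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    m <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(m)) msg <- c(msg, "counts contain NA")
    else {
        bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
        if (nrow(bad))
            msg <- c(msg, sprintf(
                "counts must be non-negative integers; offending cell (%s, %s)",
                rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate ASV id(s)")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample id(s)")
    rd <- SummarizedExperiment::rowData(object)
    miss <- setdiff(c(.RANKS, "is_fungal"), colnames(rd))
    if (length(miss))
        msg <- c(msg, paste("taxonomy lacks column(s):",
                            paste(miss, collapse = ", ")))
    else if (anyNA(rd$is_fungal))
        msg <- c(msg, "is_fungal must be TRUE/FALSE, no NA")
    cd <- SummarizedExperiment::colData(object)
    miss <- setdiff(c("date", "size_fraction", "station"), colnames(cd))
    if (length(miss))
        msg <- c(msg, paste("sample metadata lacks column(s):",
                            paste(miss, collapse = ", ")))
    else {
        if (!methods::is(cd$date, "Date") || anyNA(cd$date))
            msg <- c(msg, "sample dates must be valid Date values")
        bad <- setdiff(unique(cd$size_fraction), .FRACTIONS)
        if (length(bad))
            msg <- c(msg, paste("unknown size fraction(s):",
                                paste(bad, collapse = ", "),
                                "- valid:", paste(.FRACTIONS, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

.normaliseIdFrame <- function(df, idcol) {
    df <- as.data.frame(df)
    if (idcol %in% names(df)) {
        if (anyDuplicated(df[[idcol]]))
            stop("duplicate ", idcol, " in ",
                 deparse(substitute(df)), ": ",
                 df[[idcol]][duplicated(df[[idcol]])][1])
        rownames(df) <- df[[idcol]]
        df[[idcol]] <- NULL
    }
    df
}

.parseDates <- function(x, ids) {
    if (methods::is(x, "Date")) return(x)
    d <- as.Date(as.character(x), format = "%Y-%m-%d")
    if (anyNA(d))
        stop("unparseable date for sample '", ids[which(is.na(d))[1]],
             "': '", as.character(x)[which(is.na(d))[1]],
             "' (expected ISO-8601 YYYY-MM-DD)")
    d
}

#' Accessors for AsvExperiment
#'
#' `sampleDates`, `sizeFraction` and `sampleTotals` return per-sample
#' vectors; `isFungal` the per-ASV fungal flag; `taxonomy` the lineage table
#' as a `data.frame`. Per-sample totals are always derived as column sums of
#' the counts, never stored.
#'
#' @param x an `AsvExperiment`.
#' @return see Description.
#' @aliases sampleDates sizeFraction isFungal taxonomy sampleTotals
#' @name sampleDates
NULL

#' @rdname sampleDates
#' @export
setMethod("sampleDates", "AsvExperiment", function(x)
    setNames(SummarizedExperiment::colData(x)$date, colnames(x)))

#' @rdname sampleDates
#' @export
setMethod("sizeFraction", "AsvExperiment", function(x)
    setNames(SummarizedExperiment::colData(x)$size_fraction, colnames(x)))

#' @rdname sampleDates
#' @export
setMethod("isFungal", "AsvExperiment", function(x)
    setNames(SummarizedExperiment::rowData(x)$is_fungal, rownames(x)))

#' @rdname sampleDates
#' @export
setMethod("taxonomy", "AsvExperiment", function(x)
    as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname sampleDates
#' @export
setMethod("sampleTotals", "AsvExperiment", function(x)
    colSums(SummarizedExperiment::assay(x, "counts")))

#' @rdname sampleDates
#' @param object an `AsvExperiment` (counts method).
#' @importFrom BiocGenerics counts
#' @export counts
#' @exportMethod counts
setMethod("counts", "AsvExperiment", function(object)
    SummarizedExperiment::assay(object, "counts"))

setMethod("show", "AsvExperiment", function(object) {
    cat("AsvExperiment:", nrow(object), "ASVs x", ncol(object), "samples\n")
    fr <- table(sizeFraction(object))
    cat("  fractions:",
        paste(names(fr), as.integer(fr), sep = "=", collapse = ", "), "\n")
    d <- sampleDates(object)
    if (length(d))
        cat("  dates:", format(min(d)), "to", format(max(d)), "\n")
    cat("  fungal ASVs:", sum(isFungal(object)), "/", nrow(object), "\n")
})
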