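#' Read an ASV table from its three standard text files
#'
#' Assembles an [AsvExperiment] from a counts table, a taxonomy table and a
#' sample metadata table. The counts file may be either a dense TSV (first
#' column `asv_id`, remaining columns one per sample, integer cells) or a
#' sparse triplet TSV with columns `asv_id`, `sample_id`, `count`
#' (BIOM-style coordinate layout; omitted cells are zero). The layout is
#' auto-detected from the header unless `sparse` is set explicitly.
#'
#' Taxonomy is a TSV with columns `asv_id`, the eight PR2-style ranks and
#' `is_fungal`; metadata is a CSV with columns `sample_id`, `date`
#' (ISO-8601), `size_fraction`, `station`. Taxonomy or metadata rows that
#' reference no counted ASV/sample are dropped with a warning; a counted ASV
#' without taxonomy is an error.
#'
#' @param counts_path,taxonomy_path,metadata_path file paths.
#' @param sparse logical or `NA` (auto-detect).
#' @return an [AsvExperiment].
#' @seealso [writeAsvTable()]
#' @export
readAsvTable <- function(counts_path, taxonomy_path, metadata_path,
                         sparse = NA) {
    for (p in c(counts_path, taxonomy_path, metadata_path))
        if (!file.exists(p)) stop("file not found: ", p)

    header <- strsplit(readLines(counts_path, n = 1), "\t", fixed = TRUE)[[1]]
    if (is.na(sparse))
        sparse <- identical(header, c("asv_id", "sample_id", "count"))

    if (sparse) {
        trip <- read.delim(counts_path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric"))
        if (!identical(names(trip), c("asv_id", "sample_id", "count")))
            stop("sparse counts must have columns asv_id, sample_id, count")
        bad <- which(trip$count < 0 | trip$count != round(trip$count))
        if (length(bad))
            stop(sprintf("counts must be non-negative integers; offending cell (%s, %s)",
                         trip$asv_id[bad[1]], trip$sample_id[bad[1]]))
        asvs <- unique(trip$asv_id)
        smps <- unique(trip$sample_id)
        counts <- matrix(0L, length(asvs), length(smps),
                         dimnames = list(asvs, smps))
        counts[cbind(match(trip$asv_id, asvs), match(trip$sample_id, smps))] <-
            as.integer(trip$count)
    } else {
        df <- read.delim(counts_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
        if (names(df)[1] != "asv_id")
            stop("dense counts must have 'asv_id' as first column")
        if (anyDuplicated(df$asv_id))
            stop("duplicate asv_id in counts: ",
                 df$asv_id[duplicated(df$asv_id)][1])
        counts <- as.matrix(df[, -1, drop = FALSE])
        rownames(counts) <- df$asv_id
        if (anyDuplicated(colnames(counts)))
            stop("duplicate sample id in counts header")
        bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
                     arr.ind = TRUE)
        if (nrow(bad))
            stop(sprintf("counts must be non-negative integers; offending cell (%s, %s)",
                         rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
        storage.mode(counts) <- "integer"
    }

    taxonomy <- read.delim(taxonomy_path, stringsAsFactors = FALSE)
    metadata <- read.csv(metadata_path, stringsAsFactors = FALSE)
    AsvExperiment(counts, taxonomy, metadata)
}

#' Write an ASV table to the three standard text files
#'
#' Inverse of [readAsvTable()]: writes counts (dense TSV, or sparse triplet
#' TSV storing only non-zero cells when `sparse = TRUE`), the taxonomy TSV
#' and the metadata CSV.
#'
#' @param x an [AsvExperiment].
#' @inheritParams readAsvTable
#' @param sparse write the sparse triplet dialect instead of dense TSV.
#' @return `invisible(x)`.
#' @export
writeAsvTable <- function(x, counts_path, taxonomy_path, metadata_path,
                          sparse = FALSE) {
    stopifnot(is(x, "AsvExperiment"))
    m <- counts(x)
    if (sparse) {
        idx <- which(m > 0, arr.ind = TRUE)
        trip <- data.frame(asv_id = rownames(m)[idx[, 1]],
                           sample_id = colnames(m)[idx[, 2]],
                           count = m[idx])
        trip <- trip[order(trip$asv_id, trip$sample_id), ]
        write.table(trip, counts_path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    } else {
        df <- data.frame(asv_id = rownames(m), m, check.names = FALSE)
        write.table(df, counts_path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    tax <- data.frame(asv_id = rownames(x), taxonomy(x), check.names = FALSE)
    write.table(tax, taxonomy_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    meta <- data.frame(sample_id = colnames(x),
                       date = format(sampleDates(x)),
                       size_fraction = sizeFraction(x),
                       station = SummarizedExperiment::colData(x)$station)
    write.csv(meta, metadata_path, row.names = FALSE, quote = FALSE)
    invisible(x)
}

#' @importFrom utils read.csv write.csv
NULL
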