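#' @keywords internal
#' Resolve a taxon selector to a logical vector over ASVs.
#' Accepted selectors: "Total" (all ASVs), "Fungi" (the is_fungal flag),
#' a character vector of ASV ids, or a single lineage label matched against
#' every taxonomy rank (e.g. "Ascomycota").
.selectAsvs <- function(x, selector) {
    ids <- rownames(x)
    if (is.logical(selector)) {
        stopifnot(length(selector) == length(ids))
        return(selector)
    }
    if (length(selector) == 1 && selector == "Total")
        return(rep(TRUE, length(ids)))
    if (length(selector) == 1 && selector == "Fungi")
        return(isFungal(x))
    if (all(selector %in% ids))
        return(ids %in% selector)
    if (length(selector) == 1) {
        tax <- taxonomy(x)
        hit <- Reduce(`|`, lapply(.RANKS, function(r) tax[[r]] == selector))
        if (any(hit)) return(hit)
    }
    stop("cannot resolve taxon selector: ",
         paste(head(selector, 3), collapse = ", "))
}

.selectorLabel <- function(selector) {
    if (is.character(selector) && length(selector) == 1) selector else "set"
}

#' Relative abundance under a declared normalisation group
#'
#' Converts raw counts to per-sample relative abundances
#' RA(i, G, s) = N_i(s) / N_G(s), where the reference group G is typically
#' `"Total"` (all eukaryotic reads) or `"Fungi"`. Samples in which the group
#' has zero reads have an undefined RA and are returned as `NA`, never 0.
#'
#' @param x an [AsvExperiment].
#' @param taxa either a character vector of ASV ids (one result row per ASV)
#'   or a single selector such as `"Fungi"` or a lineage label (one
#'   aggregated row). Every selected ASV must be nested in `group`.
#' @param group reference selector (default `"Total"`).
#' @return numeric matrix of fractions in \[0, 1\] (rows = taxa, columns =
#'   samples), `NA` where the group has no reads, with attributes `group`
#'   and `sample_totals` (the per-sample group read counts used as
#'   denominators).
#' @examples
#' ae <- simulateAsvExperiment(simConfig(seed = 1, years = 1))$experiment
#' raf <- relativeAbundance(ae, "Fungi", "Total")
#' summary(as.numeric(raf))
#' @export
relativeAbundance <- function(x, taxa, group = "Total") {
    stopifnot(is(x, "AsvExperiment"))
    m <- counts(x)
    gsel <- .selectAsvs(x, group)
    tsel <- .selectAsvs(x, taxa)
    if (any(tsel & !gsel))
        stop("selected taxa are not nested in group '",
             .selectorLabel(group), "'")
    denom <- colSums(m[gsel, , drop = FALSE])
    perAsv <- is.character(taxa) && length(taxa) >= 1 &&
        all(taxa %in% rownames(x))
    if (perAsv) {
        num <- m[taxa, , drop = FALSE]
    } else {
        num <- matrix(colSums(m[tsel, , drop = FALSE]), nrow = 1,
                      dimnames = list(.selectorLabel(taxa), colnames(m)))
    }
    ra <- sweep(num, 2, denom, "/")
    ra[, denom == 0] <- NA_real_
    structure(ra, group = .selectorLabel(group), sample_totals = denom)
}

#' Cumulative Relative Abundance (CRA) of a taxon within a group
#'
#' The whole-series importance weight of taxon i within group G:
#' CRA(i, G) = sum_s RA(i, Total, s) / sum_s RA(G, Total, s), equivalently
#' the ratio of the mean Total-normalised relative abundances. Both forms
#' are computed and checked to agree to 1e-12. Samples with zero total reads
#' carry undefined RA and are excluded from both sums (never imputed as 0).
#'
#' @param x an [AsvExperiment].
#' @param taxon selector for the focal taxon (ASV id(s) or lineage label).
#' @param group selector for the enclosing group.
#' @return one-row `data.frame` with columns `taxon_id`, `group`, `cra`,
#'   `n_samples`.
#' @examples
#' ae <- simulateAsvExperiment(simConfig(seed = 1, years = 1))$experiment
#' cumulativeRelativeAbundance(ae, "Fungi", "Total")
#' @export
cumulativeRelativeAbundance <- function(x, taxon, group = "Total") {
    rec <- craTable(x, list(taxon), group)
    rec$taxon_id <- .selectorLabel(taxon)
    rec
}

#' CRA records for many taxa within one group
#'
#' Vectorised form of [cumulativeRelativeAbundance()]: one record per entry
#' of `taxa`, all sharing the reference `group`.
#'
#' @param x an [AsvExperiment].
#' @param taxa a character vector of ASV ids, or a list of selectors.
#' @param group reference selector shared by all records.
#' @return `data.frame` with columns `taxon_id`, `group`, `cra`, `n_samples`.
#' @export
craTable <- function(x, taxa = rownames(x)[isFungal(x)], group = "Fungi") {
    stopifnot(is(x, "AsvExperiment"))
    m <- counts(x)
    total <- colSums(m)
    ok <- total > 0                      # undefined RA samples excluded
    if (!any(ok)) stop("no sample has positive total reads")
    gsel <- .selectAsvs(x, group)
    raG <- colSums(m[gsel, ok, drop = FALSE]) / total[ok]
    if (sum(raG) == 0)
        stop("group '", .selectorLabel(group), "' absent from all samples")

    if (is.character(taxa)) taxa <- as.list(taxa)
    rows <- lapply(taxa, function(sel) {
        tsel <- .selectAsvs(x, sel)
        if (any(tsel & !gsel))
            stop("taxon '", .selectorLabel(sel), "' not nested in group '",
                 .selectorLabel(group), "'")
        raI <- colSums(m[tsel, ok, drop = FALSE]) / total[ok]
        cra <- sum(raI) / sum(raG)
        # Eq. identity: the sum ratio must equal the ratio of means
        stopifnot(abs(cra - mean(raI) / mean(raG)) <= 1e-12)
        data.frame(taxon_id = .selectorLabel(sel),
                   group = .selectorLabel(group),
                   cra = cra, n_samples = sum(ok))
    })
    do.call(rbind, rows)
}

#' Select the major taxa covering a CRA threshold
#'
#' Orders CRA records by descending `cra` (ties broken by ascending
#' `taxon_id`) and returns the shortest prefix whose cumulative CRA reaches
#' the threshold — the "major" taxa of the group, e.g. the small set of ASVs
#' that account for 90 % of fungal reads series-wide.
#'
#' @param cra_records `data.frame` from [craTable()]; records must share one
#'   group.
#' @param threshold fraction in (0, 1\].
#' @return `data.frame` with columns `taxon_id`, `cra`, `coverage`
#'   (cumulative CRA after each taxon), attribute `threshold`.
#' @export
selectMajorTaxa <- function(cra_records, threshold = 0.9) {
    stopifnot(threshold > 0, threshold <= 1)
    if (length(unique(cra_records$group)) != 1)
        stop("CRA records must share a single group")
    tot <- sum(cra_records$cra)
    if (tot < threshold - 1e-12)
        stop(sprintf("records only cover %.4f < threshold %.4f",
                     tot, threshold))
    ord <- order(-cra_records$cra, cra_records$taxon_id)
    r <- cra_records[ord, ]
    cov <- cumsum(r$cra)
    k <- which(cov >= threshold - 1e-12)[1]
    out <- data.frame(taxon_id = r$taxon_id[seq_len(k)],
                      cra = r$cra[seq_len(k)],
                      coverage = cov[seq_len(k)])
    attr(out, "threshold") <- threshold
    out
}
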