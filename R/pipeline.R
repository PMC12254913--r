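#' Pipeline configuration
#'
#' Assembles the full parameter set of [runPipeline()]. The `"sola2025"`
#' preset pins every analysis parameter to the study defaults: 1000-read
#' sample filter, 50 fungal reads for diversity, bloom threshold 0.05 with
#' dominance levels 0.5/0.9 and persistence gap 8 d, periodogram range
#' 2-900 d at oversampling 1 and alpha 0.01, winter defined as
#' January-March, CRA major-set threshold 0.9, and the headline growth
#' scenario (x = 1e5, y = 2.5e-6, t = 72 h). Values can be overridden by
#' name, or read from a plain `key = value` text file.
#'
#' @param preset currently `"sola2025"`.
#' @param ... overrides of preset entries.
#' @param file optional path to a `key = value` config file whose entries
#'   override the preset (applied before `...`).
#' @return named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(preset = "sola2025", ..., file = NULL) {
    stopifnot(preset == "sola2025")
    cfg <- list(seed = 42, simulate = TRUE, sim_years = 5,
                counts_path = NA, taxonomy_path = NA, metadata_path = NA,
                min_total_reads = 1000, min_fungal_reads = 50,
                bloom_threshold = 0.05, dominance_levels = c(0.5, 0.9),
                persistence_threshold = 0.10, max_gap_days = 8,
                cra_threshold = 0.9,
                min_period = 2, max_period = 900, oversampling = 1,
                alpha = 0.01,
                growth_x = 1e5, growth_y = 2.5e-6, growth_t = 72)
    if (!is.null(file)) {
        if (!file.exists(file)) stop("config file not found: ", file)
        lines <- grep("=", readLines(file), value = TRUE, fixed = TRUE)
        for (ln in lines) {
            kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
            key <- trimws(kv[1])
            val <- trimws(paste(kv[-1], collapse = "="))
            num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
            cfg[[key]] <- if (!anyNA(num)) num
                          else if (val %in% c("TRUE", "FALSE")) as.logical(val)
                          else val
        }
    }
    over <- list(...)
    cfg[names(over)] <- over
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Run the full analysis pipeline
#'
#' Chains simulate (or read) -> filter -> CRA/major ASVs -> blooms ->
#' rhythmicity -> diversity -> growth, writing one text artefact per stage
#' into `out_dir` plus a `manifest.json` recording the package version,
#' the configuration, input file digests and the MD5 of every output, so a
#' rerun with the same manifest reproduces the deterministic outputs
#' byte-for-byte. Stage outputs are written with a `.partial` suffix and
#' renamed only when all stages succeed; on a stage error the partial
#' artefacts of completed stages are retained for inspection and the error
#' names the failing stage.
#'
#' @param config a [pipelineConfig()] (or a path to a `key = value` config
#'   file).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir) {
    if (is.character(config)) config <- pipelineConfig(file = config)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    partial <- character(0)
    emit <- function(name, writer) {
        p <- file.path(out_dir, paste0(name, ".partial"))
        writer(p)
        partial[[name]] <<- p
    }
    stage <- function(name, expr)
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    writeTsv <- function(df) function(p)
        write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    writeJson <- function(x) function(p)
        jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows", pretty = TRUE)

    inputs <- list()
    tab <- stage("input", {
        if (isTRUE(config$simulate)) {
            sim <- simulateAsvExperiment(
                simConfig(seed = config$seed, years = config$sim_years))
            emit("ground_truth.tsv", writeTsv(sim$truth$sample_truth))
            sim$experiment
        } else {
            for (p in c(config$counts_path, config$taxonomy_path,
                        config$metadata_path))
                if (!file.exists(p)) stop("input file not found: ", p)
            inputs <- lapply(c(counts = config$counts_path,
                               taxonomy = config$taxonomy_path,
                               metadata = config$metadata_path),
                             function(p) unname(tools::md5sum(p)))
            readAsvTable(config$counts_path, config$taxonomy_path,
                         config$metadata_path)
        }
    })

    tab <- stage("filter", filterSamples(
        tab, sampleFilterPolicy(config$min_total_reads,
                                config$min_fungal_reads)))

    stage("cra", {
        cra <- craTable(tab, group = "Fungi")
        emit("cra.tsv", writeTsv(cra))
        emit("major_asvs.tsv",
             writeTsv(selectMajorTaxa(cra, config$cra_threshold)))
    })

    events <- stage("blooms", {
        ev <- detectBlooms(tab, config$bloom_threshold,
                           config$dominance_levels)
        emit("blooms.json", writeJson(transform(ev, date = format(date))))
        emit("bloom_months.tsv", writeTsv(data.frame(
            month = month.abb,
            bloom_fraction = unname(bloomFractionByMonth(ev, tab)))))
        pers <- lapply(setNames(.FRACTIONS, .FRACTIONS), function(fr) {
            sub <- subsetFraction(tab, fr)
            sub <- sub[, order(sampleDates(sub))]
            ra <- relativeAbundance(sub, "Fungi", "Total")[1, ]
            r <- bloomPersistence(sampleDates(sub), ra,
                                  config$persistence_threshold,
                                  config$max_gap_days)
            r$runs <- transform(r$runs, start = format(start),
                                end = format(end))
            r
        })
        emit("persistence.json", writeJson(pers))
        ev
    })

    stage("rhythm", {
        cra <- craTable(tab, group = "Fungi")
        majors <- selectMajorTaxa(cra, config$cra_threshold)$taxon_id
        sub <- subsetFraction(tab, "gt3um")
        emit("rhythm.tsv", writeTsv(classifyTable(
            sub, majors, min_period = config$min_period,
            max_period = config$max_period,
            oversampling = config$oversampling, alpha = config$alpha)))
    })

    stage("diversity", {
        div <- alphaDiversity(tab, config$min_fungal_reads)
        emit("diversity.tsv", writeTsv(transform(div, date = format(date))))
        tests <- list()
        if (nlevels(droplevels(div$season)) >= 2)
            tests$season_shannon <- compareGroups(div$shannon, div$season)
        if (length(unique(div$size_fraction)) >= 2)
            tests$fraction_shannon <-
                compareGroups(div$shannon, div$size_fraction)
        emit("diversity_tests.json", writeJson(tests))
    })

    stage("growth", {
        mu <- requiredMu(config$growth_x, config$growth_y, config$growth_t)
        emit("growth.json", writeJson(list(
            x = config$growth_x, y = config$growth_y, t = config$growth_t,
            mu_printed = mu,
            mu_exact = requiredMu(config$growth_x, config$growth_y,
                                  config$growth_t, mode = "exact"),
            feasibility = growthFeasibility(mu))))
    })

    # all stages done: promote partials, then write the manifest last
    finals <- sub("\\.partial$", "", partial)
    file.rename(partial, finals)
    manifest <- list(tool = "mycobloom",
                     version = as.character(packageVersion("mycobloom")),
                     seed = config$seed,
                     config = unclass(config),
                     inputs = inputs,
                     outputs = lapply(setNames(finals, basename(finals)),
                                      function(p) unname(tools::md5sum(p))),
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
}
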