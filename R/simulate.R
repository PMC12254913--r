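#' Configuration of the synthetic time-series generator
#'
#' Defaults emulate the study conditions the analyses assume: a roughly
#' five-year calendar starting May 2013 with fortnightly baseline sampling
#' tightened to twice a week in winter (January-March), per-sample read
#' depths log-normal around a median of ~37,000 reads, a seasonal background
#' community of 150 non-fungal ASVs, and sparse fungal ASVs of the three
#' dynamic archetypes (10 rhythmic, 20 chaotic, 10 ephemeral) whose blooms
#' last days. Two size fractions are generated by splitting each fungal
#' ASV's latent signal with an ASV-specific mixing weight.
#'
#' @param seed integer fixing every random draw.
#' @param years length of the series.
#' @param start_date first sampling date (ISO-8601).
#' @param baseline_interval_days,winter_interval_days sampling intervals
#'   (days) outside/inside January-March.
#' @param jitter_days uniform +/- jitter on each interval.
#' @param n_background_asvs,n_rhythmic,n_chaotic,n_ephemeral community
#'   sizes.
#' @param depth_log_mean,depth_log_sd log-normal read-depth parameters.
#' @param background_amplitude maximal annual-sinusoid modulation of
#'   background ASVs (0-1).
#' @param rhythmic_peak_ra,chaotic_spike_ra,ephemeral_ra latent peak RA
#'   ranges `c(lo, hi)` per archetype; peaks are drawn log-uniformly so
#'   most events stay small and only a minority cross the 5 % bloom level,
#'   keeping blooms the rare, short events the sampling programme observed.
#' @param rhythmic_day_jitter_sd sd (days) of the annual peak date jitter.
#' @param rhythmic_width_days Gaussian sd (days) of a rhythmic bloom.
#' @param chaotic_spike_rate spikes per year (Poisson mean; at least two
#'   spikes are always planted, since a chaotic taxon by definition
#'   reappears).
#' @param chaotic_width_days,ephemeral_width_days width ranges (days).
#' @param fraction_mix range of the per-ASV share of the latent fungal
#'   signal assigned to the > 3 um fraction.
#' @param background_crash optional `list(start, end, factor)` scaling the
#'   background community's absolute abundance inside a date window, to
#'   emulate compositional "false blooms": the recorded latent fungal RA
#'   rises inside the window although the fungal signal itself is
#'   unchanged.
#' @return a named list of class `SimulationConfig`.
#' @export
simConfig <- function(seed = 42, years = 5, start_date = "2013-05-01",
                      baseline_interval_days = 14,
                      winter_interval_days = 3.5, jitter_days = 1,
                      n_background_asvs = 150, n_rhythmic = 10,
                      n_chaotic = 20, n_ephemeral = 10,
                      depth_log_mean = log(37000), depth_log_sd = 0.15,
                      background_amplitude = 0.6,
                      rhythmic_peak_ra = c(0.006, 0.12),
                      rhythmic_day_jitter_sd = 10,
                      rhythmic_width_days = 6,
                      chaotic_spike_rate = 0.8,
                      chaotic_spike_ra = c(0.003, 0.22),
                      chaotic_width_days = c(1.5, 4),
                      ephemeral_ra = c(0.02, 0.20),
                      ephemeral_width_days = c(3, 12),
                      fraction_mix = c(0.55, 0.95),
                      background_crash = NULL) {
    cfg <- as.list(environment())
    stopifnot(cfg$years > 0, cfg$n_background_asvs >= 1,
              all(cfg$rhythmic_peak_ra > 0 & cfg$rhythmic_peak_ra < 1),
              all(cfg$chaotic_spike_ra > 0 & cfg$chaotic_spike_ra < 1),
              all(cfg$ephemeral_ra > 0 & cfg$ephemeral_ra < 1))
    class(cfg) <- "SimulationConfig"
    cfg
}

.rlunif <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

# run expr under a fixed seed without disturbing the caller's RNG state
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", globalenv())
        on.exit(assign(".Random.seed", old, globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

#' Sampling calendar of the synthetic series
#'
#' Strictly increasing dates with approximately fortnightly spacing,
#' tightened to `winter_interval_days` during January-March, each interval
#' perturbed by a uniform integer jitter of +/- `jitter_days`. Fully
#' deterministic under `config$seed`, and identical to the calendar used
#' inside [simulateAsvExperiment()] for the same config.
#'
#' @param config a [simConfig()].
#' @return `Date` vector.
#' @export
makeCalendar <- function(config = simConfig()) {
    .withSeed(config$seed, .drawCalendar(config))
}

.drawCalendar <- function(cfg) {
    start <- as.Date(cfg$start_date)
    horizon <- cfg$years * 365.25
    t <- 0
    offs <- numeric(0)
    while (t <= horizon) {
        offs <- c(offs, t)
        m <- as.integer(format(start + round(t), "%m"))
        iv <- if (m %in% 1:3) cfg$winter_interval_days
              else cfg$baseline_interval_days
        jit <- if (cfg$jitter_days > 0)
            sample(seq(-cfg$jitter_days, cfg$jitter_days), 1) else 0
        t <- t + max(iv + jit, 1)
    }
    start + round(offs)
}

#' Simulate an ASV table with exported ground truth
#'
#' Builds per-sample expected relative abundances from a seasonal log-normal
#' background community plus fungal ASVs of the three archetypes (annual
#' Gaussian blooms with per-year date jitter; randomly timed spikes; one
#' single window), splits the fungal signal between the two size fractions
#' with per-ASV mixing weights, renormalises the expectation to sum to one,
#' and draws each sample's counts multinomially at a log-normal depth.
#' Bloom events are planted at sampling dates so that every latent event is
#' observable at the configured sampling frequency.
#'
#' @param config a [simConfig()].
#' @return list with `experiment` (an [AsvExperiment]) and `truth`, a list
#'   holding `asv_info` (archetype, mixing weight and peak parameters per
#'   fungal ASV), `latent_ra` (latent fungal RA matrix, ASVs x samples),
#'   `sample_truth` (per sample: latent total fungal RA and drawn depth)
#'   and `events` (planted bloom windows per ASV).
#' @examples
#' sim <- simulateAsvExperiment(simConfig(seed = 1, years = 1))
#' sim$experiment
#' @export
simulateAsvExperiment <- function(config = simConfig()) {
    .withSeed(config$seed, .simulate(config))
}

.simulate <- function(cfg) {
    dates <- .drawCalendar(cfg)
    off <- as.numeric(dates - dates[1])
    doy0 <- as.integer(format(dates[1], "%j"))
    nD <- length(dates)
    nF <- cfg$n_rhythmic + cfg$n_chaotic + cfg$n_ephemeral
    archetype <- rep(c("rhythmic", "chaotic", "ephemeral"),
                     c(cfg$n_rhythmic, cfg$n_chaotic, cfg$n_ephemeral))
    fid <- sprintf("ASV%03d", seq_len(nF))
    bid <- sprintf("BKG%03d", seq_len(cfg$n_background_asvs))

    # --- background: log-normal baseline x annual sinusoid per ASV
    base <- rlnorm(cfg$n_background_asvs, 0, 1.2)
    amp <- runif(cfg$n_background_asvs, 0, cfg$background_amplitude)
    phase <- runif(cfg$n_background_asvs, 0, 365)
    doy <- as.numeric(format(dates, "%j"))
    seas <- cos(outer(phase, doy, function(p, d) 2 * pi * (d - p) / 365))
    bg <- base * (1 + amp * seas)   # length-n vectors recycle down rows
    bg <- pmax(bg, 1e-8)
    # background-crash factor scales the background's absolute abundance
    # relative to the fungal signal: fungal RA rises with no fungal growth
    crashFac <- rep(1, nD)
    if (!is.null(cfg$background_crash)) {
        inwin <- dates >= as.Date(cfg$background_crash$start) &
                 dates <= as.Date(cfg$background_crash$end)
        crashFac[inwin] <- cfg$background_crash$factor
    }

    # --- fungal latent trajectories (RA before fraction split)
    lat <- matrix(0, nF, nD, dimnames = list(fid, NULL))
    info <- data.frame(asv_id = fid, archetype = archetype,
                       peak_ra = NA_real_, peak_doy = NA_real_,
                       n_events = NA_integer_, mix_gt3 = NA_real_)
    events <- list()
    span <- max(off)
    yearsSpanned <- ceiling(cfg$years) + 1
    for (i in seq_len(nF)) {
        if (archetype[i] == "rhythmic") {
            pdoy <- runif(1, 1, 365)
            pra <- .rlunif(1, cfg$rhythmic_peak_ra)
            jit <- rnorm(yearsSpanned + 1, 0, cfg$rhythmic_day_jitter_sd)
            centers <- (pdoy - doy0) + 365.25 * (0:yearsSpanned) + jit
            centers <- centers[centers > -60 & centers < span + 60]
            w <- cfg$rhythmic_width_days
            lat[i, ] <- pra * rowSums(exp(-outer(off, centers, "-")^2 /
                                              (2 * w^2)))
            info$peak_ra[i] <- pra; info$peak_doy[i] <- pdoy
            info$n_events[i] <- length(centers)
            events[[fid[i]]] <- data.frame(center_day = centers, width = w)
        } else if (archetype[i] == "chaotic") {
            k <- max(2L, rpois(1, cfg$chaotic_spike_rate * cfg$years))
            centers <- off[sample.int(nD, k)]
            pra <- .rlunif(k, cfg$chaotic_spike_ra)
            w <- runif(k, cfg$chaotic_width_days[1], cfg$chaotic_width_days[2])
            lat[i, ] <- colSums(pra * exp(-t(outer(off, centers, "-"))^2 /
                                              (2 * w^2)))
            info$peak_ra[i] <- max(pra); info$n_events[i] <- k
            events[[fid[i]]] <- data.frame(center_day = centers, width = w)
        } else {
            w <- runif(1, cfg$ephemeral_width_days[1],
                       cfg$ephemeral_width_days[2])
            center <- off[sample.int(nD, 1)]
            pra <- .rlunif(1, cfg$ephemeral_ra)
            lat[i, ] <- pra * exp(-(off - center)^2 / (2 * (w / 2)^2))
            info$peak_ra[i] <- pra; info$n_events[i] <- 1L
            events[[fid[i]]] <- data.frame(center_day = center, width = w)
        }
    }
    lat[lat < 1e-12] <- 0
    info$mix_gt3 <- runif(nF, cfg$fraction_mix[1], cfg$fraction_mix[2])

    # --- assemble per fraction, renormalise, draw counts
    fracs <- c("gt3um", "0.2-3um")
    tag <- c(gt3um = "G", `0.2-3um` = "S")
    allCounts <- NULL; meta <- NULL; latAll <- NULL; struth <- NULL
    for (fr in fracs) {
        wmix <- if (fr == "gt3um") info$mix_gt3 else 1 - info$mix_gt3
        latF <- lat * wmix
        totF <- colSums(latF)
        if (any(totF >= 0.97))
            stop("latent fungal RA reaches ", sprintf("%.2f", max(totF)),
                 "; reduce archetype peak RA parameters")
        bgTot <- (1 - totF) * crashFac
        denom <- totF + bgTot
        latF <- sweep(latF, 2, denom, "/")   # realised RA after any crash
        totF <- totF / denom
        prob <- rbind(latF,
                      sweep(sweep(bg, 2, colSums(bg), "/"), 2,
                            bgTot / denom, "*"))
        rownames(prob) <- c(fid, bid)
        depth <- round(rlnorm(nD, cfg$depth_log_mean, cfg$depth_log_sd))
        cnt <- vapply(seq_len(nD), function(j)
            rmultinom(1, depth[j], prob[, j])[, 1],
            integer(nF + cfg$n_background_asvs))
        sid <- paste0(format(dates), "_", tag[[fr]])
        colnames(cnt) <- sid
        allCounts <- cbind(allCounts, cnt)
        meta <- rbind(meta, data.frame(
            sample_id = sid, date = dates, size_fraction = fr,
            station = "synthetic"))
        colnames(latF) <- sid
        latAll <- cbind(latAll, latF)
        struth <- rbind(struth, data.frame(
            sample_id = sid, date = dates, size_fraction = fr,
            fungal_ra = totF, depth = depth))
    }

    phyla <- c("Ascomycota", "Basidiomycota", "Chytridiomycota",
               "Cryptomycota", "unassigned")
    bgdiv <- c("Dinoflagellata", "Ochrophyta", "Ciliophora",
               "Chlorophyta", "Metazoa", "Haptophyta")
    taxo <- data.frame(
        asv_id = c(fid, bid),
        domain = "Eukaryota",
        supergroup = c(rep("Opisthokonta", nF),
                       rep("unassigned", cfg$n_background_asvs)),
        division = c(rep("Fungi", nF),
                     sample(bgdiv, cfg$n_background_asvs, replace = TRUE)),
        class = c(sample(phyla, nF, replace = TRUE),
                  rep("unassigned", cfg$n_background_asvs)),
        order = "unassigned", family = "unassigned",
        genus = "unassigned", species = "unassigned",
        is_fungal = c(rep(TRUE, nF), rep(FALSE, cfg$n_background_asvs)))

    ae <- AsvExperiment(allCounts, taxo, meta)
    list(experiment = ae,
         truth = list(asv_info = info, latent_ra = latAll,
                      sample_truth = struth, events = events,
                      config = cfg))
}
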