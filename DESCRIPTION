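Package: mycobloom
Title: Bloom and Rhythmicity Analytics for Marine Fungal Metabarcoding Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse planktonic fungal dynamics in dated 18S amplicon
    (ASV) time series. Implements relative abundance and Cumulative Relative
    Abundance (CRA) metrics with explicit normalisation groups, major-ASV
    selection, operational bloom detection with within-bloom dominance
    profiling and persistence statistics, Lomb-Scargle periodogram analysis of
    irregularly sampled trajectories with a rhythmic/chaotic/ephemeral
    classifier, fungal alpha diversity with seasonal group comparisons, a
    growth-rate feasibility calculator for bloom plausibility, and a
    ground-truthed synthetic generator emulating a coastal high-frequency
    sampling programme. Count tables are held in an S4 container extending
    SummarizedExperiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Metagenomics, Microbiome, TimeCourse, Software
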