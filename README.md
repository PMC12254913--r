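# mycobloom

Analytics for the temporal dynamics of planktonic Fungi in dated 18S
metabarcoding (ASV) time series.

Fungi are usually a minor, easily overlooked fraction of the marine
eukaryotic plankton — until they suddenly are not: coastal
high-frequency surveys show fungal reads jumping from well under 1 % to
tens of percent of eukaryotes and collapsing again within days. Working
with such series raises recurring methodological questions that this
package answers with tested, reusable code for ecologists analysing
amplicon time series:

* how to quantify a taxon's importance across a whole irregularly
  sampled series (per-sample **relative abundance** and series-wide
  **Cumulative Relative Abundance**, with explicit normalisation groups
  and principled handling of undefined values);
* how to detect and characterise **blooms** (threshold events, minimal
  dominating ASV sets, persistence across consecutive sampling points
  with a sampling-gap cap, monthly bloom frequency);
* whether a trajectory is **rhythmic, chaotic or ephemeral**
  (Lomb-Scargle periodogram for irregular sampling plus a codified,
  synthetic-validated classifier);
* how fungal **alpha diversity** varies by month, season and size
  fraction (Shannon / Gini-Simpson on within-Fungi composition,
  rarefaction, Kruskal-Wallis + Dunn + Benjamini-Hochberg);
* whether a bloom could plausibly arise from in-situ **growth**
  (two-population feasibility model).

## The core quantities

For taxon $i$ nested in group $G$ (e.g. "Total" eukaryotes, or
"Fungi"), with $N^s$ raw reads in sample $s$:

$$\mathrm{RA}_i^{G,s} = \frac{N_i^s}{N_G^s},\qquad
  \mathrm{CRA}_i^{G} = \frac{\sum_s \mathrm{RA}_i^{\mathrm{Total},s}}
                            {\sum_s \mathrm{RA}_G^{\mathrm{Total},s}}.$$

A **bloom** is a sample with $\mathrm{RA}_\mathrm{Fungi}^{\mathrm{Total}}
\ge 5\%$; its dominance profile $m(p)$ is the minimal number of ASVs
covering a fraction $p$ of the sample's fungal reads. The growth
feasibility of a bloom that multiplies an organism's relative abundance
by $x$ in $t$ hours from an initial cell fraction $y$ is

$$\mu = \tfrac{1}{t}\log_2\!\big(x - 1 + \tfrac{1}{1-xy}\big)
\ \ [\mathrm{doublings\ h^{-1}}],$$

compared against literature rates (default range 0.01–0.27 h⁻¹).

Counts live in an `AsvExperiment` (an S4 extension of
`SummarizedExperiment`) with PR2-style taxonomy and dated sample
metadata; readers/writers cover dense TSV and sparse triplet layouts. A
fully ground-truthed synthetic generator emulates a five-year coastal
sampling programme (fortnightly baseline, twice-weekly winters,
log-normal depths around 37k reads, seasonal background community, three
fungal archetypes) and backs every recovery test. See the methods
vignette (`vignettes/mycobloom-methods.Rmd`) for models, assumptions and
design decisions.

## Worked example

```r
library(mycobloom)

sim <- simulateAsvExperiment(simConfig(seed = 42))
ae  <- filterSamples(sim$experiment)
ae
#> AsvExperiment: 190 ASVs x 452 samples
#>   fractions: 0.2-3um=226, gt3um=226
#>   dates: 2013-05-01 to 2018-04-19
#>   fungal ASVs: 40 / 190

raF <- relativeAbundance(ae, "Fungi", "Total")[1, ]
round(100 * mean(raF, na.rm = TRUE), 2)      # mean % Fungi of eukaryotes
#> [1] 2.44

blooms <- detectBlooms(ae, threshold = 0.05)
c(n = nrow(blooms), pct = round(100 * nrow(blooms) / ncol(ae), 1))
#>    n  pct
#> 66.0 14.6
head(blooms, 3)
#>     sample_id       date size_fraction   ra_fungi m_0.5 m_0.9
#>  2013-05-27_G 2013-05-27         gt3um 0.05869465     2     3
#>  2013-07-06_G 2013-07-06         gt3um 0.09231331     1     2
#>  2013-11-22_G 2013-11-22         gt3um 0.08383737     1     1

majors <- selectMajorTaxa(craTable(ae, group = "Fungi"), threshold = 0.9)
nrow(majors)                                  # ASVs covering 90% of CRA
#> [1] 25

cls <- classifyTable(subsetFraction(ae, "gt3um"), majors$taxon_id)
table(cls$label)
#>   chaotic ephemeral  rhythmic
#>        15         1         9

mu <- requiredMu(x = 1e5, y = 2.5e-6, t = 72)
round(mu, 2); growthFeasibility(mu)$verdict
#> [1] 0.23
#> [1] "within"
```

Reading: Fungi average ~2.4 % of eukaryotic reads but 14.6 % of samples
are blooms, each dominated by very few ASVs (here 1–2 ASVs already cover
half the fungal reads); 25 ASVs carry 90 % of the series-wide fungal
signal, and most of them are non-rhythmic. An ASV appearing from below
detection to 25 % of reads within 3 days would need 0.23 doublings per
hour — inside, but near the top of, the range reported for cultured
marine fungi.

`runPipeline(pipelineConfig(seed = 42), "out/")` chains all stages
(simulate/read, filter, CRA, blooms, rhythm, diversity, growth) and
writes TSV/JSON artefacts plus a reproducibility manifest.

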