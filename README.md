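# gypsocom

Community-assembly analysis for perennial plant communities on gypsum
soils along aridity gradients.

Gypsum outcrops are restrictive island-like soil habitats that host a
specialist flora.  Each species can be scored with an expert-assigned
**gypsophily index** GI from 1 (avoids gypsum) to 5 (strict gypsophyte),
and treating GI as a one-dimensional functional trait lets classic
trait-based and phylogenetic community ecology ask whether heat and
drought filter which species assemble together.  `gypsocom` is for
community ecologists who have a plot-by-species cover matrix, a GI table,
a dated phylogeny and per-plot climate data, and want the full pipeline:
per-plot diversity indices, permutation null models, and gradient GLMs.

## Metrics

For a plot with relative abundances `p_i` (recomputed from cover) and
indices `GI_i`:

* richness `S` and inverse Simpson diversity `1 / Σ p_i²`;
* gypsophily range `GR = max(GI) − min(GI)` (functional-richness
  analogue on the GI axis);
* community mean gypsophily `CMG = Σ GI_i p_i` (community weighted
  mean);
* gypsophily diversity `GD = Σ_{i,j} d_ij p_i p_j` with
  `d_ij = (GI_i − GI_j)²` (Rao quadratic entropy, equal to twice the
  abundance-weighted GI variance);
* standardized effect sizes of GR and GD against a pool-wide
  species→GI shuffle (default 10 000 randomizations):
  `SES = (obs − mean_null) / sd_null`;
* phylogenetic species variability `PSV` (1 on a star phylogeny,
  smaller as co-occurring species grow related), `PSR = PSV × S`, mean
  pairwise patristic distance `MPD`, and the net relatedness index
  `NRI = −(MPD − mean MPD_null) / sd MPD_null` against an
  independent-swap null (default 999 randomizations) that preserves
  plot richness and species occupancy exactly.

Each metric is then modelled with a GLM on the mean maximum temperature
of the hottest month (T), mean annual precipitation (P), their
interaction and total plant cover — Poisson(log) for richness,
quasipoisson(log) for CMG, Gaussian(identity) for the rest — and
summarized with Type-II scaled-deviance chi-square tests, coefficient
signs and significance codes (`*` p<0.05, `**` p<0.01, `***` p<0.001).

## Worked example

No field data are bundled; the synthetic generator builds a full study
(89 plots, 111-species pool, 16 gypsophytes, realistic climate ranges)
with known seeded effects:

```r
library(gypsocom)
ds  <- generate_dataset(scenario_config(), seed = 42)
fit <- gypsum_assembly(ds$community, ds$traits, ds$tree, ds$env,
                       n_rand_trait = 1000, n_rand_phylo = 199, seed = 42)
fit
#> Gypsum community assembly analysis: 89 plots, 111 species, 16 gypsophytes
#> tmax-map collinearity: r = -0.118 (t = -1.11, P = 0.271)
#> Significant gradient terms (Type-II scaled-deviance chi-square):
#>   S          ~ cover     (+) chi2 =  44.5 ***
#>   invSimpson ~ tmax      (-) chi2 = 142.5 ***
#>   invSimpson ~ map       (-) chi2 =  64.1 ***
#>   ...
#>   GR         ~ tmax      (-) chi2 =  33.8 ***
#>   CMG        ~ tmax      (+) chi2 = 155.8 ***

head(fit$metrics[, c("plot_id","S","invSimpson","GR","CMG","GD","PSV","NRI")], 4)
#>   plot_id  S invSimpson GR  CMG   GD   PSV     NRI
#> 1 plot001 14       5.22  3 4.12 2.23 0.755 -0.0104
#> 2 plot002 17       9.15  3 3.99 2.45 0.717  0.8160
#> 3 plot003 14      13.23  3 3.14 2.56 0.730  0.4306
#> 4 plot004 17       8.65  3 3.19 2.40 0.758 -0.3280
```

Reading the report: hotter plots carry communities dominated by gypsum
specialists (CMG rises with T), spanning a narrower slice of the
soil-affinity axis (GR falls with T) and lower taxonomic diversity,
while richness itself tracks plant cover — the generator's seeded
assembly pattern, recovered by the fitted models.  `summary(fit)` prints
the full deviance table; `coef`, `predict`, `residuals` and `plot`
expose the per-metric GLMs.  `run_full_analysis()` writes `metrics.csv`,
`model_report.csv` and an audit log;
`inst/scripts/gypsocom.R` wraps simulate/analyze/all for shell use.

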