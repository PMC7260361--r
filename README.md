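# dictyfit

Comparative fitness analysis of dictyostelid spores and cysts, from
plaque-count survival assays to a fossil-calibrated molecular clock.

Dictyostelid social amoebae survive starvation either as single-celled
**cysts** or as **spores** formed in multicellular fruiting bodies — a
costly strategy (a fraction of cells dies as stalk) whose payoff is the
central question this pipeline quantifies.  `dictyfit` is aimed at
researchers analysing long-term survival assays of dormant cells,
relating that fitness to cell ultrastructure and species ecology, and
placing the result on a dated phylogeny.  Every stage runs on synthetic
data generated by the package, so the full analysis is reproducible
end to end without any external downloads.

## What it computes

* **Survival curves** from clonal plaque assays: the surviving fraction
  of a replicate is `plaques / cells plated`, with
  `cells = 10^4 cells/ml x volume / 1000` (100 cells per 10 µl aliquot).
* **Relative fitness** *F*: each curve is normalized at every timepoint
  to the mean survival of *all* spore curves (all species and storage
  conditions), then averaged over the six post-baseline timepoints
  (days 1–365).  Spore values average to exactly 1 by construction;
  *F* > 1 marks better-than-average survivors.
* **Group comparisons**: Kruskal–Wallis ("ANOVA on ranks", tie-corrected)
  over taxon-group pools with a Dunn pairwise P-matrix; exact
  permutation p-values for small samples.
* **Morphometry**: 20 per-species ultrastructure features (wall layer
  widths, organelle area fractions with granules as circles
  Σπd²/4, mitochondrion feature fractions, …), their Spearman
  correlation with frost fitness, and group-versus-rest contrasts.
* **Ecology**: climate zones ranked 1–5 (tropical → arctic/alpine),
  species ranges reduced to coldest/warmest rank, the per-group
  percentage matrix of coldest isolation climates, and climate–fitness
  correlations.
* **Node dating**: a desk-scale Bayesian relaxed clock on a fixed rooted
  topology — independent log-normal branch rates
  (log r ~ N(log µ − σ²/2, σ²), so E[r] = µ), gamma hyperpriors
  µ ~ Γ(2, 20) and σ² ~ Γ(1, 10) (shape/rate), soft-bound fossil
  calibrations with exact 2.5% tail masses, a Gaussian approximate
  branch-length likelihood, Metropolis-within-Gibbs MCMC with
  likelihood-invariant mixing moves, two-chain convergence checks and
  95% HPD summaries in units of 100 My.

## Worked example

```r
library(dictyfit)

obs <- gen_survival(seed = 1)                  # plaque-count table
fit <- relative_fitness(survival_fractions(obs))
cmp <- group_fitness_comparison(fit)
cmp$m20C_wet$pools
#>   pool      mean         se n
#> 1    c 0.4379349 0.01812441 5
#> 2 grp1 0.7366070 0.04094226 5
#> 3 grp2 1.2885336 0.08367254 5
#> 4 grp3 0.7784482 0.02399023 5
#> 5 grp4 1.7649189 0.08145956 5
round(cmp$m20C_wet$p_matrix, 4)
#>           c   grp1   grp2   grp3   grp4
#> c    1.0000 0.1562 0.0011 0.0711 0.0000
#> grp1 0.1562 1.0000 0.0647 0.6990 0.0046
#> grp2 0.0011 0.0647 1.0000 0.1440 0.3230
#> grp3 0.0711 0.6990 0.1440 1.0000 0.0143
#> grp4 0.0000 0.0046 0.3230 0.0143 1.0000
```

At wet frost (−20 °C), cysts (`c`, mean *F* = 0.44) survive far worse
than spores, and group 4 spores lead (*F* = 1.77); the Dunn matrix shows
which pool differences are individually significant (e.g. group 4 vs
cysts, p < 10⁻⁴).  The same pipeline on the broad ecology roster
reproduces the coldest-climate matrix — group 4: 19% arctic/alpine, 15%
(sub)tropical, five of 27 species from arctic or alpine tundra:

```r
build_table1(gen_ecology(deterministic = TRUE))["4", ]
#>       arctic/alpine subarctic/subalpine temperate subtropical tropical
#>                  19                  15        52           4       11
```

The analysis workflow lives in `analysis/01_simulate.R` …
`05_chronology.R`; each step reads the previous step's tables and writes
its own under `results/`.  Step 5 prints, for a simulated 8-tip tree
with a soft 400–600 My root bracket:

```
True root age: 5.000 (x100 My); posterior mean 4.966, 95% HPD [3.997, 5.990]
Convergence: pass (max between-chain discrepancy 1.41% of the calibration core)
```

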