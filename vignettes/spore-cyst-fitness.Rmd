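---
title: "Methods: comparative spore and cyst fitness, from plaque counts to a dated phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative spore and cyst fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dictyfit)
```

Dictyostelid social amoebae survive starvation in one of two walled dormant
forms: single-celled cysts, made directly by a starving amoeba, or spores,
made inside a multicellular fruiting body at the cost of a sterile stalk.
This package implements the quantitative chain of reasoning that connects
the fitness of those two forms to cell ultrastructure, species ecology and
evolutionary history: long-term survival assays under climate-mimicking
storage, a relative-fitness statistic, rank-based group comparisons,
trait-fitness and climate-fitness correlations, and a desk-scale Bayesian
relaxed-clock dating engine.  Everything runs on synthetic data generated
by the package itself, so the full pipeline is reproducible and testable
end to end.

## The survival assay and its synthetic emulation

The assay model: dormant cells are stored in suspension at a nominal
$10^4$ cells/ml under four conditions (22&nbsp;°C wet, 4&nbsp;°C wet,
−20&nbsp;°C wet, −20&nbsp;°C dry) and plated clonally with food bacteria
at days 0, 1, 7, 30, 91, 182 and 365; every viable cell founds one
countable plaque.  A 10&nbsp;µl aliquot therefore carries 100 cells;
later timepoints use 20–40&nbsp;µl so that enough plaques emerge from
decayed samples.

The generator needs a parametric survival curve although the assay itself
is model-free.  We use a Weibull decay with plateau,

$$S(t) = s_\infty + (1 - s_\infty)\,e^{-(t/\tau)^k},$$

because its three parameters capture the qualitatively different shapes
seen in this kind of data: fast near-exponential death (cysts in dry
frost: $\tau$ of a day or two), slow stretched-exponential decline
($k < 1$, typical spore curves), and long-lived resistant fractions
($s_\infty > 0$, hardy spores in dry frost).  Plaque counts are binomial
draws with the number of plated cells as size, so replicate noise scales
correctly with aliquot volume.

Default parameters per taxon group × form × condition encode the
qualitative structure of the study system, chosen once: spores and cysts
comparable at 22&nbsp;°C; spores best just above and below freezing;
group 4 spores with the largest frost $\tau$ and a dry-frost plateau,
group 2 second, groups 1 and 3 lowest; cysts dead within days of dry
frost.  At 22&nbsp;°C and 4&nbsp;°C the groups are deliberately
near-equivalent so that warm-storage survival carries no climate signal.
A per-species log-normal jitter on $\tau$ (sd 0.25, mean-preserving,
shared across conditions) provides realistic within-group variation.
When a climate roster is supplied, each species' frost $\tau$ is
additionally multiplied by $e^{0.35\,(r-3)}$ where $r$ is its coldest
climate rank — species from colder habitats are hardier in frost, which
is the coupling the climate–fitness correlation stage is designed to
detect.  Warm-storage parameters are untouched by this coupling.

What the generator does **not** emulate: plate-level overdispersion
(counts are exactly binomial), plating-efficiency drift between
timepoints, and any correlation between replicate aliquots.  Passing
tests therefore show that the pipeline recovers structure *of this kind
and strength* from binomial counting noise; they do not certify
performance on real plates, where extra-binomial variance would widen
every interval.

## Relative fitness

Survival fractions are `plaque_count / cells plated`; fractions above 1
(counting noise) are kept and flagged rather than clipped, since clipping
would bias the fitness statistic downward asymmetrically.  The
relative-fitness statistic normalizes every curve at each timepoint by
the mean survival of *all spore curves* — all species and all conditions
pooled — and averages the normalized values per species × form ×
condition over the six post-baseline timepoints (days 1–365).  Day 0 is
read as a plating-efficiency control and excluded; the choice is
configurable via the `timepoints` argument.  By construction, spore
values average to exactly 1 at each timepoint, a property the tests
assert to machine precision; cysts are normalized against the same spore
denominator, so cyst values are directly comparable to spore values.
The standard error uses the number of timepoints with a defined
normalized value (a timepoint whose spore denominator is zero is dropped
with a warning).

## Rank statistics

"ANOVA on ranks" is implemented as Kruskal–Wallis with tie-corrected
variance, with Dunn's test on the pooled tie-corrected ranks as the
pairwise follow-up; the pairwise matrix is reported raw by default (a
Holm adjustment is available) because the analysis convention here is to
show the raw P-matrix.  Average ranks are used everywhere ties occur.
Exact small-sample options are built in — full permutation enumeration
for Kruskal–Wallis ($N \le 10$), Mann–Whitney ($n_a + n_b \le 12$) and
Spearman ($n \le 8$) — and the test suite holds every statistic against
brute-force oracles and against base R's independent implementations.
For two pools, the Dunn z and the Mann–Whitney z are algebraically
identical; the tests verify the two code paths agree to within the
continuity correction.  The group-versus-rest contrasts of ultrastructure
features use two-sided Mann–Whitney at $\alpha = 0.05$, the simplest
reading of "significantly higher or lower than the others".  The
significance threshold is configurable; 0.05 is the default throughout.

Degenerate inputs are signalled, not silently numberized: a constant
vector makes a correlation *undefined* (`undefined = TRUE`, `NA`
estimates), and fully tied group data make the rank test *degenerate*
(the tie-correction factor reaches 0).

## Morphometry

Twenty per-species features summarize the per-cell TEM measurements:
wall widths (total plus up to three layers — spore walls have three,
cyst walls at most two), wall-layer electron density, cross-section
area, granule count / mean diameter / area fraction, vesicle count /
total area / area fraction, three mitochondrion-feature fractions,
polar-granule and heterochromatin fractions, and the cell aspect ratio.
Granules are treated as circular in cross-section, so their combined
area is $\sum \pi d_i^2/4$ over measured diameters; area fractions
divide by the wall-exclusive cross-section area and are capped at 1 with
a warning if measurement inconsistency pushes them over.  Measurements
averaged at several positions per cell are averaged position → cell →
species, so layer means stack exactly to the mean total width.

In the generator, qualitative per-cell flags are represented as per-cell
*fractions* (beta-distributed) rather than 0/1 indicators, so that the
degenerate no-noise limit (dispersion 0) collapses every feature to its
group mean — a property the tests use.  The correlation of features with
fitness defaults to Spearman (consistent with the climate analysis and
robust across the mixed feature scales); Pearson is available.  Whether
a species' features are matched to the fitness of the same dormant form,
to spore fitness only, or to a per-species pooled fitness is an explicit
`fitness_form` option, since all three readings are defensible.

## Ecology

Climate zones are ranked 1–5 from tropical to arctic/alpine; a species
isolated from a range of zones is reduced to its coldest (maximum) and
warmest (minimum) rank.  The percentage matrix of coldest isolation
climates rounds half away from zero, which is why a 27-species row with
counts 5/4/14/1/3 prints as 19/15/52/4/11 and sums to 101.  The default
85-species roster fixes group 4 at 27 species; the remaining 58 are
split 17/27/13/1 across groups 1, 2, 3 and the minor lineages — the only
integer split whose zone counts reproduce every printed percentage —
with per-group zone probabilities equal to those back-solved counts.
The climate–fitness correlation uses spore fitness only.

## The dating engine

The model is a relaxed clock on a fixed rooted binary topology with ages
in units of 100&nbsp;My (leaves at 0):

* **Rates.** Independent log-normal branch rates with the
  mean-preserving parameterization $\log r_b \sim \mathcal N(\log\mu -
  \sigma^2/2,\ \sigma^2)$, so $\mathbb E[r_b] = \mu$ for every
  rate-variance $\sigma^2$.  Hyperpriors $\mu \sim \Gamma(2, 20)$ and
  $\sigma^2 \sim \Gamma(1, 10)$, both read as shape/rate (prior mean
  rate 0.1 substitutions·site⁻¹ per 100&nbsp;My); the shape/scale
  reading of the same numbers would put the prior mean at 40, which is
  not a plausible rate, so shape/rate is the default and the
  parameterization is configurable.
* **Calibrations.** Soft-bound uniforms: mass $1 - 2\cdot 0.025$ flat
  between $t_{\min}$ and $t_{\max}$ and exactly 2.5% beyond each bound.
  The lower tail is a power decay $h\,(t/t_{\min})^p$ on $(0, t_{\min}]$
  and the upper an exponential $h\,e^{-\lambda (t - t_{\max})}$, both
  matched for continuity at the bound and scaled to exactly the nominal
  tail mass.  This pair was chosen over two exponential tails because
  both tails then have closed-form CDFs and quantiles, which makes
  inverse-CDF sampling and the prior-reproduction tests exact.  A bound
  too close to zero to carry its tail mass is rejected with an error.
* **Node-age prior.** Uncalibrated internal nodes get a recursive
  conditional-uniform prior: each non-root node age is uniform on
  $(0, t_{\mathrm{parent}})$, i.e. joint density $\prod_v
  1/t_{\mathrm{parent}(v)}$ on the ordered region.  This replaces a
  birth–death kernel, acceptable at desk scale where calibrations
  dominate.  Its key property: the marginal prior of a calibrated root
  is the calibration density *exactly*, and the prior is exactly
  samplable — which turns prior-reproduction and coverage checks into
  sharp tests rather than approximations.
* **Likelihood.** Independent Gaussian approximation on branch-length
  estimates, $\hat b_b \sim \mathcal N(r_b \Delta_b, v_b)$ with the
  estimates' variances supplied as data (diagonal covariance; a
  full-covariance extension would slot in at the same interface).
* **Sampler.** Metropolis-within-Gibbs: sliding-window proposals on node
  ages (rejections enforce parent > child), log-scale multiplier
  proposals on rates, $\mu$ and $\sigma^2$, and two likelihood-invariant
  mixing moves — a joint scale move (all ages × $c$, all rates and $\mu$
  ÷ $c$) for the global rate–time ridge, and a compensated age move that
  slides one node while rescaling its adjacent branch rates to keep
  expected branch lengths fixed.  Without the mixing moves the
  single-site updates stall on the ridges this model is famous for; with
  them, per-node effective sample sizes on an 8-tip problem rise from
  tens to the thousands at the same iteration count.  Step sizes
  auto-tune during burn-in toward 20–40% acceptance, then freeze.  The
  root must carry a calibration; a run without an age ceiling is refused
  as unidentifiable.  A strict-clock mode (`fix_sigma2 = TRUE`) ties all
  rates to $\mu$.
* **Summaries.** Chains (two by default, seeds derived from the master
  seed) are pooled for posterior mean ages and highest-posterior-density
  intervals — the narrowest contiguous window containing 95% of the
  sorted samples, ties broken toward the smaller lower bound.
  Convergence compares per-chain posterior mean ages; the default
  verdict requires agreement within 2% of the root calibration's core
  width.  The annotated chronogram serializes to Newick with
  `label|mean|lower|upper` node labels and round-trips through the
  reader.

### Validation design and problem sizes

Three checks validate the engine, all desk-scale by design:

1. **Prior reproduction.** With no data and a single calibrated root,
   the sampled root-age marginal must match the analytic calibration
   density (Kolmogorov–Smirnov distance below 0.05, tail fractions near
   2.5%).  We use a 3-tip tree and 5&nbsp;000 thinned samples.
2. **HPD coverage.** Truth is drawn from the model's own prior (root age
   from the calibration by inverse CDF, hyperparameters from their
   gamma priors, ages and rates from the generator), data are simulated,
   and the engine's 95% HPD for the root age must cover the truth about
   95% of the time.  We run 200 replicates of 6-tip trees with
   observation variance $10^{-4}$ and 2&nbsp;000 thinned (about
   1&nbsp;400 effective) samples per fit.  Noise is drawn *untruncated*
   here: the coverage argument is exact only when data come from the
   model the sampler assumes, and the default truncation of negative
   branch-length estimates at 0 is a (small, documented) mismatch that
   would otherwise be confounded with sampler error.  Two findings from
   building this check are recorded deliberately.  First, the
   narrowest-window HPD estimator is intrinsically anticonservative on
   the flat-topped posteriors this model produces — near-tied candidate
   windows make the minimum-width selection biased short by roughly one
   coverage point even for thousands of *independent* samples — so the
   measured coverage concentrates around 93–94% rather than 95%;
   simulation-based-calibration ranks of the same fits are uniform with
   nominal 2.5% tail rates, locating the bias in the interval estimator,
   not the sampler.  Second, the likelihood-invariant mixing moves are
   what make adequate effective sample sizes attainable at all on the
   rate–time ridges.
3. **Strict-clock recovery.** On noise-free strict-clock data with a
   soft root bracket spanning ±20% of the truth, the posterior mean root
   age must land within 10% of the truth (10 tips; the rate–time ridge
   makes this a joint test of the likelihood, the scale move and the
   calibration).

Reproducing any headline divergence date from the original 85-taxon,
240-protein analysis is out of scope by design; the engine is built for
correctness at small size, not throughput at genomic scale.

## Known limitations

* The synthetic survival model is calibrated to qualitative orderings
  only; absolute fitness values have no empirical meaning.
* The Gaussian branch-length likelihood ignores covariance between
  branch estimates; real pipelines estimate those jointly.
* The conditional-uniform node-age prior is not exchangeable across
  topologies the way a birth–death prior is; with sparse calibrations
  and many uncalibrated nodes it pulls ages toward the recent.
* Single-partition, fixed-topology, no fossil-calibration curation:
  calibration tables are consumed as given.
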