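---
title: "Methods: cross-species ageing course analysis with agecourse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species ageing course analysis with agecourse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agecourse)
```

`agecourse` analyses three-species, three-age bulk RNA-seq screens for
conserved age-regulated genes. This vignette describes the statistical
models, the tunable parameters, the synthetic-data generator, and the
design decisions that were genuinely open.

## Count model and the consensus differential-expression rule

Counts for gene *g* in sample *j* are modelled as negative binomial with
mean `mu_g * s_j` and variance `mu + phi * mu^2`, where `s_j` is a
median-of-ratios size factor (geometric-mean pseudo-reference over genes
positive in all samples, factors rescaled to geometric mean 1). Dispersion
`phi_g` is estimated by method of moments on normalized counts, pooling
within-group residual variance across age groups, then shrunk halfway
toward a lowess mean–dispersion trend (the median of raw estimates when
fewer than 50 genes are available) and floored at `1e-8`. The halfway
shrinkage weight is conventional; it trades a little bias for a large
variance reduction at 2–6 replicates and is exposed through the estimates
returned by `estimate_dispersion()`.

Three tests feed the consensus rule:

* **Exact conditional test** (`pairwise_test_A`). Group totals of
  normalized counts are conditioned on their sum. Because both group sums
  share the NB probability parameter `1 / (1 + phi * mu)` under the null,
  the conditional split distribution is free of `mu`; the two-sided
  p-value sums the probabilities of all splits at most as probable as the
  one observed (ties included with a `1 + 1e-8` relative tolerance). At
  `phi = 0` this reduces to the exact binomial split test. Normalized
  totals are rounded to integers; with equal size factors this is exact.
* **Wald test** (`pairwise_test_B`). The log2 fold change of normalized
  group means (pseudocount 0.5, so zero counts stay finite) with a
  delta-method standard error from the NB variance function.
* **Omnibus LRT** (`omnibus_test`). Group-specific versus common NB means
  at fixed `phi`, chi-square with `groups − 1` degrees of freedom. Group
  means are quasi-likelihood estimates `sum(counts) / sum(size factors)`.

A gene is a DEG iff both pairwise tests agree at FDR `alpha` (default
0.05) on at least one of the three ordered age contrasts, or the omnibus
test passes FDR `alpha`. BH adjustment is applied within each
(test, contrast) family, mirroring per-tool, per-comparison adjustment;
a global adjustment would couple the three families and change what
"agreement" means. The regulation direction comes from the first-vs-last
age contrast when both pairwise tests call it; otherwise the gene is
`mixed`. Simulated null calibration (1,200 genes, `phi = 0.1`, 6
replicates per group) puts all three tests' type-I error at `alpha = 0.05`
between 0.05 and 0.07 — slightly liberal, as expected for plug-in
dispersions, and well inside the accepted 0.03–0.08 band.

## Rescaling, combined clustering, and the validity vote

Species differ in lifespan, so chronological ages are mapped linearly to
the unit interval per species. With three ages per species the pooled
profile matrix is aligned on age rank over the common grid {0, ½, 1};
`rescale_timepoints()` also returns the per-species rescaled positions for
designs where the actual time values matter.

Each DEG that belongs to an ortholog group represented in every species
contributes one row: the per-age mean of `log(normalized count + 1)`,
z-scored. Two points deserve emphasis. First, z-scoring is what turns the
clustering into a *shape* (course) clustering — unscaled expression would
cluster by magnitude. Second, depth is normalized by median-of-ratios
size factors rather than by total mapped reads: age-regulated genes shift
the total count of a library (composition bias), and a total-count
denominator visibly tilts centroid courses; under per-row z-scoring the
gene length cancels anyway, so this choice differs from RPKM only in the
depth estimator while being robust to composition. `compute_rpkm()` is
still provided for expression reporting.

Fuzzy c-means uses the standard alternating updates with Euclidean
distance, membership exponent `m = 2`, convergence when the largest
centroid shift drops below `1e-6` (at most 300 sweeps). Memberships are
computed in log space so that small `m` (crisp limit) does not underflow;
rows coincident with centroids get membership 1 split equally across the
coincident centroids; initial centroids are `c` distinct data rows, and
`n_restarts` (default 10 in the vote) controls the usual local-optimum
sensitivity — restarts dominate initialization quality in our tests.

The number of clusters is the modal vote of five validity indices —
partition coefficient (max), partition entropy (min), Xie–Beni (min),
Fukuyama–Sugeno (min), fuzzy silhouette (max) — each evaluated on the
best-of-restarts fit per candidate `c` in 2–12, ties broken toward the
smaller `c`. The five were chosen to cover fuzziness (PC, PE), the
compactness/separation ratio (XB), scatter against the grand mean (FS)
and point-level separation (silhouette); PC/PE and FS individually carry
known monotone biases toward extreme `c`, which is exactly why a vote
rather than any single index decides.

Centroids are labelled `up` when strictly increasing over consecutive
time points, `down` when strictly decreasing, `other` otherwise. Hard
assignment by maximum membership (ties to the lowest cluster index,
reported) defines each species' up and down gene sets; an ortholog group
is conserved-up when every species has at least one member gene in its up
set, groups qualifying in both directions are excluded as conflicting.
Ortholog groups, not genes, are the unit of conservation, and a strict
one-to-one mode is available via `one_to_one()` because real orthology
relations are many-to-many.

## Set statistics

`montecarlo_intersection()` draws, per iteration, uniform subsets of the
measured universe with the observed set sizes and records the
intersection; significance uses the strict nearest-rank `mc_quantile`
rule (default 0.95 over 1,000 iterations) and the empirical p-value uses
the plus-one convention `(1 + #{draws ≥ observed}) / (iterations + 1)`,
which can never return zero. One degenerate corner is worth noting: when
both sets equal the universe every null draw ties the observed value, so
the strict rule cannot fire and `p_emp = 1` — the correct reading of the
contract, exercised in the tests with half-universe sets where maximal
overlap genuinely is significant.

Pathway enrichment is at the reaction level: a reaction is dysregulated
if any catalysing enzyme is a DEG; each pathway is scored by the
hypergeometric upper tail `P(X ≥ k)` (observed included) with the loaded
network's reactions as the population, then BH across pathways. The
population default — all reactions in the network — is the conservative
reading when the true universe of mapped reactions is unknown.

## Promoter scanning

Matrices are parsed from JASPAR or TRANSFAC count formats; frequencies
add a total pseudocount of 1 spread evenly over the four bases, and
log2-odds weights are taken against an order-0 background (estimated from
the scanned sequence with Laplace smoothing unless supplied). Scores are
discretized to `bin_width = 0.01` log2-odds units and the exact
distribution of a background word's score is built by position-wise
convolution; per-site p-values are upper tails of that distribution, so
their error is bounded by one bin's mass (halving the bin width is tested
to move no p-value by more). Both strands are scanned by default and
windows containing `N` are skipped. The per-factor aggregate "binding
probability" is a binomial upper tail over the number of scanned windows
at the site threshold (default `1e-4`); this is a declared stand-in for
aggregate scores whose published construction is unspecified, and factors
are ranked by site count first, aggregate p second.

## Lifespan statistics

Kaplan–Meier estimation and the two-group log-rank test stand on the
`survival` package behind `kaplan_meier()` and `logrank_test()`. Mean
lifespan is the restricted mean (area under the KM curve up to the last
observed time; equal to the plain mean when uncensored), median is the
first time survival reaches 0.5, and "maximum lifespan" — never formally
defined in screen reports — is the mean of the longest-lived decile of
deaths (fraction configurable). Effects are categorized as Unchanged when
the log-rank p ≥ α, otherwise Shortened (negative mean change),
Extended≥5 %, or Extended<5 %. Replicate plates are pooled; stratification
is deliberately out of scope. The packaged 41-gene screen table is the
worked example for `screen_summary()`.

## What the synthetic-data generator emulates — and what it does not

`generate_species_counts()` reproduces the statistical skeleton of the
real design: three species × three ages with species-specific age values
(worm days 1/10/20; fish months 5/24/42; mouse months 2/15/30), NB counts
with configurable `phi` (default 0.1), log-normal baselines
(`meanlog = log(100)`, `sdlog = 1`), log-normal library-size factors
(sd 0.2, mimicking a several-fold read-depth spread), a one-to-one
orthology, and planted course classes: a `frac_conserved` (default 0.1)
fraction of ortholog groups shares one of six canonical courses across
all species, the rest draw per-species classes independently with a
`frac_flat = 0.3` chance of no age effect so false-positive rates are
measurable.

The six canonical courses are fixed piecewise-linear templates over
{0, ½, 1} in log2 units scaled by `amplitude` (default 2, i.e. four-fold):
steep = concave early change `(0, 0.85, 1)`, shallow = convex late change
`(0, 0.15, 1)`, their mirrored down versions, and transient up-down /
down-up `(0, ±0.7, 0)`. Because profiles are z-scored, amplitude cannot
distinguish classes; the middle values were fixed so that every monotone
class keeps a non-negligible increment on both segments (so fitted
centroids stay strictly monotone under noise) while the six z-scored
shapes stay angularly separated (roughly 44–68° apart on the mean-zero
sphere). `simulate_course_profiles()` draws z-scored profiles from the
same templates directly (noise sd 0.2, amplitude default 2 to match the
count generator's signal-to-noise) for exercising the clustering stage in
isolation; at these settings the validity vote selects six clusters
unanimously.

Not emulated: batch effects, splice isoforms, read-level artefacts,
gene–gene correlation, many-to-many orthology, and informative censoring.
Passing the planted-recovery suites therefore demonstrates that the
pipeline recovers the structure it models, not that real data meet these
assumptions — in particular, real cross-species courses are noisier and
less balanced than six equal-sized planted classes.

`generate_survival()` draws Weibull event times (scale 20 days, shape 4 —
a realistic nematode lifespan curve) with the treatment hazard multiplied
by `hazard_ratio`; censoring is uniform on `(0, death time)` for a random
`censor_frac` of individuals, approximating roughly uninformative
walk-off/internal-hatching losses. Times are kept continuous so
closed-form checks (e.g. median `scale * log(2)^(1/shape)`) are exact;
day-rounding is a presentation concern, not a modelling one.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 1,000 genes × 3 species
(9 samples each) for end-to-end recovery with `amplitude = 3` — the
"strong course" condition under which ≥ 90 % DEG sensitivity and ≥ 80 %
conserved-group recovery are meaningful targets; 600 rows per species for
the cluster-number vote; 1,200 genes for test calibration; 500 × 200
iterations for overlap-test calibration; 1,000 replicates for log-rank
calibration. These sizes give binomial standard errors a few times
smaller than the accepted calibration bands. All generators are pure
functions of their parameters and a seed; every stochastic stage threads
a single integer seed.

Degenerate inputs are handled explicitly: all-zero genes are excluded
from testing (p = 1 by convention for zero totals), constant profile rows
are dropped with a count, groups without deaths yield a warning and a
unit survival curve, and empty orthologies or gene sets flow through as
empty results rather than errors.

## Known limitations

* The three NB tests are stand-ins preserving the consensus structure of
  published multi-tool pipelines, not reimplementations of any specific
  tool; absolute DEG lists will differ from any particular toolchain even
  on identical data.
* The exact conditional test treats normalized totals as NB sums, which
  is approximate under strongly unequal size factors.
* The omnibus LRT is slightly liberal at 2–3 replicates; with ≥ 4
  replicates per group its type-I error sits within 0.05–0.07.
* Fuzzy c-means with three time points cannot distinguish more course
  shapes than the mean-zero sphere admits; with longer designs the same
  code applies unchanged but the validity vote should be re-examined.
* The aggregate promoter-binding p-value is a binomial tail over windows;
  it ignores overlap dependence between windows and is intended for
  ranking, not for calibrated inference.
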