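---
title: "Modelling invasive plant expansion potential across ecoregions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling invasive plant expansion potential across ecoregions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`ipsexp` implements a complete presence-background species distribution
modelling (SDM) pipeline for assessing where invasive plant species (IPS)
could expand under climate-change scenarios, aggregated to ecoregions. The
chain is:

1. occurrence-record quality control and a minimum-record species filter;
2. collinearity screening of a nine-variable bioclimatic stack;
3. per-species maximum-entropy suitability models (hinge features, L1
   regularisation, 10-fold cross-validation) with logistic output;
4. AUC + six-threshold omission-rate evaluation and a retention rule;
5. multi-species suitability change aggregated zonally to ecoregions, with
   biome and growth-form rollups and a cross-scenario regression;
6. climate-feature attribution: jackknife variable importance, per-ecoregion
   climate change, per-biome regressions and summaries.

Because real inputs (occurrence aggregators, global climatologies, ecoregion
shapefiles) are large external downloads, the package ships a first-class
synthetic-world generator with analytic ground truth, so every stage is
testable end to end offline.

## The suitability model

For one species, let `f_1 … f_p` be bounded features of the climate at a
location. The model is the Gibbs (maximum-entropy) density over the
landscape,

    q(x) = exp( sum_j lambda_j f_j(x) ) / Z,

with `Z` normalised over a background sample of up to 10,000 pixels. The
weights minimise the penalised negative mean log-likelihood of the `m`
presences,

    -mean_i [ lambda . f(x_i) ] + log Z + sum_j beta * s_j / sqrt(m) * |lambda_j|,

where `s_j` is the feature's standard deviation over the presences and
`beta = 1.5` is the regularisation multiplier. This is the documented
maximum-entropy SDM formulation; it is re-implemented here as a convex
optimisation problem rather than wrapped from the reference Java tool, so
that it is fully testable and has no external runtime.

**Features.** Each climate variable contributes a min-max-scaled linear term
plus left and right hinges `max(0, (x-k)/(max-k))` and
`max(0, (k-x)/(k-min))` at 20 quantile knots (configurable). Hinge features
subsume linear and threshold features and give smooth, monotone-flexible
response curves. Knots at empirical quantiles make all downstream results
invariant to affine rescaling of any input variable.

**Output scales.** *Raw* is `q` itself, normalised over the training
background (raw values over the background sum to 1 — an invariant the tests
assert to 1e-9). *Cumulative* is `100 *` the total raw mass of background
points scoring at or below the focal value. *Logistic* is
`e^H q / (1 + e^H q)` with `H` the entropy of the fitted `q`: the
entropy-calibrated transform in (0, 1) used as the suitability index.
Projection onto new climate clamps each variable to its training range
(no extrapolation of hinge ramps); the normaliser and the cumulative
reference distribution remain those of the training background.

**Solver.** A monotone accelerated proximal-gradient method (FISTA with a
backtracking line search and a monotone safeguard that falls back to a plain
proximal step whenever the accelerated candidate would increase the
objective). The objective trace is therefore non-increasing, which the tests
assert. Convergence is declared when the KKT optimality measure (max-norm of
the projected subgradient) falls below `tol` (default 1e-4); hitting
`max_iter` first is an error that reports the final optimality measure.
Two numerical safeguards: the penalty scale `s_j` is floored at 0.05 so that
features nearly constant over the presences cannot become effectively
unpenalised (quasi-separable fits would otherwise diverge — the same role as
the minimum regularisation built into reference implementations), and
log-sum-exp is computed with the usual max-shift.

**Cross-validation.** Presences are partitioned into k = 10 folds (balanced,
seeded); each fold model trains on the other nine against a shared
background sample, and the species' suitability map is the per-pixel mean of
the fold models' logistic maps ("average of the replicates"). Whether the
final map should instead come from a single refit on all data is not
determined by the source methodology; the mean over folds was chosen as the
literal reading of averaging replicate outputs.

## Evaluation and retention

AUC is the rank-based probability that a random presence outranks a random
background point (ties half), computed per fold on the held-out presences
against the background — a presence-background AUC, as is standard for this
model family. Training omission is the fraction of training presences
scoring strictly below a threshold; six thresholds are derived per fold
(fixed cumulative 5 and 10, equal training sensitivity/specificity, maximal
training and test sensitivity+specificity, and the equal-entropy rule that
keeps the `round(e^H)` highest-scoring background points above threshold).
The per-fold omission is the mean over the six rules, then averaged over
folds; a species is retained iff mean AUC > 0.7 **and** mean omission
< 0.017. The 0.017 bound is treated as a plain configuration constant; its
provenance is not documented in the source methodology.

The omission bound is strict: it is only attainable in the regime the source
analysis describes — species whose occupied range is small relative to the
background extent, giving near-perfect presence/background separation (AUC
approaching 1). The synthetic defaults are chosen to reproduce exactly that
regime (below).

## Expansion potential

With `P_ij` the logistic suitability of retained species `i` in pixel `j`,

    E_j = sum_i P_ij            (multi-species suitability, 0 <= E_j <= k)
    A_j = E_j^future - E_j^current

and an ecoregion's expansion potential is the unweighted sum of `A_j` over
its pixels. Ecoregions are *included* only when the potential is strictly
positive (a potential of exactly zero is excluded, matching the "over 0"
inclusion phrasing). Excluded ecoregions stay in the tables with
`included = FALSE`. Pixel sums are deliberately unweighted (no cos-latitude
area correction), matching the source's direct summation; linearity in
species means growth-form-restricted maps sum exactly to the all-species
map, which the tests assert. Species dropped by the retention rule never
enter `E_j`.

Both forcing pathways (moderate, RCP4.5-like, and high, RCP8.5-like) are
computed; the cross-scenario OLS of high-forcing on moderate-forcing
potentials (paired by ecoregion) reports slope, R² and the two-sided slope
test.

## Climate-feature attribution

Variable importance is defined from the jackknife: refit without each
variable and record the drop in (unregularised) training gain,
`max(0, G_full - G_-v)`, normalised to percent contributions summing to 100;
"with-only" gains are reported alongside for transparency. The source
conflates "percent contribution" and "jackknife test" in its figure caption;
the gain-drop definition was chosen because it is the quantity the jackknife
actually measures. When no variable produces a positive drop (fully
redundant sets) the contribution falls back to an equal split, flagged by
the all-equal pattern.

The change of an important variable in ecoregion `n` is
`CV_n = V_n^f - V_n^c`, the difference of unweighted zonal means, with the
future value taken from the GCM ensemble mean (consistent with averaging
model inputs, not outputs). Per-biome OLS of potential on `CV_n` runs per
variable and per pathway at the ecoregion level (the source's phrasing
supports ecoregion-level pairs); biomes with fewer than three usable
ecoregions or zero CV variance are flagged, never silently dropped, and no
multiple-testing correction is applied because the source applies none.
Per-biome mean and sample SD of `CV_n` are computed over included
ecoregions only; fewer than two members gives an undefined SD.

## Occurrence QC

Rules run in a fixed order so multiply-flagged records are tallied once:
invalid species name (a binomial-name regex stands in for interactive
registry checking and is pluggable), invalid coordinates (an artifact
addition, tallied separately), both coordinates exactly zero, longitude
equal to latitude (all exact-equality pairs, including negative ones), and
within-cell duplicates at the working grid resolution (first record in input
order wins; cell assignment is `floor((coord - origin)/cell_size)`). The
species filter keeps a species iff it has strictly more than 100 cleaned
records; the strict reading of "over 100" is the default and a flag flips it,
since the headline species count cannot disambiguate the two readings.
Cleaning is idempotent and per-rule counts are permutation-stable (the
retained duplicate representative is the only order-dependent detail, and it
is documented).

## Collinearity screening

Pairwise Pearson correlations are computed over the usable pixels of the
*current* stack only (the screen runs once and the variable set is reused
for futures). The elimination rule is not specified by the source beyond the
|r| <= 0.85 bound; the package uses the standard greedy heuristic — while
any pair exceeds the bound, drop the member of the worst pair with the
larger mean absolute correlation against the remaining variables, breaking
ties toward keeping the variable earlier in canonical table order. The
retained set provably satisfies the pairwise bound and the procedure is
deterministic.

## The synthetic world

What it emulates: spatially autocorrelated climate fields (Gaussian-smoothed
white noise, configurable correlation scale, default 4 pixels) on plausible
scales and units for the nine bioclimatic variables; a warming gradient
toward low absolute latitude for the temperature variables and an opposite
gradient for temperature seasonality; physically consistent per-pixel
ordering Bio6 <= Bio1 <= Bio5 (enforced by sorting, on by default); additive
late-century anomalies per climate model with a high-forcing pathway as a
scaled version of the moderate one; contiguous ecoregions from seeded
breadth-first growth, labelled with the standard 16 terrestrial / 12
freshwater biome codes; species with axis-aligned Gaussian niches (the
simplest smooth unimodal response, with analytic ground truth); and
occurrence sampling proportional to true occupancy with the four
contamination classes injected in known numbers.

Key defaults and why:

* **Grid 60 x 90 cells of 1/6 degree** (10 arc-minutes, the source's working
  resolution) — large enough that a species' core range is a small fraction
  of the landscape.
* **Niche breadth 0.1 x landscape SD per driver variable** (drivers
  Bio1, Bio4, Bio12 by default). This makes species compact relative to the
  background — the regime the source analysis itself reports (it attributes
  its high AUCs to backgrounds much larger than any species' range). Broader
  niches (≥ 0.3 SD) produce mean omission rates of 0.03–0.07, which the
  0.017 retention bound rightly rejects; this is a property of the bound,
  not of the implementation.
* **Occurrence sampling**: by default clean records occupy distinct cells
  (so cleaning-stage removal counts equal the injected contamination
  exactly and the post-QC count is controllable for the over-100 filter);
  a with-replacement mode implements the literal proportional-sampling law
  and is the one used for the goodness-of-fit property test.
* **Scenario deltas**: mean warming 2.2 °C with smooth spatial variation
  (SD 0.6 °C), seasonality shift +180 (SD x 100 units), zero-mean
  precipitation anomaly (SD 60 mm) — mid-range late-century anomalies; the
  high-forcing pathway doubles the moderate one by default.

What it does **not** emulate: real climatological structure (no seasonal
physics, no orography), real ecoregion geometry, land/ocean masks beyond an
optional nodata mask, spatial sampling bias other than the injected
contaminant classes, and any dispersal or biotic process. A green test
therefore establishes that the pipeline's statistics do what they claim on
a world obeying the model's assumptions — not that the ecological
conclusions transfer to real data.

Randomness contract: one global seed fans out to per-component child seeds
by fixed offsets (`seed + 9973 * offset`, reduced below 2^31), so any module
can be re-run in isolation; fixed seeds give bit-identical worlds via R's
default Mersenne-Twister stream, and generators restore the caller's RNG
state.

## Numerical and design choices

* Normalisation of the raw density is over the background only; presences
  enter the likelihood but not the partition function. Implementations
  differ on this point, hence it is stated explicitly and asserted in tests.
* Ties in the threshold search are broken toward the smaller threshold;
  omission uses strict inequality (ties count as predicted present).
* The freshwater and terrestrial realms are generated and aggregated as
  independent label rasters; the source does not document how overlapping
  realms were rasterised against each other.
* Regression of potential on climate change uses all ecoregions with a
  defined potential by default (an `included_only` flag restricts it),
  while the per-biome mean/SD summaries are restricted to included
  ecoregions, as stated by the source.
* Grids are serialised as plain-text long-format CSV plus a JSON grid
  descriptor rather than GeoTIFF: no binary raster driver is assumed in the
  runtime environment. The interface contract (named co-registered bands)
  is unchanged.
* The pipeline config is JSON rather than YAML, for the same
  dependency-availability reason.

## Acceptance-test scaling

The acceptance suite (tests/testthat/test-acceptance.R) runs the stochastic
criteria at sizes chosen once for a single CPU: the niche-recovery criterion
uses the full canonical settings (500 presences, 10,000 background, k = 10,
beta 1.5) on a 110 x 110 grid; the directional-recovery and driver-recovery
criteria run 20 seeded replicates of reduced worlds (30 x 45 grid, k = 3,
~1,000 background, 6–8 knots) whose per-replicate behaviour matches the
full-size pipeline qualitatively. Reported bounds (Spearman >= 0.8, >= 18/20
and >= 19/20 replicate successes, coverage >= 0.93) are asserted at those
sizes.

## Known limitations

Only hinge features are implemented (no product/threshold/categorical
features); no MESS/novel-climate diagnostics; no spatially blocked
cross-validation; no area weighting in zonal sums; no spatial
autocorrelation correction in the per-biome regressions; the bias-aware
background sampler has no principled default bandwidth (the source states
the idea but no parameter — the bandwidth is exposed as configuration and
the uniform limit is the default).
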