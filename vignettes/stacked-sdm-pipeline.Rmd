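---
title: "Methods: stacked species-distribution models, range shifts, and protected-area prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked species-distribution models, range shifts, and protected-area prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stacksdm)
```

This vignette is the package's own account of its models, defaults, and
design choices: what each stage assumes, which tunables matter, what
the synthetic world does and does not emulate, and where the design was
genuinely open.

## 1. The modeling chain and its assumptions

`stacksdm` treats conservation prioritization as a chain of
well-defined operations on one planar grid: clean and thin occurrences,
screen covariates, fit one presence–background niche model per species,
evaluate it by spatial-fold-free random k-fold cross-validation,
binarize at the TSS-maximizing threshold, project to a future climate,
flag extrapolation, restrict to occurrence-supported patches, stack
into richness, and cross richness change with vegetation change inside
protected areas.

The chain carries the standard assumptions of climate-only niche
modeling: biotic interactions are ignored (an Eltonian-noise view
appropriate at large extents), presence records are informative about
suitability up to sampling bias, the background sample characterizes
available environments within a dispersal-limited accessible area, and
a species' fitted climate–suitability relationship is transferable to
the projected climate wherever the projection is environmentally
analogous to calibration (hence the MOP companion analysis).

## 2. The Maxent estimator

The fit is the penalized-likelihood form of Maxent: an
infinitely-weighted logistic lasso, solved by `glmnet` over a feature
expansion built in-package.

**Features.** Five classes over the covariates: linear, quadratic, all
pairwise products, step functions ("threshold") at `n_knots` equally
spaced knots, and forward plus reverse hinges at the same knots. Every
feature is min–max scaled to $[0,1]$ using the training bounds (the
min/max over presence and background points), which makes the fit
invariant to affine rescaling of any covariate — verified to $10^{-8}$
in the tests.

**Weights and data layout.** Presences are added to the background
(the usual convention), presences carry weight 1 and background weight
100; as the weight ratio grows the logistic fit converges to the
Maxent density estimate.

**Regularization.** Each feature's L1 penalty is the published
sample-size-dependent class default (interpolated in the number of
presences), scaled by the feature's presence-sample standard deviation
and divided by $\sqrt{n_p}$, floored at 0.1% of the feature's range;
`regularization_multiplier = 1` reproduces the defaults. With all
penalties zero the fit falls back to an unpenalized weighted logistic
regression, which the tests check against an independent BFGS optimizer
to $10^{-4}$.

**Output scales.** The raw output is the background-normalized density
$e^{\beta^\top f(x) + \alpha}$; cloglog (the default, the modern Maxent
convention) is $1 - \exp(-e^{H + \eta})$ with $H$ the entropy of the
background distribution; logistic is $\mathrm{plogis}(H + \eta)$. The
output scale is configuration, not inference: maxTSS thresholds are
derived and applied on the same scale throughout, and every
rank-based quantity (AUC, Spearman recovery) is invariant to the
choice.

**Clamping.** Projection covariates are clamped to training bounds
before feature evaluation and affected cells recorded in the
prediction's `clamped` mask — complementing, not replacing, MOP.

**Tunables that matter.** `n_knots` (default 10) controls hinge/step
resolution: more knots give more flexible response curves at higher
variance; the demo pipeline uses 5 for speed. Background size (default
10,000 per species, the field convention) bounds the resolution of the
background distribution; the demo pipeline uses 2,000 on its 10,000-cell
grid, where background nearly saturates the accessible area.

## 3. Occurrence handling

Cleaning collapses exact-duplicate coordinates and drops points on
nodata, reporting counts by reason. Species with fewer than 10 records
are excluded (exactly 10 is retained). Thinning enforces a minimum
pairwise distance by randomized repeated removal — each attempt removes
the point with the most too-close neighbors (ties at random) until no
violation remains; the best of `reps = 100` attempts by retained count
wins, ties by attempt order. On small instances this matches the exact
maximum independent set (tested by enumeration for n ≤ 15). The
thinning distance itself is a per-species configuration parameter;
`suggest_thinning_distance()` offers a Moran's-I-correlogram-based
candidate (first distance bin where I of the presence indicator drops
below 0.1) but is never auto-applied, because a data-driven distance
silently changes the estimand.

Fold assignment is a random partition into k = 5 folds with sizes
differing by at most one, per species, seeded.

## 4. Evaluation and thresholding

Background points stand in for absences in the confusion-matrix
metrics — the standard, imperfect convention for presence-background
models; Jaccard and Sørensen are reported alongside Kappa/TSS precisely
because they are less distorted by the arbitrary background-to-presence
ratio (with a large background, false-positive counts depress Sørensen
even for good models, as visible in the demo output). AUC is the
rank-based concordance probability with ties counted ½. The maxTSS
threshold is chosen by exhaustive scan over the observed scores
(prediction = score ≥ threshold), lowest threshold on ties — finite,
deterministic, and identical to the brute-force oracle by construction.
Each fold derives its own threshold from its training scores applied to
held-out data; the threshold used downstream for binarization is the
full-data fit's maxTSS value.

## 5. Transfer, MOP, and OBR

Projection reuses the calibration threshold — re-deriving it on the
projection would leak scenario information into the cut. MOP
standardizes covariates by reference mean/SD and scores each projection
cell by its mean distance to the nearest 10% (configurable) of
reference points, linearly rescaled to a $[0,1]$ similarity; cells
outside any covariate's reference range are strict extrapolation and
forced to similarity 0. MOP is reported, not used to mask binary maps,
by default (masking is a configuration switch): the package treats
extrapolation risk as a diagnostic rather than silently altering range
estimates. The reference cloud is subsampled to at most 2,000 points
(seed-fixed) to bound the distance computation; on the grids used here
the induced similarity error is negligible relative to the rescaling.

OBR keeps a connected suitable patch (8-neighbor) only if it contains
an occurrence or lies within the cutoff distance of one, with cutoff =
the maximum nearest-neighbor distance among occurrences — the
occurrence-based-restriction definition of the a-posteriori method
family. The operator is contractive and idempotent (property-tested on
random maps). With fewer than two occurrences the cutoff is undefined
and the map passes through unchanged with a warning.

## 6. Richness, shifts, and prioritization

Richness is the per-cell sum of binary maps; richness change is
$\Delta S = S_{future} - S_{current}$, classified low risk
($\Delta S > 0$) or high risk ($\Delta S < 0$). Range shift is
$R = (A_{t1} - A_{t0}) / A_{t0} \times 100$; extinct ($A_{t1} = 0$)
species belong to the contracting group for group means (R = −100) and
are also counted separately, since "contracting" and "possibly extinct"
are overlapping facts about a cohort. Areas are reported both as cell
counts and in squared map units (cell_size²), mirroring km²-style
reporting while keeping the math cell-based.

The four-region classification crosses the sign of $\Delta S$ with
vegetation change (lost vs. kept-or-gained; never-vegetated cells are
outside the scheme). $\Delta S = 0$ cells are excluded by default
because the rule names only gains and losses; `zero_to = "low_risk"`
maps them to the gain side. Per protected area, every region whose
share of the PA's classified cells reaches `reporting_fraction = 0.25`
enters that PA's recommendation list — an explicit substitute for an
unstated per-PA assignment rule, and deliberately permissive so one PA
can carry both a restoration and a refugia recommendation. Aggregate
region shares are computed both area-based and PA-count-based, since
either reading of "percent of protected areas" is defensible. The
effectiveness test is a two-sample Kolmogorov–Smirnov on per-cell
richness inside versus outside PAs, with the asymptotic p-value (cell
values are integers, so ties are pervasive and exact p-values
unavailable; D itself is tie-exact and is what the tests verify).

## 7. The synthetic world

The generator emulates, with known ground truth: spatially
autocorrelated layers (Gaussian smoothing of white noise, scale
`autocorrelation_range = 4` cells); controlled inter-layer correlation;
role-specific marginals (temperature-like 5–30, precipitation-like
0–3000, via rank mapping); a contiguous "sea" nodata region of ≥ 5% of
cells; virtual species with linear/Gaussian/hinge responses; biased,
within-cell-jittered occurrence records; a warmed (+1.4 by default,
matching the magnitude of projected mid-century tropical warming) and
wetted (×1.1) future with smooth noise; clustered native-vegetation
loss (30% of vegetated cells by default); and protected areas grown as
disjoint patches to ~12% of land — the order of magnitude of real
terrestrial reserve coverage.

**Correlation imposition.** The smoothed fields are whitened
empirically over land cells and then colored with the matrix square
root of the target correlation. Imposing the correlation only in
expectation (mixing noise before smoothing) leaves sampling noise of
order one over the square root of the effective number of independent
patches — enough to push a nominally independent pair past |r| = 0.3 on
a 64×64 grid — whereas whitening makes the realized land-cell
correlations hit the target at any grid size. Rank mapping afterwards
perturbs Pearson correlations only slightly (a 0.95 target realizes
≈ 0.93).

**Occupancy.** True occupancy is the top `prevalence` fraction of land
cells by suitability, ties broken by cell order — a deterministic
thresholding that remains well-defined under tied suitability (e.g.
constant layers), where a quantile cut does not.

**What it does not emulate.** Real marginal climate distributions,
climate-model-specific spatial structure, elevation or coastline
physiography, taxonomic error, temporally varying sampling effort, or
vector protected-area boundaries. Passing tests therefore demonstrate
the correctness and calibration of the machinery — exact metrics,
parameter recovery, chance-level nulls, bookkeeping identities,
determinism — not predictive skill on real occurrence data, where bias
and non-analog structure are harsher.

## 8. The recovery and null benchmarks

The Gaussian-niche recovery experiment (500 presences, 10,000
background, six covariates, one driver) draws occurrences with
detection probability proportional to true suitability via the
generator's bias surface, at prevalence 0.5. Under uniform-over-occupancy
sampling the presence density is flat on the occupied set and a smooth
optimum is not identifiable from the data at all — suitability-
proportional detection is the standard virtual-species convention and
makes recovery a well-posed question. Recovery is scored by: Spearman ρ
between predicted and true suitability over land; the driver's rank in
permutation importance (training-AUC drop, averaged over permutations,
normalized to 100%); and the recovered optimum, estimated as the
expectation of the covariate under the fitted Maxent density along a
1-D profile (others at their land means). The profile expectation is
used instead of the profile argmax because hinge features produce
flat-topped piecewise-linear profiles on which an argmax wanders;
"within ±10% of truth" is read as 10% of the driver's training range,
the only scale-free reading.

The null benchmark scores 20 replicate "species" whose 200 presences
are uniform over land, by 5-fold cross-validated AUC with
linear+quadratic features; calibration requires the mean AUC in
[0.4, 0.6] for at least 90% of replicates.

## 9. Numerical choices and degenerate inputs

- Grid convention: north-up, row-major, cell-center coordinates,
  half-open cell intervals; one convention, used everywhere and tested
  in I/O round-trips (plain-text ASCII grids, so artifacts diff
  cleanly).
- Determinism: every stochastic operation takes a seed; the pipeline
  fans a master seed into per-stage, per-species child seeds by stable
  string hashing (all below 2³¹), so runs are bit-reproducible and
  stages independently replayable.
- Collinearity screening resolves pairs in descending |r| (the common
  reproducible convention; the elimination order is otherwise
  unstated), prefers earlier layers in an explicit `preference`
  ordering, drops zero-variance layers first with a warning, and
  subsamples at most 50,000 cells (seed-fixed) for the correlation
  estimate.
- Degenerate guards: empty cleaned occurrence sets return empty
  results with reason counts, not errors; all-identical scores yield a
  degenerate threshold with a warning; metrics with undefined
  denominators report NA rather than 0; a species with no current
  range reports status "not modeled" rather than a division by zero;
  excluding every covariate, empty KS samples, non-PSD correlation
  targets, and PA coverage > 0.9 are refused with diagnoses.
- Problem sizes: the bundled demo and benchmarks run on 100×100 (and
  smaller) grids with 2,000–10,000 background points — sizes chosen so
  a complete pipeline, its replicate benchmarks, and a full
  determinism re-run all execute comfortably on a single desktop core
  while leaving every statistical property testable.

## 10. Known limitations

- Background-as-absence evaluation inflates false positives; Sørensen
  and Jaccard values are comparable within this package's convention
  but not directly against studies using true absences.
- The penalized fit follows the published default-regularization
  tables; no model selection across feature classes is performed (by
  design, out of scope).
- MOP similarity is a linear rescaling of mean nearest-set distance;
  it orders cells correctly but its absolute values are not
  probabilities.
- Thinning is randomized-greedy; optimality is guaranteed only as
  observed on small instances (it matched exhaustive search in all
  tested cases), not in general.
- The land-use and protected-area generators produce plausible spatial
  patterning, not calibrated replicas of any real landscape; CLUE-s
  style land-use simulation is explicitly out of scope and projected
  vegetation maps are consumed as inputs.
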