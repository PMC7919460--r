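# stacksdm

Stacked species-distribution modeling with range-shift statistics and
protected-area prioritization, on a fully synthetic, ground-truthed
virtual-species world.

## The problem

Conservation planning under climate change routinely asks three linked
questions: where is each species' suitable habitat now, where will it be
under a future climate, and which protected areas should be prioritized
when projected biodiversity change is crossed with projected land-use
change? `stacksdm` implements this entire analysis chain for gridded
environmental covariates and presence-only occurrence records, for
ecologists and conservation analysts who want a reproducible,
desk-scale, fully testable version of the workflow:

1. **Occurrence preparation** — duplicate removal, a minimum-record
   filter (species with fewer than 10 records are excluded), spatial
   thinning to a minimum pairwise distance (randomized maximal
   retention, spThin-style), and random k-fold partitioning.
2. **Covariate preparation** — pairwise-correlation screening that drops
   one member of every pair with |r| > 0.7, a-priori layer exclusion,
   and simple-average ensembling of climate-model members.
3. **Niche modeling** — maximum-entropy (Maxent) presence-background
   models with linear, quadratic, product, threshold and hinge feature
   classes, class-specific default regularization, a dispersal-based
   accessible area ("M") delimiting background sampling, and cloglog /
   logistic / raw output scales.
4. **Evaluation** — AUC, Kappa, TSS, Jaccard and Sørensen under k-fold
   cross-validation, with binarization at the threshold maximizing TSS.
5. **Transfer** — projection onto future climate reusing the
   calibration threshold, mobility-oriented parity (MOP) extrapolation
   detection, and occurrence-based restriction (OBR) of far suitable
   patches.
6. **Biodiversity redistribution** — per-cell species richness by
   stacking binary maps, per-species range shifts, richness change, and
   a four-region prioritization (restoration / habitat management /
   species management / refugia) crossed with native-vegetation change,
   summarized per protected area with a Kolmogorov–Smirnov
   effectiveness test.

A synthetic-world generator (spatially autocorrelated, inter-correlated
climate layers; virtual species with known response curves; biased
occurrence sampling; a warmed/wetted future; clustered vegetation loss;
patchy protected areas) supplies every input with known ground truth,
so the full pipeline runs and is validated without any downloads.

## The core models

**Maxent.** For presence points and background points with feature
vector $f(x)$, the fitted distribution over the landscape is
$\pi(x) \propto e^{\beta^\top f(x)}$, estimated as an
infinitely-weighted logistic lasso: background points enter with weight
100, features are min–max scaled to $[0,1]$ on training bounds, and the
L1 penalty per feature follows the published sample-size-dependent
Maxent defaults per feature class. The cloglog output
$1 - \exp(-e^{H + \beta^\top f(x) + \alpha})$ (with $H$ the entropy of
the background-normalized distribution) gives suitability in $[0,1]$.

**Richness and range shift.** With $bin_{i,k} \in \{0,1\}$ the
thresholded prediction for species $i$ in cell $k$, per-cell richness is
$S_k = \sum_{i=1}^{N} bin_{i,k}$, and each species' range shift between
scenarios is $R_i = \frac{A_{t1} - A_{t0}}{A_{t0}} \times 100$, with
$R_i < 0$ contraction, $R_i > 0$ expansion and $A_{t1} = 0$ projected
extinction.

**Prioritization.** Cells are classified by the sign of richness change
$\Delta S = S_{future} - S_{current}$ crossed with native-vegetation
change: region 1 ($\Delta S < 0$, vegetation lost) — habitat
restoration; region 2 ($\Delta S > 0$, lost) — habitat management;
region 3 ($\Delta S < 0$, kept) — species management; region 4
($\Delta S > 0$, kept) — habitat refugia.

## Worked example

```r
library(stacksdm)

cfg <- pipeline_config(
  world = synthetic_world_config(100, 100, n_layers = 6, seed = 42),
  n_species = 5, seed = 42)
res <- run_pipeline(cfg)

res$shifts[, c("species", "area_current", "area_future",
               "shift_percent", "status")]
#> # A tibble: 5 × 5
#>   species    area_current area_future shift_percent status
#>   <chr>             <int>       <int>         <dbl> <chr>
#> 1 species_01         2073        2016         -2.75 contraction
#> 2 species_02         2854        2511        -12.0  contraction
#> 3 species_03         2757        2524         -8.45 contraction
#> 4 species_04         1931        1643        -14.9  contraction
#> 5 species_05         2574        2351         -8.66 contraction

res$ks_current
#> # A tibble: 1 × 4
#>   d_statistic    p_value n_inside n_outside
#>         <dbl>      <dbl>    <int>     <int>
#> 1      0.0810 0.00000390     1140      8359
```

Each row of `res$shifts` is one virtual species: its suitable-cell
count under the current and future climate (after maxTSS binarization
and occurrence-based restriction) and the resulting percent range
shift — here all five species contract under the default +1.4 °C,
wetter future. `res$ks_current` compares per-cell richness inside
versus outside the synthetic protected areas: D = 0.081 with a small
p-value means the richness distributions differ (protected cells hold
detectably different richness), though far less starkly than in a real,
deliberately sited reserve network. `res$evaluation_summary`,
`res$pa_summary` and `autoplot(res$priority)` give the per-species
cross-validated metrics, the per-protected-area recommendations, and
the four-region priority map.

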