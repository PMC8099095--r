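---
title: "Methods: sulfur isoscape construction and multi-isotope geographic assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sulfur isoscape construction and multi-isotope geographic assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator emulates (and does not), the numerical choices,
and the design decisions taken where the design was genuinely open.

## 1. The provenance problem

Teeth form in childhood and are isotopically inert afterwards, so the
isotopic composition of enamel and tooth collagen records the environment
in which an individual grew up. Three systems carry complementary
geographic signal. Collagen δ³⁴S mixes heavy marine sulfate — deposited as
sea-salt aerosol, so its imprint decays inland — with geologically variable
bedrock sulfur. Enamel δ¹⁸O follows drinking water and hence precipitation.
Enamel ⁸⁷Sr/⁸⁶Sr traces bioavailable strontium and thus bedrock age and
composition. Given a gridded prediction of each quantity with an
uncertainty (an *isoscape*), a measured individual can be assigned a
probability of origin at every grid cell; combining systems multiplies the
evidence and shrinks the credible region.

Oxygen and strontium isoscapes exist as published data products and are
consumed by this package as mean/SD raster pairs. The sulfur isoscape is
the part that must be built: from a compilation of archaeological collagen
δ³⁴S analyses and environmental covariate grids.

## 2. Compilation screening and site averaging

`loadCompilation()` ingests one row per analyzed specimen.
`screenRecords()` applies the preservation and locality screens:

* elemental ratios: keep only records with C/S < 300 **and** N/S < 100
  (strict inequalities — a record at exactly 300 fails). C/S and N/S are
  weight-percent ratios (`pctC/pctS`, `pctN/pctS`) while C/N is atomic —
  the mixed convention under which collagen preservation values are
  conventionally reported;
* records carrying only sulfur data (`s_only`) are exempt from the ratio
  screen, since no ratios exist to screen on. Records lacking both ratios
  and the flag are treated the same way, with a warning: compilations
  predate uniform reporting, and silently discarding them would bias
  against older literature;
* reported diagenesis/contamination, explicit non-local designation
  (defined as an origin more than 100 km away; consumed as an annotation,
  never recomputed from coordinates), and aquatic animals or fish
  consumers are excluded. Each rejection carries exactly one primary
  reason, evaluated in the fixed order diagenesis → non-local → aquatic →
  elemental-ratio, so rejection tallies are reproducible.

`siteAverage()` collapses records to one value per site (arithmetic mean;
sample SD with the n−1 denominator, undefined for single-record sites —
such sites contribute no SD to the summary). `summarizeCompilation()`
reports the headline statistics and a Shapiro–Wilk statistic on the site
means as a normality diagnostic.

## 3. The random-forest isoscape model

`regressionDataset()` joins site means with covariates extracted at the
site cells. The forest defaults are conventional for regression forests:
500 trees, `max(1, floor(p/3))` candidate features per split, minimum node
size 5. All fits are deterministic given a seed.

### Variable selection

`selectVariables()` follows the rank-then-add strategy of forest-based
variable selection, in two stages:

1. **Ranking/elimination.** Permutation importance (mean increase in OOB
   MSE when a variable is permuted, unscaled) is averaged over 25 forests.
   The lowest-ranked half of the candidates estimates the noise scale of
   the importance measure; variables below 3 × the SD of that half are
   eliminated. The three-sigma multiplier matters: uninformative variables
   acquire persistently positive importance through spurious sample
   correlations with the response, a data-level effect that forest
   averaging cannot remove, so a one-sigma threshold lets such variables
   through regularly. When even the lowest-ranked variables carry
   substantial importance (> 10% of the top variable's), there is no noise
   floor to estimate and elimination is skipped.
2. **Stepwise addition.** Survivors are added in rank order; an addition
   is kept if it lowers the OOB RMSE, averaged over 10 forests to
   stabilize the decision, by more than `additionTolerance` (default 0 —
   deliberately permissive, so weak true predictors are not lost once
   stage 1 has removed the noise; an adaptive tolerance equal to the SD of
   the replicate OOB estimates is available). The path starts from the
   intercept-only RMSE, i.e. the SD of the response.

### Cross-validation

The published description of the validation scheme is internally
ambiguous: a "10-fold" scheme implies 90% training, while "80% of the data
for training" is stated explicitly. `crossValidate()` honors the explicit
statement: the default scheme is 10 random 80/20 splits repeated 5 times
(50 model fits), with classic k-fold partitions reachable via
`trainFraction = NULL`. RMSE and R² are computed on the pooled held-out
pairs only — skill is never measured on training folds, and a
shuffled-response control drives R² to zero (this is a test in the suite).

### Prediction and uncertainty

`predictIsoscape()` evaluates the final forest on every grid cell with
complete covariates. Random forests carry no built-in spatial uncertainty,
so the SD surface is constant and equal to the cross-validated RMSE. Two
known simplifications follow. First, the residual-kriging stage of a full
regression-kriging treatment is omitted: the final uncertainty treatment
is the constant RMSE. Second, constant RMSE is calibrated against *site
means*; a single individual additionally carries within-site scatter, so
posterior regions for individuals are very slightly anticonservative (see
§6). Spatially varying uncertainty (quantile forests) is out of scope.

## 4. Oxygen conversion chain

Measured enamel structural-carbonate δ¹⁸O is brought to the drinking-water
scale in three affine steps: the VPDB → VSMOW scale relation
(1.03091 x + 30.91), carbonate → phosphate ((x − 8.79)/1.015), and
phosphate → water ((x − 21.28)/0.68). Each step checks and carries
scale/fraction tags (`OxygenValues`), is strictly increasing, and is
exactly invertible — round trips recover inputs to 10⁻⁹ ‰ in the tests.

One decision deserves emphasis: enamel carbonate values are conventionally
reported on VPDB while the calibration literature operates on VSMOW, and
the source calibrations do not state a scale conversion. The pipeline
applies the standard VPDB → VSMOW relation first, and exposes
`assumeInputScale` so users who believe their inputs are already on VSMOW
can say so.

The combined uncertainty of the two calibrations is taken as the constant
1 ‰ summary value and added to the precipitation-isoscape SD in quadrature
(the default; arithmetic addition — the more conservative reading of
"added" — is available via `mode = "additive"`). A first-order
delta-method propagation from the four printed coefficient SDs
(`chainUncertainty()`) is provided for comparison; treating the published
coefficient SDs as independent it yields ≈ 1.8 ‰ at typical enamel values,
which overstates the calibration scatter because the coefficient estimates
are strongly correlated — the reason the constant summary value is the
default.

## 5. Continuous-surface assignment

For each measured system, `zSurface()` standardizes the measurement
against the isoscape (optionally inflating σ_c by the analytical
uncertainty in quadrature), `likelihoodSurface()` applies the standard
normal density f(z) = (1/√(2π)) exp(−z²/2), and the surface is normalized
to unit mass over the valid cells. Note that the density of *z* is used,
not the density of *x* (which would carry an extra 1/σ_c factor): with the
constant-SD sulfur isoscape the two differ only by a constant, and the
z-density is the published convention of the assignment framework this
package follows.

Joint surfaces are cell-wise products under the independence assumption,
renormalized over the intersected mask. All normalization runs in log
space with max-subtraction (`probabilitySurfaceFromZ()`, used throughout
the orchestration), so assignments survive |z| of hundreds without
underflow; the direct density path is kept for exactness checks.

`topMassRegion()` implements the "highest 33.3% of the probability
distribution" threshold as cumulative posterior mass: cells sorted by
decreasing probability, the shortest prefix reaching q included, ties at
the cut all included (deterministic and permutation-invariant). The
alternative reading — the top third of *cells* by probability — is exposed
as `mode = "area_fraction"`. Precision is `pctAreaRemoved()`: the percent
of valid study area outside the region; on the equal-area grid, areas are
cell counts.

## 6. The synthetic world

`syntheticWorld()` generates the study conditions under which the pipeline
is validated: a 120 × 120 grid of 10-km cells (scale-free; chosen so the
full end-to-end experiment runs in well under a minute), a wavy western
coastline, and

* **r.ssa** — sea-salt deposition, exponential decay with distance to
  coast (12 kg ha⁻¹ yr⁻¹ at the coast, 80-km decay length);
* **r.dust** — a smooth north-to-south dust deposition gradient with
  low-frequency noise, 0.2–5 g m⁻² yr⁻¹;
* **r.bouguer** — a smooth bounded random field, ±150 mGal;
* six pure-noise decoy layers.

The true sulfur surface is marine + dust + gravity: a logistic decline in
distance to coast expressed through the sea-salt covariate (plateau 15 ‰
near the coast, total drop 13 ‰ centered at 150 km with a 40-km
transition), plus ±3 ‰ dust and ±3.5 ‰ gravity terms. The logistic
replaces a softplus-style decline that would keep falling linearly far
inland: the marine imprint is flat near the coast, drops over roughly
150–200 km, and is absent beyond — so the far field must be flat. The
surface spans ≈ −5 to 21 ‰, matching the observed range of compiled
European collagen values.

Noise is calibrated, not tuned: within-site replicate SD is fixed at
1.77 ‰ (the compilation's observed average), and the site-level effect SD
is set so the true surface explains exactly the configured
`signalFraction` (default 0.65) of site-mean variance —
τ² = V(1−f)/f with V the surface variance over land, split as
τ² = σ²_site + σ²_within/n. The individual-level SD
√(σ²_site + σ²_within) becomes the SD of the true sulfur isoscape.
Oxygen (precipitation water, −10.5 to −3.5 ‰, SD 0.6–1.0 ‰) and strontium
(0.7065–0.7135, SD 0.001–0.0015) truths are smooth synthetic surfaces in
realistic ranges. One seed drives everything through derived sub-seeds, so
worlds, compilations and individuals are independently regenerable and
byte-identical across runs.

**What passing tests show — and what they do not.** The generator emulates
the *structure* of the real problem: monotone covariate responses,
plateaued marine decline, site-level and replicate noise, decoy
covariates, well- and mis-specified measurement noise. It deliberately
does not emulate real European geography, the spatial autocorrelation of
real residuals, cross-correlated covariates (real deposition, gravity and
distance-to-coast are mutually correlated; the synthetic ones are nearly
orthogonal), multi-resolution raster artifacts, or non-uniform site
placement (real compilations oversample some regions). Recovery results
on the synthetic world therefore validate the machinery — screening
arithmetic, selection behavior, CV honesty, posterior calibration, region
geometry — not the attainable accuracy on real data.

Two empirical regularities of the synthetic experiments are worth naming.
Cross-validated R² sits a few points *below* the configured signal
fraction (≈ 0.58 vs 0.65 on average over seeds) because the forest's own
approximation error adds to the irreducible noise; the recovery criterion
(±0.1) anticipates exactly this gap. And triple-assignment coverage of
true origins at q = 1/3 runs at or slightly below nominal when the sulfur
surface is the *predicted* isoscape with constant RMSE (≈ 0.28–0.35 across
seeds), since RMSE is calibrated on site means rather than individuals;
with well-specified truth isoscapes, coverage is at or above nominal, as
posterior theory requires.

## 7. Numerical and interface choices

* **Grids** are matrices with `NA` nodata inside S4 containers
  (`GridSpec`, `RasterGrid`, `CovariateStack`, `Isoscape`,
  `ProbabilitySurface`, `BinaryRegion`) with validity checks (unit mass to
  1e-9, positive SDs, shared masks). Raster I/O uses the ESRI ASCII grid
  format — plain text, single band, explicit nodata; the CRS travels in
  the configuration and manifests, since the format has no CRS tag.
* **Cell convention**: row-major, origin upper-left, half-open cells
  `[x, x+s) × (y−s, y]` — a point on a shared edge belongs to the cell to
  its right/below, one deterministic rule verified against a brute-force
  containment oracle.
* **Projection**: Eckert IV (equal-area, so cell counting is area
  arithmetic) implemented in closed form with Newton iteration for the
  parametric angle; validated against an independent root-finder and by
  round-trips to 1e-9 degrees. Continuous layers resample bilinearly,
  discrete layers by nearest/mode, nodata propagates.
* **Distance to coast** uses an exact Euclidean distance transform
  (cell-center to cell-center), verified against the O(n²) definition on
  random masks.
* **Determinism**: every stochastic step reseeds from
  `deriveSeed(seed, offset)`; identical seeds yield byte-identical CSV,
  JSON and grid artifacts (manifests deliberately carry no timestamps).
* **Problem sizes** used by the test-suite and acceptance script — 200
  sites × 5 records, 200–500 individuals, five seeds, 120 × 120 cells
  (48 × 48 in unit tests) — are the package's chosen study conditions: big
  enough for stable statistics, small enough to iterate on.

## 8. Known limitations

* The constant-RMSE uncertainty is a single number for a spatially
  heterogeneous error; regions in covariate space where the forest
  extrapolates get the same SD as well-sampled ones.
* Forest predictions are bounded by the training response range, so the
  isoscape cannot predict beyond the compiled extremes.
* The independence assumption of the joint assignment ignores shared
  environmental drivers among isotope systems (e.g. coastal proximity
  affects both δ³⁴S and δ¹⁸O).
* XLSX ingestion requires the optional readxl package; CSV is the
  first-class path.
* The generalized-linear-model alternative to the forest is not
  implemented, having been discarded in the source analysis.
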