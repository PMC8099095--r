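# sulfurscape

Sulfur isoscapes and multi-isotope probabilistic geographic assignment.

`sulfurscape` is an R package for researchers in isotope archaeology and
paleoecology who want to answer the question *"where did this individual
grow up?"* from the isotopic composition of teeth. It implements, as a
tested and reusable pipeline:

1. **Sulfur isoscape construction** — screening a compilation of collagen
   δ³⁴S analyses for preservation quality, averaging per site, and fitting
   a random-forest regression on environmental covariates (sea-salt and
   dust aerosol deposition, Bouguer gravity anomaly, soil and climate
   layers) with two-stage variable selection and repeated cross-validation,
   yielding a gridded δ³⁴S prediction with constant-RMSE uncertainty.
2. **Oxygen conversion** — bringing measured enamel structural-carbonate
   δ¹⁸O onto the drinking-water scale through the carbonate → phosphate →
   water calibration chain, with uncertainty propagation.
3. **Continuous-surface assignment** — turning isoscapes plus per-individual
   tissue measurements (δ³⁴S, δ¹⁸O, ⁸⁷Sr/⁸⁶Sr) into normalized
   probability-of-origin surfaces, combining systems multiplicatively,
   thresholding the highest-probability mass, and reporting assignment
   precision as percent of study area removed.
4. **A synthetic world** with known ground truth, so every stage can be
   validated end to end without external rasters.

## The model

For a tissue measurement `x*` compared against an isoscape with per-cell
predicted mean μ_c and standard deviation σ_c, each grid cell `c` is scored
by the standardized deviation and the standard normal density

    z* = (x* − μ_c) / σ_c
    f(z* | c) = (1/√(2π)) · exp(−z*²/2)

and the densities are normalized over the study area into a probability of
origin relative to all other locations. Under independence of the isotopic
systems, the joint surface is the renormalized cell-wise product of the
single-system surfaces. Zones of high probability are the smallest set of
cells, taken in decreasing probability order, whose cumulative posterior
mass reaches q = 1/3.

Oxygen enters the comparison on the water scale through two affine
calibrations (with the VPDB → VSMOW scale conversion applied first):

    δ¹⁸O_p = (δ¹⁸O_c − 8.79) / 1.015
    δ¹⁸O_w = (δ¹⁸O_p − 21.28) / 0.68

with a summary chain uncertainty of 1 ‰ added in quadrature to the
precipitation-isoscape uncertainty.

The sulfur isoscape itself is a random-forest regression of screened,
site-averaged collagen δ³⁴S on gridded covariates; predictors are chosen by
ranking permutation importance and then adding variables in rank order while
out-of-bag RMSE improves, and predictive skill is estimated by 10 × 5
repeated cross-validation at an 80/20 split. Because a random forest has no
built-in spatial uncertainty, the isoscape SD is constant and equal to the
cross-validated RMSE.

## Worked example

Run the whole pipeline on a synthetic world whose true δ³⁴S surface,
covariates and noise levels are known, then assign 200 individuals of known
origin:

```r
library(sulfurscape)
rep <- endToEndExperiment(worldSpec(seed = 1), nIndividuals = 200, seed = 1)
print(rep)
```

```
End-to-end synthetic experiment (seed 1)
  compilation: 900 records, 200 sites, mean site SD 1.67 permil
  selection: r.ssa, r.bouguer, r.dust, decoy_5 (recall 1.00, 1 decoys)
  CV: R2 0.602, RMSE 3.69 permil; grid RMSE vs truth 1.54
  mean % area removed: S 83.7, O 85.1, Sr 88.4, S+O 90.9, S+Sr 93.5, O+Sr 94.1, S+O+Sr 96.1
  coverage at q: S 0.34, O 0.33, Sr 0.32, S+O 0.32, S+Sr 0.30, O+Sr 0.34, S+O+Sr 0.28
```

Reading this output: the simulated compilation of 900 records at 200 sites
shows within-site replicate scatter of 1.67 ‰ (the generator's configured
1.77 ‰, shrunk by the small-sample bias of the SD). Variable selection
recovered all three informative covariates — sea-salt deposition, gravity
anomaly, dust deposition — here with one spurious decoy. Cross-validation
explains 60% of the site-mean variance (the world is calibrated so a
perfect model would explain 65%), and the predicted surface tracks the true
surface to 1.5 ‰ grid-wide. Assignment precision grows from single
(83–88% of the study area removed at q = 1/3) through dual (91–94%) to the
triple-isotope assignment (96%), and the q = 1/3 regions contain the true
origin cell at close to their nominal one-third frequency.

Converting a measured enamel carbonate value to drinking water:

```r
tissueToWater(-4.0)
#> OxygenValues [water, VSMOW]: -5.21999 (sd 1) permil
```

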