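# Smooth standardized random field: sum of random plane waves over the unit
# square, standardized to mean 0 / sd 1. Caller controls the RNG state.
.smoothField <- function(nr, nc, nWaves = 8) {
  X <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  Y <- matrix(rep((seq_len(nr) - 0.5) / nr, nc), nr, nc)
  f <- matrix(0, nr, nc)
  for (k in seq_len(nWaves)) {
    a <- stats::rnorm(1)
    fr <- stats::runif(2, 0.5, 3)
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + a * cos(2 * pi * (fr[1] * X + fr[2] * Y) + ph)
  }
  (f - mean(f)) / stats::sd(f)
}

#' Specification of a synthetic isoscape world
#'
#' Bundles the parameters of the synthetic world used for ground-truth
#' validation: grid geometry, the coast-driven sulfur response, covariate
#' amplitudes, noise levels and the target signal fraction. Defaults emulate
#' the structure of the western-European compilation: a 120 x 120 grid of
#' 10-km cells, a sulfur surface spanning about -5 to 21 permil that
#' plateaus near the coast and drops steeply beyond ~150 km, within-site
#' replicate scatter of 1.77 permil, and site-level noise calibrated so the
#' true surface explains 65% of the site-mean variance.
#'
#' @param nrows,ncols,cellSize grid dimensions and cell edge (metres).
#' @param seed integer seed governing every random component of the world.
#' @param plateau coastal plateau of the marine sulfur response (permil).
#' @param drop total decline of the marine response far inland (permil).
#' @param breakpointKm distance at which the decline is half-complete (km).
#' @param widthKm width of the logistic transition (km).
#' @param dustAmp,bouguerAmp amplitudes of the additive dust and gravity
#'   terms (permil).
#' @param ssaScale,ssaDecayKm sea-salt deposition at the coast
#'   (kg/ha/yr) and its exponential decay length (km).
#' @param signalFraction target fraction of site-mean variance explained by
#'   the true surface.
#' @param withinSiteSd within-site replicate SD (permil).
#' @param perSiteN default records per site (enters the site-noise
#'   calibration).
#' @param nDecoys number of pure-noise decoy covariate layers.
#' @return A list of class `WorldSpec` (including `$spec`, the
#'   [GridSpec-class] in the `"local"` CRS).
#' @export
worldSpec <- function(nrows = 120, ncols = 120, cellSize = 10000, seed = 1,
                      plateau = 15, drop = 13, breakpointKm = 150,
                      widthKm = 40, dustAmp = 3, bouguerAmp = 3.5,
                      ssaScale = 12, ssaDecayKm = 80,
                      signalFraction = 0.65, withinSiteSd = 1.77,
                      perSiteN = 5, nDecoys = 6) {
  stopifnot(signalFraction > 0, signalFraction < 1, nDecoys >= 1)
  out <- list(nrows = nrows, ncols = ncols, cellSize = cellSize, seed = seed,
              plateau = plateau, drop = drop, breakpointKm = breakpointKm,
              widthKm = widthKm, dustAmp = dustAmp, bouguerAmp = bouguerAmp,
              ssaScale = ssaScale, ssaDecayKm = ssaDecayKm,
              signalFraction = signalFraction, withinSiteSd = withinSiteSd,
              perSiteN = perSiteN, nDecoys = nDecoys,
              spec = GridSpec(nrows, ncols, cellSize, crs = "local"))
  class(out) <- "WorldSpec"
  out
}

# Parametric land/sea mask: sea along a wavy western coastline.
.makeLandMask <- function(ws) {
  spec <- ws$spec
  xkm <- matrix(rep(((seq_len(spec@ncols)) - 0.5) * spec@cellSize / 1000,
                    each = spec@nrows), spec@nrows, spec@ncols)
  rowIdx <- matrix(rep(seq_len(spec@nrows), spec@ncols),
                   spec@nrows, spec@ncols)
  ykm <- (spec@nrows - rowIdx + 0.5) * spec@cellSize / 1000
  coast <- 150 + 80 * sin(2 * pi * ykm / 800) + 40 * sin(2 * pi * ykm / 230 + 1)
  land <- (xkm >= coast) * 1
  rasterGrid(land, spec, name = "land")
}

#' Generate a synthetic world with known ground truth
#'
#' Builds the full synthetic fixture: a wavy western coastline, covariate
#' stack, true isoscapes for all three systems and the calibrated noise
#' model. Everything is deterministic given `ws$seed`.
#'
#' The covariate stack contains three informative layers — `r.ssa` (sea-salt
#' deposition, exponential decay with distance to coast), `r.dust` (a smooth
#' north-to-south dust deposition gradient with low-frequency noise) and
#' `r.bouguer` (a smooth random gravity-anomaly field) — plus `nDecoys` pure
#' white-noise decoy layers. The true sulfur surface is
#' `marine + dust + gravity` where the marine term is a logistic decline in
#' distance to coast (expressed through `r.ssa`, so the forest can learn it
#' from the deposition covariate): flat near the coast, dropping around
#' `breakpointKm`, flat again far inland. Oxygen (precipitation water, mean
#' and SD) and strontium (ratio, mean and SD) truths are smooth synthetic
#' surfaces in realistic ranges.
#'
#' Noise calibration: with `V` the variance of the true sulfur surface over
#' land and `f` the target signal fraction, total site-mean noise is
#' `tau^2 = V (1 - f) / f`, split into a site-level effect and the
#' within-site SD (`tau^2 = sigmaSite^2 + withinSiteSd^2 / perSiteN`). The
#' individual-level measurement SD is `sqrt(sigmaSite^2 + withinSiteSd^2)`
#' and becomes the SD of the true sulfur isoscape.
#'
#' @param ws a [worldSpec()].
#' @return A list of class `SyntheticWorld`: `ws`, `spec`, `landMask`,
#'   `distance` (km to coast), `stack` ([CovariateStack-class]),
#'   `isoscapes` (list of true S/O/Sr [Isoscape-class]; O is the
#'   precipitation-water surface with its own SD, before chain widening),
#'   `components` (marine/dust/gravity terms of the sulfur truth),
#'   `varSurface`, `tau2`, `sigmaSite`, `sigmaIndiv`, `landCells` (indices).
#' @export
syntheticWorld <- function(ws) {
  spec <- ws$spec
  nr <- spec@nrows; nc <- spec@ncols
  landMask <- .makeLandMask(ws)
  land <- landMask@values != 0
  dist <- distanceToCoast(landMask)
  dkm <- dist@values

  naSea <- function(m) { m[!land] <- NA_real_; m }

  ssa <- ws$ssaScale * exp(-dkm / ws$ssaDecayKm)

  set.seed(deriveSeed(ws$seed, 11L))
  dustNoise <- .smoothField(nr, nc)
  rowFrac <- matrix(rep((seq_len(nr) - 0.5) / nr, nc), nr, nc)  # 0 N, 1 S
  dustRaw <- rowFrac + 0.35 * dustNoise
  rng <- range(dustRaw[land])
  dust01 <- (dustRaw - rng[1]) / diff(rng)
  dust <- 0.2 + 4.8 * dust01                    # g m^-2 yr^-1

  set.seed(deriveSeed(ws$seed, 12L))
  bougField <- tanh(.smoothField(nr, nc))
  bouguer <- 150 * bougField                    # mGal, bounded

  layers <- list(
    r.ssa = rasterGrid(naSea(ssa), spec, "r.ssa"),
    r.dust = rasterGrid(naSea(dust), spec, "r.dust"),
    r.bouguer = rasterGrid(naSea(bouguer), spec, "r.bouguer"))
  set.seed(deriveSeed(ws$seed, 13L))
  for (k in seq_len(ws$nDecoys)) {
    nm <- sprintf("decoy_%d", k)
    layers[[nm]] <- rasterGrid(naSea(matrix(stats::rnorm(nr * nc), nr, nc)),
                               spec, nm)
  }
  stack <- covariateStack(layers)

  # true sulfur surface, expressed through the covariates
  dFromSsa <- -ws$ssaDecayKm * log(pmax(ssa / ws$ssaScale, 1e-12))
  marine <- ws$plateau -
    ws$drop * stats::plogis((dFromSsa - ws$breakpointKm) / ws$widthKm)
  dustTerm <- ws$dustAmp * (2 * dust01 - 1)
  bougTerm <- ws$bouguerAmp * bougField
  muS <- naSea(marine + dustTerm + bougTerm)

  V <- stats::var(muS[land])
  f <- ws$signalFraction
  tau2 <- V * (1 - f) / f
  sigmaSite <- sqrt(max(tau2 - ws$withinSiteSd^2 / ws$perSiteN, 1e-4))
  sigmaIndiv <- sqrt(sigmaSite^2 + ws$withinSiteSd^2)
  trueS <- isoscape("S", rasterGrid(muS, spec, "d34S.true"), sigmaIndiv,
                    note = "synthetic truth")

  # oxygen: precipitation-water surface, wetter/heavier south and coastal
  set.seed(deriveSeed(ws$seed, 14L))
  fO <- .smoothField(nr, nc)
  north01 <- 1 - rowFrac
  dmax <- max(dkm[land])
  muO <- naSea(-3.5 - 4.5 * dkm / dmax - 2.5 * north01 + 0.5 * tanh(fO))
  sdO <- naSea(0.6 + 0.4 * north01)
  trueO <- isoscape("O", rasterGrid(muO, spec, "d18Ow.true"),
                    rasterGrid(sdO, spec, "d18Ow.sd"),
                    note = "synthetic precipitation truth")

  # strontium: smooth geological field
  set.seed(deriveSeed(ws$seed, 15L))
  fSr1 <- .smoothField(nr, nc); fSr2 <- .smoothField(nr, nc)
  muSr <- naSea(0.710 + 0.0035 * tanh(fSr1))
  sdSr <- naSea(0.001 + 0.0005 * stats::plogis(fSr2))
  trueSr <- isoscape("Sr", rasterGrid(muSr, spec, "sr.true"),
                     rasterGrid(sdSr, spec, "sr.sd"),
                     note = "synthetic bioavailable Sr truth")

  out <- list(ws = ws, spec = spec, landMask = landMask, distance = dist,
              stack = stack,
              isoscapes = list(S = trueS, O = trueO, Sr = trueSr),
              components = list(marine = naSea(marine),
                                dust = naSea(dustTerm),
                                bouguer = naSea(bougTerm)),
              varSurface = V, tau2 = tau2, sigmaSite = sigmaSite,
              sigmaIndiv = sigmaIndiv, landCells = which(land))
  class(out) <- "SyntheticWorld"
  out
}

#' @export
print.SyntheticWorld <- function(x, ...) {
  cat(sprintf("SyntheticWorld: %d x %d cells (%.0f km), %d land cells\n",
              x$spec@nrows, x$spec@ncols, x$spec@cellSize / 1000,
              length(x$landCells)))
  cat(sprintf("  true d34S range [%.1f, %.1f] permil, surface var %.2f\n",
              min(x$isoscapes$S@mean@values, na.rm = TRUE),
              max(x$isoscapes$S@mean@values, na.rm = TRUE), x$varSurface))
  cat(sprintf("  noise: site sd %.2f, individual sd %.2f (signal fraction %.2f)\n",
              x$sigmaSite, x$sigmaIndiv, x$ws$signalFraction))
  invisible(x)
}

#' Isoscapes as used at assignment time
#'
#' The sulfur and strontium truths are used as-is; the oxygen
#' precipitation-water SD is widened by the carbonate-to-water conversion
#' chain uncertainty (in quadrature), since measured enamel values reach the
#' water scale through that chain.
#'
#' @param world a [syntheticWorld()].
#' @param params oxygen [conversionParams()].
#' @return Named list of [Isoscape-class] objects (`S`, `O`, `Sr`).
#' @export
assignmentIsoscapes <- function(world, params = conversionParams()) {
  o <- world$isoscapes$O
  list(S = world$isoscapes$S,
       O = isoscape("O", o@mean,
                    combineOxygenUncertainty(o@sd, params$chainSd),
                    note = "precipitation truth + conversion chain"),
       Sr = world$isoscapes$Sr)
}

#' Sample a synthetic site compilation
#'
#' Draws `nSites` distinct land cells and, for each, `perSiteN` collagen
#' records: true surface value at the cell, plus a site-level effect
#' (SD `sigmaSite`, calibrated by the world unless overridden) plus
#' within-site replicate noise (SD `withinSd`). A fraction of records
#' carries screening violations (cyclically: non-local flag, aquatic flag,
#' reported diagenesis, failing C/S ratio) to exercise [screenRecords()];
#' the remainder carry preservation-grade elemental percentages.
#'
#' Coordinates are cell centers in projected metres (the world's `"local"`
#' CRS), so extraction recovers the generating cell exactly.
#'
#' @param world a [syntheticWorld()].
#' @param nSites number of sites (distinct land cells).
#' @param perSiteN records per site.
#' @param flaggedFraction fraction of records with screening violations.
#' @param seed integer seed.
#' @param sigmaSite,withinSd noise overrides (set both 0 for a noise-free
#'   compilation).
#' @return A data.frame of canonical compilation records (see
#'   [loadCompilation()]) with an extra attribute `"cells"`: the generating
#'   cell index per site.
#' @export
sampleSites <- function(world, nSites = 200, perSiteN = world$ws$perSiteN,
                        flaggedFraction = 0.1, seed = 1,
                        sigmaSite = NULL, withinSd = NULL) {
  if (is.null(withinSd)) withinSd <- world$ws$withinSiteSd
  if (is.null(sigmaSite))
    sigmaSite <- sqrt(max(world$tau2 - withinSd^2 / perSiteN, 1e-4))
  if (nSites > length(world$landCells))
    stop("more sites than land cells", call. = FALSE)
  spec <- world$spec
  mu <- world$isoscapes$S@mean@values

  set.seed(deriveSeed(seed, 21L))
  cells <- sample(world$landCells, nSites)
  rows <- ((cells - 1L) %% spec@nrows) + 1L
  cols <- ((cells - 1L) %/% spec@nrows) + 1L
  ctr <- xyFromCell(spec, rows, cols)
  siteEffect <- stats::rnorm(nSites, 0, sigmaSite)

  n <- nSites * perSiteN
  siteIdx <- rep(seq_len(nSites), each = perSiteN)
  d34S <- mu[cells][siteIdx] + siteEffect[siteIdx] +
    stats::rnorm(n, 0, withinSd)

  rec <- data.frame(
    record_id = sprintf("rec%05d", seq_len(n)),
    site_id = sprintf("S%04d", siteIdx),
    latitude = ctr[siteIdx, "y"],
    longitude = ctr[siteIdx, "x"],
    species = "synthetic", period = "synthetic",
    d34S = d34S, d13C = NA_real_, d15N = NA_real_,
    pctC = 42.1, pctN = 15.5, pctS = 0.2,
    CS_ratio = NA_real_, NS_ratio = NA_real_, CN_ratio = NA_real_,
    diagenesis_reported = FALSE, nonlocal_reported = FALSE,
    aquatic_or_fish_consumer = FALSE, s_only = FALSE)

  nFlag <- round(flaggedFraction * n)
  if (nFlag > 0) {
    bad <- sample(n, nFlag)
    kind <- rep_len(c("nonlocal", "aquatic", "diagenesis", "ratio"), nFlag)
    rec$nonlocal_reported[bad[kind == "nonlocal"]] <- TRUE
    rec$aquatic_or_fish_consumer[bad[kind == "aquatic"]] <- TRUE
    rec$diagenesis_reported[bad[kind == "diagenesis"]] <- TRUE
    rec$pctS[bad[kind == "ratio"]] <- 0.12    # C/S about 351: fails screen
  }
  rec$CS_ratio <- rec$pctC / rec$pctS
  rec$NS_ratio <- rec$pctN / rec$pctS
  rec$CN_ratio <- (rec$pctC / 12.011) / (rec$pctN / 14.007)
  attr(rec, "cells") <- cells
  rec
}

#' Sample individuals of known origin
#'
#' Draws `n` individuals at uniformly random land cells and measures each on
#' the requested isotope systems: true surface value at the origin cell plus
#' Gaussian noise whose SD equals the assignment-time isoscape SD at that
#' cell (the well-specified case) times `noiseMultiplier`.
#'
#' @param world a [syntheticWorld()].
#' @param n number of individuals.
#' @param systems isotope systems to measure.
#' @param seed integer seed.
#' @param isoscapes named list of assignment-time [Isoscape-class] objects
#'   supplying means (truth) and noise SDs; defaults to
#'   [assignmentIsoscapes()] of the world.
#' @param noiseMultiplier multiply the noise SD (use > 1 for the
#'   mis-specified case).
#' @return A data.frame: `individual_id`, `cell`, `true_row`, `true_col`,
#'   and one column per measured system (`S`, `O` — water-equivalent
#'   permil — and/or `Sr`).
#' @export
sampleIndividuals <- function(world, n = 500, systems = c("S", "O", "Sr"),
                              seed = 1, isoscapes = NULL,
                              noiseMultiplier = 1) {
  if (is.null(isoscapes)) isoscapes <- assignmentIsoscapes(world)
  spec <- world$spec
  set.seed(deriveSeed(seed, 31L))
  cells <- sample(world$landCells, n, replace = TRUE)
  out <- data.frame(individual_id = sprintf("ind%05d", seq_len(n)),
                    cell = cells,
                    true_row = ((cells - 1L) %% spec@nrows) + 1L,
                    true_col = ((cells - 1L) %/% spec@nrows) + 1L)
  for (sys in systems) {
    iso <- isoscapes[[sys]]
    if (is.null(iso)) stop("no isoscape for system ", sys, call. = FALSE)
    mu <- world$isoscapes[[sys]]@mean@values[cells]
    sdv <- iso@sd@values[cells] * noiseMultiplier
    out[[sys]] <- mu + stats::rnorm(n, 0, sdv)
  }
  out
}

#' Coverage and precision of assignments on known-origin individuals
#'
#' Assigns each sampled individual with [assignOrigin()] against the given
#' isoscapes and records, for every system subset, whether the true origin
#' cell falls inside the highest-mass region at `q` (coverage) and the
#' percent of study area the region removes (precision).
#'
#' @param world a [syntheticWorld()].
#' @param individuals data.frame from [sampleIndividuals()].
#' @param isoscapes named list of assignment [Isoscape-class] objects;
#'   defaults to [assignmentIsoscapes()].
#' @param q mass threshold.
#' @return A list: `coverage` and `meanPctAreaRemoved` (named by subset,
#'   e.g. `"S"`, `"S+O"`, `"S+O+Sr"`), `n`, `q`.
#' @export
coverageExperiment <- function(world, individuals, isoscapes = NULL,
                               q = 1/3) {
  if (is.null(isoscapes)) isoscapes <- assignmentIsoscapes(world)
  systems <- intersect(c("S", "O", "Sr"), names(individuals))
  n <- nrow(individuals)
  inReg <- NULL; removed <- NULL
  for (i in seq_len(n)) {
    meas <- data.frame(system = systems,
                       value = as.numeric(individuals[i, systems]))
    res <- assignOrigin(meas, isoscapes, q = q)
    hit <- vapply(res$regions, function(r)
      r@included[individuals$true_row[i], individuals$true_col[i]],
      logical(1))
    if (is.null(inReg)) {
      inReg <- matrix(0, n, length(hit), dimnames = list(NULL, names(hit)))
      removed <- inReg
    }
    inReg[i, ] <- hit
    removed[i, ] <- res$pctAreaRemoved[colnames(removed)]
  }
  list(coverage = colMeans(inReg), meanPctAreaRemoved = colMeans(removed),
       n = n, q = q)
}

#' Run the full pipeline end-to-end on a synthetic world
#'
#' Exercises every stage against known ground truth with one seed:
#' generate world -> sample and screen a compilation -> site averages ->
#' covariate extraction -> two-stage variable selection -> repeated
#' cross-validation -> final forest and constant-RMSE sulfur isoscape ->
#' sample known-origin individuals (measurement noise at the true
#' individual-level SDs; oxygen measured as enamel carbonate and converted
#' through the chain) -> assignment of singles, duals and the triple against
#' the predicted sulfur isoscape with constant-RMSE uncertainty.
#'
#' @param ws a [worldSpec()]; its seed is replaced by `seed`.
#' @param nSites,perSiteN compilation size.
#' @param nIndividuals number of assigned individuals.
#' @param q region mass threshold.
#' @param seed integer seed for the entire experiment.
#' @return A list of class `EndToEndReport`: `summary`
#'   (`CompilationSummary`), `selection`, `cv`, `cvR2`, `cvRmse`,
#'   `selectionRecall` (fraction of the informative covariates selected),
#'   `nDecoysSelected`, `isoscapeRmseVsTruth` (grid-wide RMSE of the
#'   predicted vs true surface), `coverage`, `meanPctAreaRemoved` (per
#'   subset), `world`, `isoscape`, `seed`.
#' @export
endToEndExperiment <- function(ws = worldSpec(), nSites = 200,
                               perSiteN = ws$perSiteN, nIndividuals = 500,
                               q = 1/3, seed = ws$seed) {
  ws$seed <- seed
  world <- syntheticWorld(ws)

  records <- sampleSites(world, nSites = nSites, perSiteN = perSiteN,
                         seed = deriveSeed(seed, 1L))
  scr <- screenRecords(records)
  sites <- siteAverage(scr$kept)
  summ <- summarizeCompilation(sites)

  covM <- suppressWarnings(extractAtPoints(world$stack, sites))
  ds <- regressionDataset(sites, covM)
  sel <- selectVariables(ds, seed = deriveSeed(seed, 2L))
  cv <- crossValidate(ds, sel$selected, seed = deriveSeed(seed, 3L))
  fm <- fitForest(ds, sel$selected, seed = deriveSeed(seed, 4L))
  isoS <- predictIsoscape(fm, world$stack, constantRmse = cv$rmse)

  # noise SDs come from the true isoscapes (well-specified individuals);
  # assignment then uses the predicted sulfur surface with RMSE uncertainty
  isos <- assignmentIsoscapes(world)
  indiv <- sampleIndividuals(world, n = nIndividuals,
                             seed = deriveSeed(seed, 5L), isoscapes = isos)
  isos$S <- isoS
  # oxygen measured as enamel carbonate (VPDB) and brought back to the
  # water scale through the conversion chain (exactly invertible)
  carb <- smowToPdb(phosphateToCarbonate(waterToPhosphate(
    oxygenValues(indiv$O, "VSMOW", "water"))))
  indiv$O <- oxValue(tissueToWater(oxValue(carb)))

  covr <- coverageExperiment(world, indiv, isoscapes = isos, q = q)

  informative <- c("r.ssa", "r.dust", "r.bouguer")
  truth <- world$isoscapes$S@mean@values
  pred <- isoS@mean@values
  both <- !is.na(truth) & !is.na(pred)

  out <- list(summary = summ, selection = sel, cv = cv,
              cvR2 = cv$r2, cvRmse = cv$rmse,
              selectionRecall = mean(informative %in% sel$selected),
              nDecoysSelected = sum(grepl("^decoy", sel$selected)),
              isoscapeRmseVsTruth = sqrt(mean((pred[both] - truth[both])^2)),
              coverage = covr$coverage,
              meanPctAreaRemoved = covr$meanPctAreaRemoved,
              world = world, isoscape = isoS, seed = seed)
  class(out) <- "EndToEndReport"
  out
}

#' @export
print.EndToEndReport <- function(x, ...) {
  cat("End-to-end synthetic experiment (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  compilation: %d records, %d sites, mean site SD %.2f permil\n",
              x$summary$n_records, x$summary$n_sites, x$summary$mean_site_sd))
  cat(sprintf("  selection: %s (recall %.2f, %d decoys)\n",
              paste(x$selection$selected, collapse = ", "),
              x$selectionRecall, x$nDecoysSelected))
  cat(sprintf("  CV: R2 %.3f, RMSE %.2f permil; grid RMSE vs truth %.2f\n",
              x$cvR2, x$cvRmse, x$isoscapeRmseVsTruth))
  cat("  mean % area removed: ",
      paste(sprintf("%s %.1f", names(x$meanPctAreaRemoved),
                    x$meanPctAreaRemoved), collapse = ", "), "\n", sep = "")
  cat("  coverage at q: ",
      paste(sprintf("%s %.2f", names(x$coverage), x$coverage),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
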