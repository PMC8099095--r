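#' Pipeline configuration
#'
#' `defaultConfig()` returns the full configuration tree with every default
#' at its conventional value: screening thresholds C/S < 300 and N/S < 100,
#' 10 x 5 cross-validation splits at 80% training, oxygen conversion-chain
#' coefficients with a 1 permil summary uncertainty combined in quadrature,
#' and highest-mass region threshold q = 1/3. `readConfig()` loads a YAML
#' file and merges it over the defaults (unknown keys are kept).
#'
#' @param path path to a YAML configuration file.
#' @return A nested named list.
#' @export
defaultConfig <- function() {
  list(
    columns = list(),
    screening = list(cs_max = 300, ns_max = 100, nonlocal_km = 100),
    grid = list(crs = "local"),
    model = list(ntree = 500, nodesize = 5, n_rank_forests = 25,
                 importance_sd_multiplier = 3, addition_tolerance = 0,
                 n_forests_per_step = 10),
    cv = list(folds = 10, repeats = 5, train_fraction = 0.8),
    oxygen = list(assume_input_scale = "VPDB",
                  uncertainty_mode = "quadrature", chain_sd = 1.0),
    assignment = list(q = 1/3, threshold_mode = "mass"),
    seed = 1)
}

#' @rdname defaultConfig
#' @export
readConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  mergeLists <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        mergeLists(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  mergeLists(defaultConfig(), usr)
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

# Manifest: artifact list, input hashes, embedded config and seed.
# Deliberately carries no timestamps so reruns are byte-identical.
.writeManifest <- function(dir, artifacts, inputs, config, seed) {
  man <- list(
    artifacts = as.list(sort(artifacts)),
    inputs = as.list(tools::md5sum(inputs)[sort(names(tools::md5sum(inputs)))]),
    config = config,
    seed = seed)
  .writeJson(man, file.path(dir, "manifest.json"))
}

.writeCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Emit a complete synthetic fixture set
#'
#' Generates a synthetic world and writes every input the downstream stages
#' consume: one ASCII grid per covariate layer, the land mask and
#' distance-to-coast grids, true isoscape mean/sd pairs for all three
#' systems, the record-level compilation CSV, a per-site truth CSV and a
#' known-origin individuals CSV (oxygen reported as enamel carbonate on
#' VPDB). Deterministic given `seed`.
#'
#' @param outDir output directory (created if needed).
#' @param ws a [worldSpec()]; its seed is replaced by `seed`.
#' @param nSites,perSiteN,nIndividuals fixture sizes.
#' @param seed integer seed.
#' @return Invisibly, the output directory.
#' @export
runSimulate <- function(outDir, ws = worldSpec(), nSites = 200,
                        perSiteN = ws$perSiteN, nIndividuals = 100,
                        seed = ws$seed) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ws$seed <- seed
  world <- syntheticWorld(ws)
  arts <- character(0)
  wgrid <- function(grid, nm) {
    p <- file.path(outDir, paste0(nm, ".asc"))
    writeAsciiGrid(grid, p)
    arts <<- c(arts, basename(p))
  }
  for (nm in layerNames(world$stack))
    wgrid(world$stack@layers[[nm]], nm)
  wgrid(world$landMask, "land_mask")
  wgrid(world$distance, "distance_km")
  for (sys in names(world$isoscapes)) {
    wgrid(world$isoscapes[[sys]]@mean, paste0("true_", sys, "_mean"))
    wgrid(world$isoscapes[[sys]]@sd, paste0("true_", sys, "_sd"))
  }

  records <- sampleSites(world, nSites = nSites, perSiteN = perSiteN,
                         seed = deriveSeed(seed, 1L))
  .writeCsv(records, file.path(outDir, "compilation.csv"))
  cells <- attr(records, "cells")
  truth <- data.frame(site_id = sprintf("S%04d", seq_along(cells)),
                      cell = cells,
                      true_d34S = world$isoscapes$S@mean@values[cells])
  .writeCsv(truth, file.path(outDir, "site_truth.csv"))

  indiv <- sampleIndividuals(world, n = nIndividuals,
                             seed = deriveSeed(seed, 5L))
  carb <- smowToPdb(phosphateToCarbonate(waterToPhosphate(
    oxygenValues(indiv$O, "VSMOW", "water"))))
  indiv$d18O_carbonate <- oxValue(carb)
  .writeCsv(indiv, file.path(outDir, "individuals.csv"))
  arts <- c(arts, "compilation.csv", "site_truth.csv", "individuals.csv")

  .writeManifest(outDir, arts, inputs = character(0),
                 config = list(world = ws[setdiff(names(ws), "spec")],
                               n_sites = nSites, per_site_n = perSiteN,
                               n_individuals = nIndividuals), seed = seed)
  invisible(outDir)
}

#' Build a sulfur isoscape from a compilation and covariate grids
#'
#' Full isoscape construction stage: load and screen the compilation,
#' average per site, extract covariates, select variables, cross-validate,
#' fit the final forest and predict the mean surface with constant-RMSE
#' uncertainty. Writes six artifacts — `screened.csv`, `sites.csv`,
#' `selection.json`, `cv.json`, `isoscape_mean.asc`, `isoscape_sd.asc` —
#' plus a `manifest.json` recording artifact names, input file hashes, the
#' embedded configuration and the seed.
#'
#' @param outDir output directory.
#' @param compilation path to the compilation CSV/XLSX.
#' @param covariates either a directory containing one `.asc` file per
#'   covariate layer, or a named character vector of `.asc` paths.
#' @param config configuration list (see [defaultConfig()]).
#' @return Invisibly, a list with the fitted objects (`screen`, `sites`,
#'   `selection`, `cv`, `model`, `isoscape`) and `outDir`.
#' @export
runBuildIsoscape <- function(outDir, compilation, covariates,
                             config = defaultConfig()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  if (length(covariates) == 1L && dir.exists(covariates))
    covariates <- list.files(covariates, pattern = "\\.asc$",
                             full.names = TRUE)
  if (is.null(names(covariates)) || any(names(covariates) == ""))
    names(covariates) <- sub("\\.asc$", "", basename(covariates))

  records <- loadCompilation(compilation, columns = config$columns,
                             coords = if (config$grid$crs == "local")
                               "projected" else "wgs84")
  scr <- screenRecords(records, csMax = config$screening$cs_max,
                       nsMax = config$screening$ns_max)
  sites <- siteAverage(scr$kept)
  layers <- lapply(names(covariates), function(nm)
    readAsciiGrid(covariates[[nm]], crs = config$grid$crs, name = nm))
  names(layers) <- names(covariates)
  stack <- covariateStack(layers)
  covM <- suppressWarnings(extractAtPoints(stack, sites))
  ds <- regressionDataset(sites, covM)

  mc <- config$model
  sel <- selectVariables(ds, nRankForests = mc$n_rank_forests,
                         importanceSdMultiplier = mc$importance_sd_multiplier,
                         additionTolerance = mc$addition_tolerance,
                         nForestsPerStep = mc$n_forests_per_step,
                         ntree = mc$ntree, seed = deriveSeed(seed, 2L))
  cv <- crossValidate(ds, sel$selected, folds = config$cv$folds,
                      repeats = config$cv$repeats,
                      trainFraction = config$cv$train_fraction,
                      ntree = mc$ntree, seed = deriveSeed(seed, 3L))
  fm <- fitForest(ds, sel$selected, ntree = mc$ntree,
                  nodesize = mc$nodesize, seed = deriveSeed(seed, 4L))
  iso <- predictIsoscape(fm, stack, constantRmse = cv$rmse)

  .writeCsv(scr$kept, file.path(outDir, "screened.csv"))
  .writeCsv(sites, file.path(outDir, "sites.csv"))
  .writeJson(list(selected = sel$selected,
                  elimination_threshold = sel$eliminationThreshold,
                  ranked = sel$ranked, oob_path = sel$oobPath),
             file.path(outDir, "selection.json"))
  .writeJson(list(scheme = cv$scheme, rmse = cv$rmse, r2 = cv$r2,
                  resid_shapiro_W = cv$residShapiroW,
                  resid_shapiro_p = cv$residShapiroP,
                  per_fold = cv$perFold),
             file.path(outDir, "cv.json"))
  writeAsciiGrid(iso@mean, file.path(outDir, "isoscape_mean.asc"))
  writeAsciiGrid(iso@sd, file.path(outDir, "isoscape_sd.asc"))
  .writeManifest(outDir,
                 artifacts = c("screened.csv", "sites.csv", "selection.json",
                               "cv.json", "isoscape_mean.asc",
                               "isoscape_sd.asc"),
                 inputs = c(compilation, unname(covariates)),
                 config = config, seed = seed)
  invisible(list(screen = scr, sites = sites, selection = sel, cv = cv,
                 model = fm, isoscape = iso, outDir = outDir))
}

#' Batch-convert enamel carbonate d18O to drinking water
#'
#' Reads a CSV with a `d18O_carbonate` column, applies [tissueToWater()] to
#' every row and writes the input plus `d18O_water` and `d18O_water_sd`
#' columns. An input with zero rows produces a header-only output.
#'
#' @param input,output CSV paths.
#' @param config configuration list (uses the `oxygen` block).
#' @return Invisibly, the output data.frame.
#' @export
runConvertOxygen <- function(input, output, config = defaultConfig()) {
  df <- utils::read.csv(input)
  if (!"d18O_carbonate" %in% names(df))
    stop("input must have a 'd18O_carbonate' column", call. = FALSE)
  params <- conversionParams(chainSd = config$oxygen$chain_sd)
  if (nrow(df) > 0) {
    w <- tissueToWater(df$d18O_carbonate, params,
                       assumeInputScale = config$oxygen$assume_input_scale)
    df$d18O_water <- oxValue(w)
    df$d18O_water_sd <- rep_len(oxSd(w), nrow(df))
  } else {
    df$d18O_water <- numeric(0)
    df$d18O_water_sd <- numeric(0)
  }
  .writeCsv(df, output)
  invisible(df)
}

#' Assign individuals against isoscape rasters
#'
#' Reads long-format measurements (`individual_id`, `system`, `value`,
#' optional `measurement_sd`; oxygen values must already be
#' water-equivalent) and mean/sd isoscape raster pairs, runs
#' [assignOrigin()] for every individual over every subset of its measured
#' systems, and writes `summary.csv` / `summary.json` (one row per
#' individual x subset: percent area removed, mass captured, mode cell) plus
#' optional per-surface grids.
#'
#' @param outDir output directory.
#' @param measurements path to the measurements CSV.
#' @param isoscapePaths named list (by system) of length-2 character vectors
#'   `c(mean = path, sd = path)` of ASCII grids.
#' @param config configuration list.
#' @param writeSurfaces also write per-individual joint probability and
#'   region grids.
#' @return Invisibly, the summary data.frame.
#' @export
runAssign <- function(outDir, measurements, isoscapePaths,
                      config = defaultConfig(), writeSurfaces = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  meas <- utils::read.csv(measurements)
  isos <- lapply(names(isoscapePaths), function(sys) {
    p <- isoscapePaths[[sys]]
    isoscape(sys, readAsciiGrid(p[["mean"]], crs = config$grid$crs),
             readAsciiGrid(p[["sd"]], crs = config$grid$crs))
  })
  names(isos) <- names(isoscapePaths)

  q <- config$assignment$q
  mode <- config$assignment$threshold_mode
  rows <- list(); arts <- c("summary.csv", "summary.json")
  for (id in unique(meas$individual_id)) {
    mi <- meas[meas$individual_id == id, , drop = FALSE]
    res <- assignOrigin(mi, isos, q = q, mode = mode)
    for (nm in names(res$pctAreaRemoved)) {
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = id, subset = nm,
        n_systems = length(strsplit(nm, "+", fixed = TRUE)[[1L]]),
        pct_area_removed = res$pctAreaRemoved[[nm]],
        mass_captured = res$massCaptured[[nm]],
        mode_row = res$modeCell["row"], mode_col = res$modeCell["col"])
    }
    if (writeSurfaces) {
      joint <- names(res$surfaces)[length(res$surfaces)]
      sp <- sprintf("%s_joint_prob.asc", id)
      rp <- sprintf("%s_joint_region.asc", id)
      writeAsciiGrid(rasterGrid(res$surfaces[[joint]]@probs,
                                res$surfaces[[joint]]@spec, "prob"),
                     file.path(outDir, sp))
      writeAsciiGrid(rasterGrid(res$regions[[joint]]@included * 1,
                                res$regions[[joint]]@spec, "region"),
                     file.path(outDir, rp))
      arts <- c(arts, sp, rp)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  .writeCsv(summary, file.path(outDir, "summary.csv"))
  .writeJson(summary, file.path(outDir, "summary.json"))
  .writeManifest(outDir, artifacts = arts,
                 inputs = c(measurements,
                            unname(unlist(isoscapePaths))),
                 config = config, seed = config$seed)
  invisible(summary)
}
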