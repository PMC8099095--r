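#' Assemble the regression dataset
#'
#' Joins site-averaged d34S values with extracted covariates into the
#' regression matrix: one row per site with a complete covariate vector.
#' Sites with any missing covariate (nodata cell, outside extent) are
#' dropped.
#'
#' @param sites data.frame from [siteAverage()].
#' @param covMatrix data.frame from [extractAtPoints()] (column `site_id`
#'   plus one column per covariate).
#' @return A list of class `RegressionDataset`: `sites` (the retained site
#'   rows), `X` (data.frame of covariates), `y` (numeric site mean d34S),
#'   `variables` (covariate names).
#' @export
regressionDataset <- function(sites, covMatrix) {
  vars <- setdiff(names(covMatrix), c("site_id", "x", "y"))
  m <- merge(sites, covMatrix, by = "site_id", sort = TRUE)
  keep <- stats::complete.cases(m[, vars, drop = FALSE])
  if (sum(keep) == 0L) stop("no sites with complete covariates", call. = FALSE)
  m <- m[keep, , drop = FALSE]
  out <- list(sites = m[, names(sites), drop = FALSE],
              X = m[, vars, drop = FALSE],
              y = m$mean_d34S, variables = vars)
  class(out) <- "RegressionDataset"
  out
}

#' @export
print.RegressionDataset <- function(x, ...) {
  cat(sprintf("RegressionDataset: %d sites x %d covariates\n",
              length(x$y), length(x$variables)))
  cat("  ", paste(x$variables, collapse = ", "), "\n", sep = "")
  invisible(x)
}

.rfDefaults <- function(p) {
  list(ntree = 500L, mtry = max(1L, floor(p / 3)), nodesize = 5L)
}

.oobRmse <- function(rf, y) sqrt(mean((y - rf$predicted)^2))

#' Two-stage variable selection for the isoscape regression
#'
#' Selects a parsimonious predictor set in two stages, following the
#' rank-then-add strategy of forest-based variable selection:
#'
#' 1. *Ranking/elimination*: permutation importance (mean increase in OOB
#'    MSE when the variable is permuted) is averaged over `nRankForests`
#'    forests; variables whose mean importance falls below
#'    `importanceSdMultiplier` times the SD of the importances among the
#'    lowest-ranked half of the variables are eliminated. The lowest-ranked
#'    half estimates the noise scale of the importance measure, and the
#'    default multiplier of 3 applies the usual three-sigma exclusion
#'    against it; this stage is the decisive filter, because spurious
#'    sample correlations give uninformative variables persistently nonzero
#'    importance that no amount of forest averaging removes. When even the
#'    lowest-ranked variables carry substantial importance (more than 10% of
#'    the top variable's), no noise floor can be estimated and elimination
#'    is skipped: stage 2 arbitrates among all positive-importance
#'    variables.
#' 2. *Stepwise addition*: surviving variables are added in rank order; an
#'    addition is kept only if it lowers the out-of-bag RMSE — averaged over
#'    `nForestsPerStep` forests to stabilize the accept/reject decision — by
#'    more than `additionTolerance` relative to the best model so far (the
#'    starting point is the intercept-only RMSE, i.e. the SD of `y`). The
#'    default tolerance of 0 accepts any averaged improvement — appropriate
#'    once stage 1 has removed uninformative candidates, and deliberately
#'    permissive so weak true predictors are not lost; `NULL` switches to an
#'    adaptive tolerance (the SD of the replicate OOB RMSE estimates).
#'
#' @param ds a `RegressionDataset` from [regressionDataset()].
#' @param nRankForests forests averaged in the ranking stage.
#' @param importanceSdMultiplier elimination threshold multiplier.
#' @param additionTolerance minimum OOB RMSE improvement (permil) an addition
#'   must deliver; 0 (default) for the any-improvement rule, `NULL` for the
#'   adaptive rule above.
#' @param nForestsPerStep forests averaged per candidate model in stage 2.
#' @param ntree trees per forest.
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @return A list of class `SelectionResult`: `ranked` (data.frame of
#'   variable, importance, in rank order), `selected` (character),
#'   `eliminationThreshold`, `oobPath` (data.frame variable_added, oob_rmse
#'   for every accepted addition, starting from the intercept baseline).
#' @export
selectVariables <- function(ds, nRankForests = 25, importanceSdMultiplier = 3,
                            additionTolerance = 0, nForestsPerStep = 10,
                            ntree = 500, seed = 1) {
  p <- length(ds$variables)
  if (p < 2L) stop("need at least 2 candidate variables", call. = FALSE)
  if (length(ds$y) < 20L) stop("need at least 20 rows", call. = FALSE)
  hp <- .rfDefaults(p)

  impMat <- matrix(NA_real_, p, nRankForests,
                   dimnames = list(ds$variables, NULL))
  for (i in seq_len(nRankForests)) {
    set.seed(deriveSeed(seed, i))
    rf <- randomForest::randomForest(ds$X, ds$y, ntree = ntree,
                                     mtry = hp$mtry, nodesize = hp$nodesize,
                                     importance = TRUE)
    impMat[, i] <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1L]
  }
  imp <- rowMeans(impMat)
  ord <- order(imp, decreasing = TRUE)
  ranked <- data.frame(variable = ds$variables[ord], importance = imp[ord],
                       row.names = NULL)
  nLow <- max(2L, floor(p / 2))
  lowImp <- ranked$importance[(p - nLow + 1L):p]
  threshold <- importanceSdMultiplier * stats::sd(lowImp)
  if (all(lowImp > 0.1 * ranked$importance[1L])) {
    # every low-ranked variable still carries substantial importance: there
    # is no noise floor to estimate a threshold from, so elimination is
    # skipped and stage 2 arbitrates among all positive-importance variables
    threshold <- 0
  }
  surviving <- ranked$variable[ranked$importance > threshold]
  if (length(surviving) == 0L)
    stop("all variables eliminated at the ranking stage; consider relaxing ",
         "importanceSdMultiplier", call. = FALSE)

  baseline <- sqrt(mean((ds$y - mean(ds$y))^2))
  selected <- character(0)
  bestRmse <- baseline
  oobPath <- data.frame(variable_added = "(none)", oob_rmse = baseline)
  step <- 0L
  for (v in surviving) {
    step <- step + 1L
    cand <- c(selected, v)
    hpc <- .rfDefaults(length(cand))
    rmses <- vapply(seq_len(nForestsPerStep), function(j) {
      set.seed(deriveSeed(seed, 1000L + 50L * step + j))
      rf <- randomForest::randomForest(ds$X[, cand, drop = FALSE], ds$y,
                                       ntree = ntree, mtry = hpc$mtry,
                                       nodesize = hpc$nodesize)
      .oobRmse(rf, ds$y)
    }, numeric(1))
    rmse <- mean(rmses)
    tol <- if (is.null(additionTolerance)) stats::sd(rmses)
      else additionTolerance
    if (bestRmse - rmse > tol) {
      selected <- cand
      bestRmse <- rmse
      oobPath <- rbind(oobPath,
                       data.frame(variable_added = v, oob_rmse = rmse))
    }
  }
  out <- list(ranked = ranked, selected = selected,
              eliminationThreshold = threshold, oobPath = oobPath)
  class(out) <- "SelectionResult"
  out
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat("Variable selection (", nrow(x$ranked), " candidates, threshold ",
      signif(x$eliminationThreshold, 4), ")\n", sep = "")
  cat("  selected: ", paste(x$selected, collapse = ", "), "\n", sep = "")
  cat("  OOB path:\n")
  print(x$oobPath, row.names = FALSE)
  invisible(x)
}

#' Fit the isoscape random forest
#'
#' Fits a random forest regression of site-mean d34S on the given covariates.
#' Defaults follow common regression-forest practice: 500 trees, `p/3`
#' features tried per split, minimum node size 5. Out-of-bag predictions and
#' permutation importance are retained. Deterministic given `seed`.
#'
#' @param ds a `RegressionDataset`.
#' @param variables covariates to use (subset of `ds$variables`).
#' @param ntree,mtry,nodesize forest hyperparameters (`mtry` defaults to
#'   `max(1, floor(p/3))`).
#' @param seed integer seed.
#' @param ... further arguments passed to [randomForest::randomForest()]
#'   (e.g. `replace`, `sampsize`).
#' @return A list of class `ForestModel`: `model` (the randomForest fit),
#'   `variables`, `yRange` (range of training response; forest predictions
#'   are mean aggregations, so predictions never leave it), `oobRmse`,
#'   `seed`.
#' @export
fitForest <- function(ds, variables = ds$variables, ntree = 500,
                      mtry = NULL, nodesize = 5, seed = 1, ...) {
  bad <- setdiff(variables, names(ds$X))
  if (length(bad))
    stop("unknown variable(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(ds$y) < nodesize)
    stop("fewer rows (", length(ds$y), ") than the minimum leaf size (",
         nodesize, ")", call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(length(variables) / 3))
  set.seed(deriveSeed(seed, 0L))
  rf <- randomForest::randomForest(ds$X[, variables, drop = FALSE], ds$y,
                                   ntree = ntree, mtry = mtry,
                                   nodesize = nodesize, importance = TRUE,
                                   ...)
  out <- list(model = rf, variables = variables, yRange = range(ds$y),
              oobRmse = .oobRmse(rf, ds$y), seed = seed)
  class(out) <- "ForestModel"
  out
}

#' @export
print.ForestModel <- function(x, ...) {
  cat(sprintf("ForestModel: %d trees on %s; OOB RMSE %.3f permil\n",
              x$model$ntree, paste(x$variables, collapse = ", "), x$oobRmse))
  invisible(x)
}

#' Repeated cross-validation of the isoscape regression
#'
#' Estimates predictive skill by repeated random train/test splits: `repeats`
#' repetitions of `folds` random partitions, each training on
#' `trainFraction` of the sites and predicting the held-out remainder
#' (default 10 splits x 5 repeats at 80/20). Setting `trainFraction = NULL`
#' switches to classic k-fold partitions (every site held out exactly once
#' per repeat). RMSE and R-squared are computed on the pooled held-out
#' predicted/observed pairs, never on training folds.
#'
#' @param ds a `RegressionDataset`.
#' @param variables covariates to use.
#' @param folds,repeats,trainFraction the scheme described above.
#' @param ntree trees per forest.
#' @param seed integer seed.
#' @return A list of class `CVReport`: `scheme`, `perFold` (data.frame of
#'   per-split rmse and r2), `pooled` (data.frame observed, predicted),
#'   `rmse`, `r2`, `residuals`, `residShapiroW`, `residShapiroP`.
#' @export
crossValidate <- function(ds, variables = ds$variables, folds = 10,
                          repeats = 5, trainFraction = 0.8, ntree = 500,
                          seed = 1) {
  n <- length(ds$y)
  if (folds > n) stop("more folds than rows", call. = FALSE)
  hp <- .rfDefaults(length(variables))
  X <- ds$X[, variables, drop = FALSE]
  obs <- pred <- numeric(0)
  perFold <- NULL
  split <- 0L
  for (r in seq_len(repeats)) {
    if (is.null(trainFraction)) {
      set.seed(deriveSeed(seed, 5000L + r))
      foldId <- sample(rep_len(seq_len(folds), n))
      holdouts <- lapply(seq_len(folds), function(k) which(foldId == k))
    } else {
      holdouts <- lapply(seq_len(folds), function(k) {
        set.seed(deriveSeed(seed, 5000L + 100L * r + k))
        sample(n, size = max(1L, round((1 - trainFraction) * n)))
      })
    }
    for (hold in holdouts) {
      split <- split + 1L
      set.seed(deriveSeed(seed, 20000L + split))
      rf <- randomForest::randomForest(X[-hold, , drop = FALSE], ds$y[-hold],
                                       ntree = ntree, mtry = hp$mtry,
                                       nodesize = hp$nodesize)
      ph <- predict(rf, X[hold, , drop = FALSE])
      obs <- c(obs, ds$y[hold]); pred <- c(pred, ph)
      sse <- sum((ds$y[hold] - ph)^2)
      sst <- sum((ds$y[hold] - mean(ds$y[hold]))^2)
      perFold <- rbind(perFold,
                       data.frame(split = split,
                                  rmse = sqrt(mean((ds$y[hold] - ph)^2)),
                                  r2 = 1 - sse / sst))
    }
  }
  resid <- obs - pred
  sw <- if (length(resid) >= 3L && length(resid) <= 5000L)
    stats::shapiro.test(resid) else NULL
  out <- list(scheme = list(folds = folds, repeats = repeats,
                            trainFraction = trainFraction),
              perFold = perFold,
              pooled = data.frame(observed = obs, predicted = pred),
              rmse = sqrt(mean(resid^2)),
              r2 = 1 - sum(resid^2) / sum((obs - mean(obs))^2),
              residuals = resid,
              residShapiroW = if (is.null(sw)) NA_real_
                else unname(sw$statistic),
              residShapiroP = if (is.null(sw)) NA_real_ else sw$p.value)
  class(out) <- "CVReport"
  out
}

#' @export
print.CVReport <- function(x, ...) {
  sch <- x$scheme
  cat(sprintf("Cross-validation: %d x %d splits (train fraction %s)\n",
              sch$folds, sch$repeats,
              if (is.null(sch$trainFraction)) "k-fold"
              else format(sch$trainFraction)))
  cat(sprintf("  pooled RMSE %.3f permil, R2 %.3f (%d held-out pairs)\n",
              x$rmse, x$r2, nrow(x$pooled)))
  invisible(x)
}

#' Permutation importance of a fitted forest
#'
#' Mean increase in out-of-bag MSE when each variable is permuted, as
#' recorded by the forest during fitting; the quantitative importance used
#' for ranking predictors.
#'
#' @param model a `ForestModel` from [fitForest()].
#' @return data.frame `variable`, `importance` (mean increase in MSE),
#'   ordered decreasing.
#' @export
variableImportance <- function(model) {
  imp <- randomForest::importance(model$model, type = 1, scale = FALSE)[, 1L]
  ord <- order(imp, decreasing = TRUE)
  data.frame(variable = names(imp)[ord], importance = unname(imp[ord]),
             row.names = NULL)
}

#' Partial dependence of the forest prediction on one covariate
#'
#' For each probe value `v`, sets the covariate to `v` for every training
#' row, predicts, and averages: the model's mean response as the covariate is
#' swept with all others held at their observed values.
#'
#' @param model a `ForestModel`.
#' @param ds the `RegressionDataset` the model was trained on.
#' @param variable covariate to sweep.
#' @param grid probe values; default 25 points spanning the observed range.
#' @return data.frame `value`, `prediction`.
#' @export
partialDependence <- function(model, ds, variable, grid = NULL) {
  if (!variable %in% model$variables)
    stop("unknown variable '", variable, "'", call. = FALSE)
  X <- ds$X[, model$variables, drop = FALSE]
  if (is.null(grid))
    grid <- seq(min(X[[variable]]), max(X[[variable]]), length.out = 25)
  pd <- vapply(grid, function(v) {
    Xv <- X; Xv[[variable]] <- v
    mean(predict(model$model, Xv))
  }, numeric(1))
  data.frame(value = grid, prediction = pd)
}

#' Predict the isoscape over a covariate stack
#'
#' Evaluates the fitted forest on every grid cell with complete covariates,
#' producing the mean surface; the uncertainty surface is constant and equal
#' to the supplied RMSE (the cross-validation RMSE of the final model), the
#' convention for forests without built-in spatial uncertainty. Cells where
#' any required layer is nodata are nodata in the output.
#'
#' @param model a `ForestModel`.
#' @param stack a [CovariateStack-class] providing every training variable.
#' @param constantRmse positive scalar, the constant 1-sd uncertainty
#'   (permil).
#' @param system isotope system tag for the resulting isoscape.
#' @param note provenance note.
#' @return An [Isoscape-class].
#' @export
predictIsoscape <- function(model, stack, constantRmse,
                            system = "S", note = "random-forest prediction") {
  missing <- setdiff(model$variables, layerNames(stack))
  if (length(missing))
    stop("stack is missing required layer(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  stopifnot(constantRmse > 0)
  spec <- stack@spec
  cols <- lapply(model$variables, function(nm)
    as.vector(stack@layers[[nm]]@values))
  names(cols) <- model$variables
  newX <- as.data.frame(cols)
  valid <- stats::complete.cases(newX)
  m <- matrix(NA_real_, spec@nrows, spec@ncols)
  if (any(valid))
    m[valid] <- predict(model$model, newX[valid, , drop = FALSE])
  meanGrid <- rasterGrid(m, spec, name = "d34S.mean")
  isoscape(system, meanGrid, constantRmse, note = note)
}
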