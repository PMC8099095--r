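# Small regression datasets built directly (bypassing the site/extraction
# plumbing) for focused model tests.
makeDs <- function(X, y) {
  structure(list(sites = data.frame(site_id = seq_along(y), mean_d34S = y),
                 X = as.data.frame(X), y = y,
                 variables = colnames(as.data.frame(X))),
            class = "RegressionDataset")
}

test_that("constant response gives constant predictions", {
  set.seed(1)
  ds <- makeDs(data.frame(a = runif(30), b = runif(30)), rep(7, 30))
  fm <- suppressWarnings(fitForest(ds, seed = 1))   # constant y is the point
  expect_true(all(abs(predict(fm$model, ds$X) - 7) < 1e-9))
})

test_that("a single full-sample tree recovers group means", {
  ds <- makeDs(data.frame(g = c(0, 0, 1, 1)), c(1, 3, 11, 13))
  # suppress the few-unique-values regression note: tiny n is the point here
  fm <- suppressWarnings(fitForest(ds, ntree = 1, nodesize = 2, seed = 1,
                                   replace = FALSE, sampsize = 4))
  expect_equal(unname(predict(fm$model, ds$X)), c(2, 2, 12, 12))
})

test_that("a dense noisy ramp is fit with high OOB skill", {
  set.seed(2)
  n <- 300
  x <- runif(n)
  y <- 10 * x + rnorm(n, 0, 1)     # noise SD = 10% of signal range
  ds <- makeDs(data.frame(x = x), y)
  fm <- fitForest(ds, seed = 2)
  oobR2 <- 1 - fm$oobRmse^2 / mean((y - mean(y))^2)
  expect_gt(oobR2, 0.8)
  # monotone step approximation of the ramp: strong rising trend with only
  # small local wiggles from the tree steps
  pd <- partialDependence(fm, ds, "x", grid = seq(0.1, 0.9, 0.1))
  expect_gt(cor(pd$value, pd$prediction), 0.98)
  expect_gt(pd$prediction[9] - pd$prediction[1], 6)
  expect_true(all(diff(pd$prediction) > -0.5))
})

test_that("predictions never leave the training response range", {
  set.seed(3)
  ds <- makeDs(data.frame(a = rnorm(80), b = rnorm(80)),
               rnorm(80, 8, 4))
  fm <- fitForest(ds, seed = 3)
  probe <- data.frame(a = rnorm(500, 0, 5), b = rnorm(500, 0, 5))
  p <- predict(fm$model, probe)
  expect_true(all(p >= fm$yRange[1] - 1e-9 & p <= fm$yRange[2] + 1e-9))
})

test_that("degenerate fits are refused", {
  ds <- makeDs(data.frame(a = 1:3), c(1, 2, 3))
  expect_error(fitForest(ds, seed = 1), "fewer rows")
  expect_error(fitForest(makeDs(data.frame(a = 1:30), rnorm(30)),
                         variables = "zz", seed = 1), "zz")
})

test_that("selection keeps an exact predictor and drops pure-noise decoys", {
  hits <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 100
    X <- as.data.frame(matrix(rnorm(n * 10), n,
                              dimnames = list(NULL, c("signal",
                                paste0("decoy", 1:9)))))
    y <- X$signal * 5
    ds <- makeDs(X, y)
    sel <- selectVariables(ds, nRankForests = 8, nForestsPerStep = 4,
                           ntree = 300, seed = s)
    if ("signal" %in% sel$selected &&
        !any(grepl("decoy", sel$selected))) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("selection on pure noise exercises the empty/error path", {
  outcomes <- vapply(1:3, function(s) {
    set.seed(200 + s)
    X <- as.data.frame(matrix(rnorm(60 * 6), 60,
                              dimnames = list(NULL, paste0("v", 1:6))))
    ds <- makeDs(X, rnorm(60))
    r <- tryCatch(selectVariables(ds, nRankForests = 6, nForestsPerStep = 3,
                                  ntree = 300, seed = s),
                  error = function(e) e)
    if (inherits(r, "error")) "error" else
      if (length(r$selected) <= 2) "small" else "large"
  }, character(1))
  expect_true(all(outcomes %in% c("error", "small")))
})

test_that("selection result structure is coherent", {
  set.seed(5)
  n <- 80
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  y <- 6 * X$a + 3 * X$b + rnorm(n)
  sel <- selectVariables(makeDs(X, y), nRankForests = 6,
                         nForestsPerStep = 4, ntree = 300, seed = 5)
  expect_true(all(sel$selected %in% sel$ranked$variable))
  # the OOB path is non-increasing at every accepted addition
  expect_true(all(diff(sel$oobPath$oob_rmse) < 0))
  expect_true(all(c("a", "b") %in% sel$selected))
  expect_error(selectVariables(makeDs(X[, 1, drop = FALSE], y)),
               "2 candidate")
  expect_error(selectVariables(makeDs(X[1:10, ], y[1:10])), "20 rows")
})

test_that("cross-validation is honest and calibrated in the noiseless limit", {
  set.seed(6)
  n <- 120
  x <- runif(n)
  ds <- makeDs(data.frame(x = x), 10 * x)
  cv <- crossValidate(ds, folds = 5, repeats = 2, seed = 6)
  expect_gt(cv$r2, 0.95)
  expect_lt(cv$rmse, 0.6)
  expect_equal(nrow(cv$pooled), 5 * 2 * round(0.2 * n))
  expect_error(crossValidate(makeDs(data.frame(x = 1:4), 1:4), folds = 10),
               "folds")
})

test_that("cross-validation on pure noise recovers the noise scale", {
  set.seed(7)
  n <- 150; sigma <- 2
  ds <- makeDs(data.frame(a = rnorm(n), b = rnorm(n)), rnorm(n, 0, sigma))
  cv <- crossValidate(ds, folds = 10, repeats = 2, seed = 7)
  expect_lt(abs(cv$r2), 0.2)               # no skill, within sampling error
  expect_lt(abs(cv$rmse - sigma) / sigma, 0.15)
})

test_that("k-fold partitions are reachable and hold every row out once", {
  set.seed(8)
  n <- 60
  ds <- makeDs(data.frame(x = runif(n)), rnorm(n))
  cv <- crossValidate(ds, folds = 6, repeats = 1, trainFraction = NULL,
                      seed = 8)
  expect_equal(nrow(cv$pooled), n)
})

test_that("shuffling the response destroys cross-validated skill", {
  set.seed(9)
  n <- 150
  x <- runif(n)
  y <- 8 * x + rnorm(n, 0, 1)
  ds <- makeDs(data.frame(x = x), y)
  real <- crossValidate(ds, folds = 5, repeats = 1, seed = 9)
  expect_gt(real$r2, 0.5)
  dsShuf <- makeDs(data.frame(x = x), sample(y))
  shuf <- crossValidate(dsShuf, folds = 5, repeats = 1, seed = 9)
  expect_lt(shuf$r2, 0.1)
})

test_that("permutation importance separates signal from decoys", {
  set.seed(10)
  n <- 150
  X <- data.frame(s = rnorm(n), d = rnorm(n))
  y <- 6 * X$s + rnorm(n, 0, 0.5)
  fm <- fitForest(makeDs(X, y), seed = 10)
  imp <- variableImportance(fm)
  expect_equal(imp$variable[1], "s")
  expect_gt(imp$importance[1], 0)
  # decoy importance is null up to noise, far below the signal
  expect_lt(abs(imp$importance[imp$variable == "d"]),
            0.05 * imp$importance[1])
})

test_that("duplicated covariates share their importance", {
  set.seed(11)
  n <- 200
  x <- rnorm(n)
  X <- data.frame(x1 = x, x2 = x, z = rnorm(n))
  y <- 5 * x + rnorm(n, 0, 0.5)
  fmDup <- fitForest(makeDs(X, y), seed = 11)
  impDup <- variableImportance(fmDup)
  single <- fitForest(makeDs(X[, c("x1", "z")], y), seed = 11)
  impSingle <- variableImportance(single)
  iS <- impSingle$importance[impSingle$variable == "x1"]
  i1 <- impDup$importance[impDup$variable == "x1"]
  i2 <- impDup$importance[impDup$variable == "x2"]
  expect_lt(i1, iS)                       # each copy individually reduced
  expect_lt(i2, iS)
  expect_gt(i1 + i2, 0.5 * iS)            # combined importance comparable
  expect_lt(i1 + i2, 2.0 * iS)
})

test_that("partial dependence is flat for ignored variables, identity-like otherwise", {
  set.seed(12)
  n <- 250
  X <- data.frame(x = runif(n), u = runif(n))
  y <- 10 * X$x
  # mtry = 2 lets every split choose the informative variable, so the
  # fitted model genuinely ignores u
  fm <- fitForest(makeDs(X, y), seed = 12, mtry = 2)
  pdU <- partialDependence(fm, makeDs(X, y), "u")
  expect_lt(diff(range(pdU$prediction)), 0.5)
  pdX <- partialDependence(fm, makeDs(X, y), "x",
                           grid = seq(0.15, 0.85, 0.1))
  expect_equal(pdX$prediction, 10 * pdX$value, tolerance = 0.15 * 10)
  expect_error(partialDependence(fm, makeDs(X, y), "nope"), "nope")
})

test_that("identical seeds give bit-identical models, CV and selection", {
  set.seed(13)
  n <- 80
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 4 * X$a + rnorm(n)
  ds <- makeDs(X, y)
  s1 <- selectVariables(ds, nRankForests = 4, nForestsPerStep = 3,
                        ntree = 200, seed = 99)
  s2 <- selectVariables(ds, nRankForests = 4, nForestsPerStep = 3,
                        ntree = 200, seed = 99)
  expect_identical(s1$ranked, s2$ranked)
  expect_identical(s1$oobPath, s2$oobPath)
  cv1 <- crossValidate(ds, folds = 4, repeats = 1, ntree = 200, seed = 99)
  cv2 <- crossValidate(ds, folds = 4, repeats = 1, ntree = 200, seed = 99)
  expect_identical(cv1$pooled, cv2$pooled)
  f1 <- fitForest(ds, ntree = 200, seed = 99)
  f2 <- fitForest(ds, ntree = 200, seed = 99)
  expect_identical(predict(f1$model, ds$X), predict(f2$model, ds$X))
  f3 <- fitForest(ds, ntree = 200, seed = 100)
  expect_false(identical(predict(f1$model, ds$X), predict(f3$model, ds$X)))
})

test_that("isoscape prediction covers the grid with constant uncertainty", {
  world <- smallWorld()
  set.seed(14)
  records <- sampleSites(world, nSites = 60, seed = 14)
  sites <- siteAverage(screenRecords(records)$kept)
  covM <- suppressWarnings(extractAtPoints(world$stack, sites))
  ds <- regressionDataset(sites, covM)
  fm <- fitForest(ds, c("r.ssa", "r.bouguer", "r.dust"), seed = 14)
  iso <- predictIsoscape(fm, world$stack, constantRmse = 2.8)

  land <- validMask(world$isoscapes$S)
  expect_equal(validMask(iso), land)
  expect_true(all(gridValues(isoSd(iso))[land] == 2.8))
  mv <- gridValues(isoMean(iso))
  expect_true(all(mv[land] >= fm$yRange[1] & mv[land] <= fm$yRange[2]))

  # re-evaluating at a training site's cell reproduces the fitted value
  rc <- cellFromXY(world$spec, covM$x[1], covM$y[1])
  expect_equal(mv[rc[1, 1], rc[1, 2]],
               unname(predict(fm$model, ds$X[ds$sites$site_id ==
                                               covM$site_id[1], ])))

  expect_error(predictIsoscape(fm, covariateStack(
    world$stack@layers["r.ssa"]), 2.8), "r.bouguer")

  # constant-covariate world predicts a constant surface
  csta <- covariateStack(list(
    r.ssa = makeGrid(matrix(5, 4, 4)), r.bouguer = makeGrid(matrix(1, 4, 4)),
    r.dust = makeGrid(matrix(2, 4, 4))))
  flat <- predictIsoscape(fm, csta, 2.8)
  expect_equal(length(unique(as.vector(gridValues(isoMean(flat))))), 1L)
})
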