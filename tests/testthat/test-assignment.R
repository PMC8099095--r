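constIso <- function(mu, sd, n = 3, system = "S") {
  isoscape(system, makeGrid(matrix(mu, n, n), cellSize = 1000,
                            name = "mu"), sd)
}

test_that("z surfaces standardize against the isoscape", {
  iso <- constIso(12, 2.8)
  z0 <- zSurface(list(system = "S", value = 12), iso)
  expect_true(all(gridValues(z0) == 0))
  # measured collagen value of the documented local woman vs a cell
  z <- zSurface(list(system = "S", value = 14.7), iso)
  expect_equal(gridValues(z)[1, 1], (14.7 - 12) / 2.8, tolerance = 1e-9)
  # analytical uncertainty inflates the cell SD in quadrature
  z2 <- zSurface(list(system = "S", value = 14.7, measurement_sd = 2.1), iso)
  expect_equal(gridValues(z2)[1, 1], (14.7 - 12) / sqrt(2.8^2 + 2.1^2),
               tolerance = 1e-9)
  expect_equal(sqrt(2.8^2 + 2.1^2), 3.5)
  expect_error(zSurface(list(system = "O", value = 1), iso), "system")
})

test_that("likelihood surface evaluates the standard normal density", {
  z <- makeGrid(matrix(c(0, 1, -1, 2), 2, 2))
  f <- gridValues(likelihoodSurface(z))
  expect_lt(abs(f[1, 1] - 0.398942), 1e-6)
  expect_lt(abs(f[2, 1] - 0.241971), 1e-6)
  set.seed(4)
  a <- rnorm(100, 0, 3)
  fp <- gridValues(likelihoodSurface(makeGrid(matrix(a, 10, 10))))
  fm <- gridValues(likelihoodSurface(makeGrid(matrix(-a, 10, 10))))
  expect_equal(fp, fm, tolerance = 1e-12)   # even function
})

test_that("normalization yields a unit-mass surface", {
  lik <- makeGrid(matrix(c(0.3989, 0.2420), 1, 2))
  P <- normalizeSurface(lik)
  expect_equal(as.vector(gridValues(P)), c(0.62245, 0.37755),
               tolerance = 1e-4)
  expect_equal(sum(gridValues(P)), 1, tolerance = 1e-12)

  u <- normalizeSurface(makeGrid(matrix(1, 5, 5)))
  expect_true(all(abs(gridValues(u) - 1 / 25) < 1e-12))

  one <- makeGrid(matrix(c(NA, 0.7, NA, NA), 2, 2))
  expect_equal(sum(gridValues(normalizeSurface(one)), na.rm = TRUE), 1)

  expect_error(normalizeSurface(makeGrid(matrix(0, 2, 2))), "log space")
})

test_that("log-space path matches direct normalization and survives huge z", {
  set.seed(8)
  z <- makeGrid(matrix(rnorm(25), 5, 5))
  direct <- normalizeSurface(likelihoodSurface(z))
  logged <- probabilitySurfaceFromZ(z)
  expect_equal(gridValues(logged), gridValues(direct), tolerance = 1e-12)

  zbig <- makeGrid(matrix(c(40, 41, 80, 120), 2, 2))
  P <- probabilitySurfaceFromZ(zbig)
  expect_equal(sum(gridValues(P)), 1, tolerance = 1e-9)
  expect_true(gridValues(P)[1, 1] > gridValues(P)[2, 1])
})

test_that("combining surfaces multiplies and renormalizes", {
  P <- makeSurface(matrix(c(0.8, 0.2), 1, 2))
  U <- makeSurface(matrix(c(0.5, 0.5), 1, 2))
  J <- combineSurfaces(list(P, U))
  expect_equal(as.vector(gridValues(J)), c(0.8, 0.2), tolerance = 1e-12)

  set.seed(13)
  A <- makeSurface(matrix(runif(4), 2, 2))
  B <- makeSurface(matrix(runif(4), 2, 2))
  C <- makeSurface(matrix(runif(4), 2, 2))
  J1 <- combineSurfaces(list(A, B, C))
  J2 <- combineSurfaces(list(C, A, B))
  expect_equal(gridValues(J1), gridValues(J2), tolerance = 1e-12)

  D <- makeSurface(matrix(runif(9), 3, 3))
  expect_error(combineSurfaces(list(A, D)), "GridSpec")
  expect_error(combineSurfaces(list(A)), "at least two")
})

test_that("masks intersect when combining", {
  pa <- matrix(c(0.5, 0.5, NA, NA), 2, 2); pa <- pa / sum(pa, na.rm = TRUE)
  pb <- matrix(c(0.3, NA, 0.7, NA), 2, 2); pb <- pb / sum(pb, na.rm = TRUE)
  A <- new("ProbabilitySurface", spec = GridSpec(2, 2, 1000), probs = pa)
  B <- new("ProbabilitySurface", spec = GridSpec(2, 2, 1000), probs = pb)
  J <- combineSurfaces(list(A, B))
  expect_equal(gridValues(J)[1, 1], 1)          # only shared valid cell
  expect_equal(sum(!is.na(gridValues(J))), 1L)
})

test_that("highest-mass region matches hand-worked cases", {
  P <- makeSurface(matrix(c(0.4, 0.3, 0.15, 0.1, 0.05), 1, 5))
  r <- topMassRegion(P, 1/3)
  expect_equal(sum(includedCells(r)), 1L)
  expect_equal(which(includedCells(r)), 1L)
  expect_equal(massCaptured(r), 0.4)

  # total tie: a uniform surface includes everything at any q
  U <- makeSurface(matrix(1, 3, 3))
  expect_equal(sum(includedCells(topMassRegion(U, 1/3))), 9L)

  # q near 1 includes all valid cells
  expect_equal(sum(includedCells(topMassRegion(P, 0.999))), 5L)
})

test_that("highest-mass region matches the exhaustive oracle on small grids", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    w <- runif(n)
    w[sample(n, sample(0:2, 1))] <- w[1]      # inject ties
    P <- makeSurface(matrix(w, 1, n))
    q <- runif(1, 0.05, 0.95)
    got <- which(includedCells(topMassRegion(P, q)))
    expect_equal(got, bruteTopMass(as.vector(gridValues(P)), q))
  }
})

test_that("area-fraction thresholding is available as an alternative", {
  P <- makeSurface(matrix(c(5, 4, 3, 2, 1, 1), 1, 6))
  r <- topMassRegion(P, 1/3, mode = "area_fraction")
  expect_equal(sum(includedCells(r)), 2L)      # top third of 6 cells
})

test_that("percent area removed is cell counting on the equal-area grid", {
  P <- makeSurface(matrix(c(0.4, 0.3, 0.15, 0.1, 0.05), 1, 5))
  r <- topMassRegion(P, 1/3)
  expect_equal(pctAreaRemoved(r, 5), 80)
  expect_equal(pctAreaRemoved(topMassRegion(P, 0.999), 5), 0)
})

test_that("cell probability decreases monotonically with |x - mu|", {
  iso <- isoscape("S", makeGrid(matrix(seq(0, 24, length.out = 25), 5, 5),
                                name = "mu"), 2)
  res <- assignOrigin(data.frame(system = "S", value = 12), iso = list(S = iso))
  P <- res$surfaces[["S"]]
  d <- abs(gridValues(isoMean(iso)) - 12)
  ord <- order(d)
  expect_true(all(diff(gridValues(P)[ord]) <= 1e-15))
})

test_that("assignment orchestration: subsets, modes and errors", {
  set.seed(17)
  n <- 6
  muS <- matrix(rnorm(n * n, 10, 4), n, n)
  muO <- matrix(rnorm(n * n, -6, 1.5), n, n)
  muSr <- matrix(runif(n * n, 0.705, 0.715), n, n)
  isos <- list(S = isoscape("S", makeGrid(muS, name = "s"), 2),
               O = isoscape("O", makeGrid(muO, name = "o"), 1),
               Sr = isoscape("Sr", makeGrid(muSr, name = "r"), 0.002))
  truth <- c(4, 3)
  meas <- data.frame(system = c("S", "O", "Sr"),
                     value = c(muS[4, 3], muO[4, 3], muSr[4, 3]))
  res <- assignOrigin(meas, isos)
  expect_length(res$surfaces, 7L)             # 3 singles, 3 duals, 1 triple
  expect_equal(unname(res$modeCell), truth)   # exact match dominance
  expect_true(all(res$pctAreaRemoved >= 0 & res$pctAreaRemoved <= 100))

  # an individual measured on one system only is that system's surface
  resS <- assignOrigin(meas[1, ], isos)
  expect_equal(gridValues(resS$surfaces[["S"]]),
               gridValues(res$surfaces[["S"]]))

  expect_error(assignOrigin(meas, isos[c("S", "O")]), "Sr")
})

test_that("a Brittany-like fixture puts the dog's joint mode in the target zone", {
  # construct isoscapes whose north-west corner matches the dog's measured
  # values (collagen d34S 13.3, enamel d18Oc -5.0 -> water, 87Sr/86Sr 0.71270)
  n <- 10
  target <- cbind(rep(1:3, 3), rep(1:3, each = 3))   # NW 3x3 block
  muS <- matrix(6, n, n);  muS[target] <- 13.3
  muO <- matrix(-9, n, n); muO[target] <- oxValue(tissueToWater(-5.0))
  muSr <- matrix(0.708, n, n); muSr[target] <- 0.71270
  isos <- list(S = isoscape("S", makeGrid(muS, name = "s"), 2.8),
               O = isoscape("O", makeGrid(muO, name = "o"), 1.4),
               Sr = isoscape("Sr", makeGrid(muSr, name = "r"), 0.0018))
  meas <- data.frame(system = c("S", "O", "Sr"),
                     value = c(13.3, oxValue(tissueToWater(-5.0)), 0.71270))
  res <- assignOrigin(meas, isos)
  expect_true(res$modeCell["row"] <= 3 && res$modeCell["col"] <= 3)
  # the triple assignment is at least as precise as any single
  expect_true(res$pctAreaRemoved[["S+O+Sr"]] >=
                max(res$pctAreaRemoved[c("S", "O", "Sr")]) - 1e-9)
})

test_that("probability surfaces always sum to one and combine preserves it", {
  set.seed(23)
  for (k in 1:20) {
    z1 <- makeGrid(matrix(rnorm(36, 0, 6), 6, 6))
    z2 <- makeGrid(matrix(rnorm(36, 0, 6), 6, 6))
    P1 <- probabilitySurfaceFromZ(z1); P2 <- probabilitySurfaceFromZ(z2)
    expect_equal(sum(gridValues(P1)), 1, tolerance = 1e-9)
    J <- combineSurfaces(list(P1, P2))
    expect_equal(sum(gridValues(J), na.rm = TRUE), 1, tolerance = 1e-9)
  }
})
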