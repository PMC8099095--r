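test_that("cell containment follows the half-open convention", {
  spec <- GridSpec(4, 4, 1000)          # extent x [0,4000], y [0,4000]
  # interior point
  expect_equal(cellFromXY(spec, 1500, 3500)[1, ], c(row = 1L, col = 2L))
  # point on a vertical shared edge belongs to the cell on its right
  expect_equal(unname(cellFromXY(spec, 1000, 3500)[1, "col"]), 2L)
  # point on a horizontal shared edge belongs to the cell below
  expect_equal(unname(cellFromXY(spec, 500, 3000)[1, "row"]), 2L)
  # top edge belongs to row 1; bottom/right edges are outside
  expect_equal(unname(cellFromXY(spec, 500, 4000)[1, "row"]), 1L)
  expect_true(is.na(cellFromXY(spec, 4000, 500)[1, "col"]))
  expect_true(is.na(cellFromXY(spec, 500, 0)[1, "row"]))
})

test_that("cell containment matches a brute-force oracle", {
  spec <- GridSpec(7, 9, 500, xmin = -1000, ymax = 2500)
  set.seed(5)
  x <- runif(300, spec@xmin - 300, spec@xmax + 300)
  y <- runif(300, spec@ymin - 300, spec@ymax + 300)
  # include exact edges among the probes
  x[1:10] <- spec@xmin + (0:9) * spec@cellSize
  y[1:10] <- spec@ymax - (0:9) * spec@cellSize
  got <- cellFromXY(spec, x, y)
  for (k in seq_along(x)) {
    hit <- NA
    for (r in seq_len(spec@nrows)) for (cc in seq_len(spec@ncols)) {
      x0 <- spec@xmin + (cc - 1) * spec@cellSize
      y1 <- spec@ymax - (r - 1) * spec@cellSize
      inx <- x[k] >= x0 & x[k] < x0 + spec@cellSize
      iny <- y[k] <= y1 & y[k] > y1 - spec@cellSize
      if (r == 1L) iny <- iny | y[k] == spec@ymax
      if (inx && iny) hit <- c(r, cc)
    }
    if (all(is.na(hit))) expect_true(is.na(got[k, 1]))
    else expect_equal(unname(got[k, ]), hit)
  }
})

test_that("extraction picks the containing cell and flags nodata", {
  m <- matrix(1:9, 3, 3)
  m[2, 2] <- NA                       # sea cell
  stack <- covariateStack(list(v = makeGrid(m, cellSize = 1000)))
  pts <- data.frame(site_id = c("a", "b", "c"),
                    longitude = c(1500, 1500, 9999),
                    latitude = c(2500, 1500, 1500))
  expect_warning(expect_warning(cm <- extractAtPoints(stack, pts),
                                "outside"), "nodata")
  expect_equal(cm$v[1], m[1, 2])      # center of row-1/col-2 cell
  expect_true(is.na(cm$v[2]))         # nodata cell
  expect_true(is.na(cm$v[3]))         # outside extent
})

test_that("point at the center of a cell recovers its exact value", {
  m <- matrix(0, 3, 3); m[2, 3] <- 7.3
  stack <- covariateStack(list(v = makeGrid(m)))
  pt <- data.frame(site_id = "p", longitude = 2500, latitude = 1500)
  expect_equal(extractAtPoints(stack, pt)$v, 7.3)
})

test_that("Eckert IV projection round-trips and satisfies symmetries", {
  set.seed(9)
  lon <- runif(200, -179, 179); lat <- runif(200, -85, 85)
  xy <- eckert4Forward(lon, lat)
  ll <- eckert4Inverse(xy[, "x"], xy[, "y"])
  expect_equal(ll[, "lon"], lon, tolerance = 1e-9)
  expect_equal(ll[, "lat"], lat, tolerance = 1e-9)
  expect_equal(unname(eckert4Forward(0, 45)[1, "x"]), 0)
  expect_equal(unname(eckert4Forward(10, 0)[1, "y"]), 0)
  # antisymmetry in both axes
  expect_equal(eckert4Forward(-10, 20), -eckert4Forward(10, -20),
               ignore_attr = TRUE)
})

test_that("Eckert IV parametric angle matches an independent solver", {
  lats <- c(-80, -45, -10, 0, 15, 30, 60, 89)
  for (lat in lats) {
    phi <- lat * pi / 180
    # independent oracle: root-find the defining equation with uniroot
    g <- function(t) t + sin(t) * cos(t) + 2 * sin(t) - (2 + pi / 2) * sin(phi)
    theta <- uniroot(g, c(-pi / 2, pi / 2), tol = 1e-14)$root
    R <- 6371007.181
    expected <- 2 * sqrt(pi / (4 + pi)) * R * sin(theta)
    expect_equal(unname(eckert4Forward(0, lat)[1, "y"]), expected,
                 tolerance = 1e-9)
  }
})

test_that("resampling is the identity on the target spec and preserves constants", {
  m <- matrix(rnorm(12), 3, 4)
  g <- makeGrid(m)
  expect_equal(gridValues(resampleToGrid(g, gridSpec(g))), m)

  const <- makeGrid(matrix(5, 2, 2), cellSize = 2000)
  up <- GridSpec(4, 4, 1000)
  for (meth in c("nearest", "bilinear", "mode"))
    expect_true(all(gridValues(resampleToGrid(const, up, meth)) == 5))
})

test_that("bilinear resampling reproduces closed-form midpoint means", {
  # 1D ramp 0,2,4,6 across columns; doubling resolution puts new cell
  # centers exactly at the source centers and their midpoints
  src <- makeGrid(matrix(c(0, 2, 4, 6), 1, 4, byrow = TRUE),
                  cellSize = 2000)
  tgt <- GridSpec(2, 8, 1000)
  out <- gridValues(resampleToGrid(src, tgt, "bilinear"))
  # x positions 500,1500,...: alternating source centers and midpoints,
  # clamped at the edges
  expect_equal(out[1, ], c(0, 0.5, 1.5, 2.5, 3.5, 4.5, 5.5, 6))
})

test_that("resampling is idempotent and propagates nodata", {
  m <- matrix(rnorm(36), 6, 6); m[3, 3] <- NA
  src <- makeGrid(m, cellSize = 1000)
  tgt <- GridSpec(12, 12, 500)
  once <- resampleToGrid(src, tgt, "bilinear")
  twice <- resampleToGrid(once, tgt, "bilinear")
  expect_equal(gridValues(twice), gridValues(once))
  # all four target cells overlapping the nodata source center are NA
  expect_true(anyNA(gridValues(once)))

  near <- resampleToGrid(src, tgt, "nearest")
  expect_equal(sum(is.na(gridValues(near))), 4L)
})

test_that("longlat sources reproject onto the equal-area grid", {
  # constant field survives reprojection regardless of distortion
  llspec <- GridSpec(18, 36, 10, xmin = -180, ymax = 90, crs = "longlat")
  src <- rasterGrid(matrix(3.3, 18, 36), llspec, "c")
  xy <- eckert4Forward(c(-20, 20), c(35, 65))
  tgt <- GridSpec(10, 10, 200000, xmin = min(xy[, "x"]),
                  ymax = max(xy[, "y"]), crs = "eckert4")
  out <- resampleToGrid(src, tgt, "bilinear")
  expect_true(all(gridValues(out) == 3.3))
  # unsupported CRS pair fails naming the source CRS
  locsrc <- makeGrid(matrix(1, 2, 2))
  expect_error(resampleToGrid(locsrc, tgt), "local")
})

test_that("distance to coast matches the hand-derived 3x3 case", {
  m <- matrix(1, 3, 3); m[2, 2] <- 0      # single sea cell at center
  d <- distanceToCoast(makeGrid(m, cellSize = 1000))
  s2 <- sqrt(2)
  expect_equal(gridValues(d),
               matrix(c(s2, 1, s2, 1, 0, 1, s2, 1, s2), 3, 3),
               tolerance = 1e-9)
  # coastal land cell adjacent to sea is 1 cell away
  m2 <- matrix(1, 2, 3); m2[1, 1] <- 0
  d2 <- gridValues(distanceToCoast(makeGrid(m2, cellSize = 1000)))
  expect_equal(d2[1, 2], 1)
  expect_equal(d2[2, 1], 1)
})

test_that("degenerate masks are rejected", {
  expect_error(distanceToCoast(makeGrid(matrix(1, 3, 3))), "all land")
  expect_error(distanceToCoast(makeGrid(matrix(0, 3, 3))), "all sea")
})

test_that("distance to coast agrees with brute force on random masks", {
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(as.numeric(runif(30 * 30) > 0.2), 30, 30)
    if (all(m == 1) || all(m == 0)) next
    g <- makeGrid(m, cellSize = 1000)
    got <- gridValues(distanceToCoast(g))
    expect_equal(got, bruteDistanceToCoast(g), tolerance = 1e-9)
    # zero exactly on sea
    expect_true(all(got[m == 0] == 0))
    # 1-Lipschitz between horizontal/vertical neighbours, diagonal bound
    dx <- abs(got[, -1] - got[, -ncol(got)])
    dy <- abs(got[-1, ] - got[-nrow(got), ])
    expect_true(all(dx <= sqrt(2) + 1e-9))
    expect_true(all(dy <= sqrt(2) + 1e-9))
  }
})

test_that("ASCII grid files round-trip values, mask and georeferencing", {
  m <- matrix(rnorm(20), 4, 5); m[2, 3] <- NA
  g <- rasterGrid(m, GridSpec(4, 5, 1000, xmin = 100, ymax = 7000), "t")
  f <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(g, f)
  back <- readAsciiGrid(f)
  expect_equal(gridValues(back), m, tolerance = 1e-9)
  expect_equal(gridSpec(back)@xmin, 100)
  expect_equal(gridSpec(back)@ymax, 7000)
  expect_error(readAsciiGrid(withr::local_tempfile(fileext = ".asc")),
               "not found")
  bad <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "cellsize 1", "0 0"), bad)
  expect_error(readAsciiGrid(bad), "missing")
})
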