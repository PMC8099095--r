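# Shared fixtures, built in code at test time.

# Canonical record data.frame with sensible defaults, overridable per field.
makeRecords <- function(n = 3, site_id = "A", d34S = seq_len(n) + 9,
                        latitude = 48, longitude = -2,
                        pctC = 42, pctN = 15.5, pctS = 0.2, ...) {
  df <- data.frame(record_id = sprintf("r%02d", seq_len(n)),
                   site_id = site_id, latitude = latitude,
                   longitude = longitude, species = "x", period = "x",
                   d34S = d34S, d13C = NA_real_, d15N = NA_real_,
                   pctC = pctC, pctN = pctN, pctS = pctS,
                   CS_ratio = NA_real_, NS_ratio = NA_real_,
                   CN_ratio = NA_real_,
                   diagenesis_reported = FALSE, nonlocal_reported = FALSE,
                   aquatic_or_fish_consumer = FALSE, s_only = FALSE)
  df$CS_ratio <- df$pctC / df$pctS
  df$NS_ratio <- df$pctN / df$pctS
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

# Small raster on a local grid from a matrix.
makeGrid <- function(m, cellSize = 1000, name = "layer", crs = "local") {
  spec <- GridSpec(nrow(m), ncol(m), cellSize, crs = crs)
  rasterGrid(m, spec, name = name)
}

# Uniform-ish probability surface from nonnegative weights.
makeSurface <- function(w) {
  m <- as.matrix(w)
  p <- m / sum(m, na.rm = TRUE)
  new("ProbabilitySurface", spec = GridSpec(nrow(m), ncol(m), 1000),
      probs = p)
}

# A small synthetic world, built once per test run and reused.
.worldCache <- new.env(parent = emptyenv())
smallWorld <- function(seed = 42) {
  key <- paste0("w", seed)
  if (is.null(.worldCache[[key]]))
    .worldCache[[key]] <- syntheticWorld(
      worldSpec(nrows = 48, ncols = 48, cellSize = 10000, seed = seed))
  .worldCache[[key]]
}

# Brute-force O(n^2) distance-to-coast oracle (km).
bruteDistanceToCoast <- function(landMask) {
  m <- landMask@values
  cs <- landMask@spec@cellSize / 1000
  sea <- which(m == 0, arr.ind = TRUE)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j] == 0) next
    out[i, j] <- sqrt(min((sea[, 1] - i)^2 + (sea[, 2] - j)^2)) * cs
  }
  out
}

# Exhaustive minimal-prefix oracle for the highest-mass region.
bruteTopMass <- function(p, q) {
  ord <- order(p, decreasing = TRUE)
  cum <- cumsum(p[ord])
  k <- which(cum >= q - 1e-12)[1L]
  cut <- p[ord[k]]
  which(p >= cut)
}
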