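#' Standardized deviation surface for one tissue measurement
#'
#' For a measured tissue value `x*` and an isoscape with per-cell predicted
#' mean and SD, computes `z(c) = (x* - mu_c) / sigma_c` on every valid cell.
#' When the measurement carries analytical uncertainty, the cell SD is
#' inflated to `sqrt(sigma_c^2 + measurementSd^2)`.
#'
#' @param measurement a list or one-row data.frame with elements `system`
#'   (`"S"`, `"O"` or `"Sr"`), `value` (same units as the isoscape: permil
#'   for S and O-water-equivalent, ratio for Sr) and optional
#'   `measurement_sd` (default 0).
#' @param iso an [Isoscape-class] for the same system.
#' @return A [RasterGrid-class] of z values (nodata where the isoscape is
#'   nodata).
#' @export
zSurface <- function(measurement, iso) {
  sys <- as.character(measurement$system)
  if (!identical(sys, iso@system))
    stop("measurement system '", sys, "' does not match isoscape system '",
         iso@system, "'", call. = FALSE)
  msd <- measurement$measurement_sd
  if (is.null(msd) || is.na(msd)) msd <- 0
  sigma <- sqrt(iso@sd@values^2 + msd^2)
  z <- (measurement$value - iso@mean@values) / sigma
  rasterGrid(z, iso@mean@spec, name = paste0("z.", sys))
}

#' Standard-normal likelihood surface
#'
#' Evaluates the standard normal probability density
#' `f(z) = (1/sqrt(2*pi)) * exp(-z^2/2)` cellwise on a z surface: the
#' likelihood that each cell is the origin of the measured individual.
#'
#' @param z a [RasterGrid-class] of standardized deviations.
#' @return A [RasterGrid-class] of densities.
#' @export
likelihoodSurface <- function(z) {
  rasterGrid(stats::dnorm(z@values), z@spec,
             name = sub("^z\\.", "f.", z@name))
}

#' Normalize a likelihood surface to a probability-of-origin surface
#'
#' Divides cellwise likelihoods by their sum over the valid mask, yielding a
#' per-cell probability of origin relative to all other locations.
#'
#' @param lik a [RasterGrid-class] of nonnegative densities.
#' @return A [ProbabilitySurface-class].
#' @export
normalizeSurface <- function(lik) {
  tot <- sum(lik@values, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0)
    stop("likelihood surface sums to zero (numeric underflow); ",
         "use probabilitySurfaceFromZ() which normalizes in log space",
         call. = FALSE)
  new("ProbabilitySurface", spec = lik@spec, probs = lik@values / tot)
}

#' Probability surface from a z surface, computed in log space
#'
#' Numerically robust path from standardized deviations to a normalized
#' probability surface: log-densities are shifted by their maximum before
#' exponentiation, so surfaces survive arbitrarily large |z| without
#' underflow. Identical to
#' `normalizeSurface(likelihoodSurface(z))` whenever the direct path does not
#' underflow.
#'
#' @param z a [RasterGrid-class] of standardized deviations.
#' @return A [ProbabilitySurface-class].
#' @export
probabilitySurfaceFromZ <- function(z) {
  lg <- -z@values^2 / 2
  m <- max(lg, na.rm = TRUE)
  p <- exp(lg - m)
  new("ProbabilitySurface", spec = z@spec,
      probs = p / sum(p, na.rm = TRUE))
}

#' Combine single-isotope probability surfaces
#'
#' Under the assumption of independence between isotopic systems, the joint
#' probability of origin is the renormalized cellwise product of the
#' single-system surfaces. Masks are intersected; the product is accumulated
#' in log space with max-subtraction before renormalization.
#'
#' @param surfaces a list of two or more [ProbabilitySurface-class] objects
#'   on the identical [GridSpec-class].
#' @return A [ProbabilitySurface-class] on the intersected mask.
#' @export
combineSurfaces <- function(surfaces) {
  if (length(surfaces) < 2L)
    stop("need at least two surfaces to combine", call. = FALSE)
  spec <- surfaces[[1L]]@spec
  for (s in surfaces[-1L])
    if (!isTRUE(all.equal(s@spec, spec)))
      stop("surfaces must share an identical GridSpec", call. = FALSE)
  mask <- Reduce(`&`, lapply(surfaces, validMask))
  if (!any(mask))
    stop("no valid cells in the intersected mask", call. = FALSE)
  lg <- matrix(0, spec@nrows, spec@ncols)
  for (s in surfaces) lg <- lg + log(s@probs)
  lg[!mask] <- NA_real_
  valid <- mask & is.finite(lg)
  if (!any(valid))
    stop("joint surface is zero everywhere on the intersected mask",
         call. = FALSE)
  m <- max(lg[valid])
  p <- matrix(NA_real_, spec@nrows, spec@ncols)
  p[mask] <- exp(pmax(lg[mask] - m, -745))   # exp underflow floor -> 0
  p[mask & !is.finite(lg)] <- 0
  new("ProbabilitySurface", spec = spec, probs = p / sum(p[mask]))
}

#' Highest-posterior-mass region of a probability surface
#'
#' Thresholds a probability-of-origin surface at cumulative posterior mass
#' `q`: cells are ranked by decreasing probability and the shortest prefix
#' whose cumulative probability reaches `q` is included; cells tied with the
#' last included probability are all included, making the region
#' deterministic and permutation-invariant. This is the "highest q of the
#' probability distribution" rule used to define zones of high probability
#' (default q = 1/3).
#'
#' The alternative reading of the threshold — the top `q` fraction of valid
#' *cells* by probability value — is available as `mode = "area_fraction"`.
#'
#' @param P a [ProbabilitySurface-class].
#' @param q mass (or area) fraction in (0, 1); default 1/3.
#' @param mode `"mass"` (default, cumulative posterior mass) or
#'   `"area_fraction"`.
#' @return A [BinaryRegion-class].
#' @export
topMassRegion <- function(P, q = 1/3, mode = c("mass", "area_fraction")) {
  mode <- match.arg(mode)
  stopifnot(q > 0, q < 1)
  p <- as.vector(P@probs)
  valid <- which(!is.na(p))
  ord <- valid[order(p[valid], decreasing = TRUE)]
  if (mode == "mass") {
    cum <- cumsum(p[ord])
    k <- which(cum >= q - 1e-12)[1L]
    if (is.na(k)) k <- length(ord)
  } else {
    k <- ceiling(q * length(ord))
  }
  cut <- p[ord[k]]
  sel <- valid[p[valid] >= cut]      # include ties at the cut
  inc <- matrix(FALSE, P@spec@nrows, P@spec@ncols)
  inc[sel] <- TRUE
  new("BinaryRegion", spec = P@spec, included = inc, q = q,
      massCaptured = sum(p[sel]))
}

#' Percent of study area removed by a region
#'
#' The precision metric of a geographic assignment: the percentage of the
#' valid study area excluded from the high-probability region. On an
#' equal-area grid, areas are cell counts.
#'
#' @param region a [BinaryRegion-class].
#' @param totalValidCells number of valid cells in the study area (e.g.
#'   `sum(validMask(P))` of the surface the region came from).
#' @return Percentage in `[0, 100]`.
#' @export
pctAreaRemoved <- function(region, totalValidCells) {
  stopifnot(totalValidCells >= 1)
  100 * (1 - sum(region@included) / totalValidCells)
}

# All non-empty subsets of the measured systems, ordered singles, duals,
# triple; names like "S", "S+O", "S+O+Sr".
.systemSubsets <- function(systems) {
  subs <- list()
  for (k in seq_along(systems))
    subs <- c(subs, utils::combn(systems, k, simplify = FALSE))
  names(subs) <- vapply(subs, paste, character(1), collapse = "+")
  subs
}

#' Multi-isotope probabilistic geographic assignment of one individual
#'
#' Orchestrates the full assignment for one individual: for every measured
#' isotope system, a z surface, likelihood and normalized probability surface
#' against the matching isoscape; for every requested combination of systems,
#' the joint (product) surface; for each surface, the highest-mass region at
#' `q` and the percent of study area it removes.
#'
#' @param measurements data.frame with one row per measured system: columns
#'   `system`, `value`, optional `measurement_sd`. Oxygen values must already
#'   be on the drinking-water-equivalent scale (see [tissueToWater()]).
#' @param isoscapes named list of [Isoscape-class] objects keyed by system;
#'   every measured system must be present, and all isoscapes must share one
#'   [GridSpec-class].
#' @param q mass threshold for the high-probability regions.
#' @param subsets `"all"` (every non-empty combination of measured systems)
#'   or a list of character vectors of systems.
#' @param mode region thresholding mode, see [topMassRegion()].
#' @return A list of class `AssignmentResult`: `surfaces` (per-subset
#'   [ProbabilitySurface-class]), `regions` (per-subset
#'   [BinaryRegion-class]), `pctAreaRemoved` (named numeric),
#'   `massCaptured` (named numeric), `modeCell` (row/col of the joint-surface
#'   maximum for the largest subset), `systems`, `q`.
#' @export
assignOrigin <- function(measurements, isoscapes, q = 1/3, subsets = "all",
                         mode = c("mass", "area_fraction")) {
  mode <- match.arg(mode)
  measurements <- as.data.frame(measurements)
  systems <- as.character(measurements$system)
  if (anyDuplicated(systems))
    stop("duplicate measurement systems", call. = FALSE)
  missing <- setdiff(systems, names(isoscapes))
  if (length(missing))
    stop("no isoscape supplied for measured system(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  single <- list()
  for (i in seq_along(systems)) {
    sys <- systems[i]
    z <- zSurface(measurements[i, , drop = FALSE], isoscapes[[sys]])
    single[[sys]] <- probabilitySurfaceFromZ(z)
  }

  subs <- if (identical(subsets, "all")) .systemSubsets(systems)
    else { names(subsets) <- vapply(subsets, paste, character(1),
                                    collapse = "+"); subsets }
  surfaces <- list(); regions <- list()
  removed <- numeric(0); mass <- numeric(0)
  for (nm in names(subs)) {
    ss <- subs[[nm]]
    surf <- if (length(ss) == 1L) single[[ss]]
      else combineSurfaces(single[ss])
    reg <- topMassRegion(surf, q = q, mode = mode)
    surfaces[[nm]] <- surf
    regions[[nm]] <- reg
    removed[nm] <- pctAreaRemoved(reg, sum(validMask(surf)))
    mass[nm] <- reg@massCaptured
  }
  jointName <- names(subs)[which.max(lengths(subs))]
  jp <- surfaces[[jointName]]@probs
  mc <- which(jp == max(jp, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  out <- list(surfaces = surfaces, regions = regions,
              pctAreaRemoved = removed, massCaptured = mass,
              modeCell = c(row = unname(mc[1L]), col = unname(mc[2L])),
              systems = systems, q = q)
  class(out) <- "AssignmentResult"
  out
}

#' @export
print.AssignmentResult <- function(x, ...) {
  cat("Geographic assignment (q = ", signif(x$q, 4), ") over systems: ",
      paste(x$systems, collapse = ", "), "\n", sep = "")
  for (nm in names(x$pctAreaRemoved))
    cat(sprintf("  %-10s area removed %6.2f%%  (mass captured %.3f)\n",
                nm, x$pctAreaRemoved[nm], x$massCaptured[nm]))
  cat(sprintf("  joint mode cell: row %d, col %d\n",
              x$modeCell["row"], x$modeCell["col"]))
  invisible(x)
}
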