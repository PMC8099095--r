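# Eckert IV equal-area projection of WGS84 longitude/latitude.
#
# The projection maps (lon, lat) in degrees to metres on a sphere of authalic
# radius R. The parametric angle theta solves
#   theta + sin(theta) cos(theta) + 2 sin(theta) = (2 + pi/2) sin(lat)
# (Newton iteration; derivative 2 cos(theta) (1 + cos(theta))), then
#   x = (2 / sqrt(4 pi + pi^2)) R lon (1 + cos(theta))
#   y = 2 sqrt(pi / (4 + pi)) R sin(theta).
# The inverse is closed-form given theta recovered from y.

.ECK4_R  <- 6371007.181   # WGS84 authalic sphere radius (m)
.ECK4_CX <- 2 / sqrt(4 * pi + pi^2)
.ECK4_CY <- 2 * sqrt(pi / (4 + pi))

.eck4Theta <- function(latRad) {
  rhs <- (2 + pi / 2) * sin(latRad)
  theta <- latRad / 2
  for (i in 1:50) {
    f <- theta + sin(theta) * cos(theta) + 2 * sin(theta) - rhs
    fp <- 2 * cos(theta) * (1 + cos(theta))
    fp[abs(fp) < 1e-12] <- 1e-12          # poles: derivative vanishes
    delta <- f / fp
    theta <- theta - delta
    if (all(abs(delta) < 1e-13)) break
  }
  theta
}

#' Eckert IV equal-area projection
#'
#' Forward and inverse Eckert IV projection on the WGS84 authalic sphere, the
#' equal-area convention used for continental-scale isoscape grids.
#'
#' @param lon,lat longitude and latitude in decimal degrees (WGS84).
#' @param x,y projected coordinates in metres.
#' @return `eckert4Forward`: two-column matrix `(x, y)` in metres;
#'   `eckert4Inverse`: two-column matrix `(lon, lat)` in degrees.
#' @examples
#' xy <- eckert4Forward(2.35, 48.85)   # Paris
#' eckert4Inverse(xy[, 1], xy[, 2])
#' @export
eckert4Forward <- function(lon, lat) {
  stopifnot(all(is.na(lat) | abs(lat) <= 90), all(is.na(lon) | abs(lon) <= 180))
  theta <- .eck4Theta(lat * pi / 180)
  cbind(x = .ECK4_CX * .ECK4_R * (lon * pi / 180) * (1 + cos(theta)),
        y = .ECK4_CY * .ECK4_R * sin(theta))
}

#' @rdname eckert4Forward
#' @export
eckert4Inverse <- function(x, y) {
  s <- y / (.ECK4_CY * .ECK4_R)
  if (any(abs(s) > 1 + 1e-12, na.rm = TRUE))
    stop("y outside the projection range", call. = FALSE)
  theta <- asin(pmin(pmax(s, -1), 1))
  lat <- asin(pmin(pmax((theta + sin(theta) * cos(theta) + 2 * sin(theta)) /
                          (2 + pi / 2), -1), 1))
  lon <- x / (.ECK4_CX * .ECK4_R * (1 + cos(theta)))
  cbind(lon = lon * 180 / pi, lat = lat * 180 / pi)
}

# Project (lon, lat) points into the coordinate system of a GridSpec.
# Under "local" the coordinates are taken as already-projected metres
# (longitude -> x, latitude -> y).
projectToSpec <- function(spec, lon, lat) {
  if (spec@crs == "eckert4") eckert4Forward(lon, lat)
  else cbind(x = as.numeric(lon), y = as.numeric(lat))
}
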