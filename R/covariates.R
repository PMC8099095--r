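# Coordinate transformation between the supported reference systems.
# Returns a two-column matrix (x, y) in the target system.
transformPoints <- function(fromCrs, toCrs, x, y) {
  if (identical(fromCrs, toCrs)) return(cbind(x = x, y = y))
  if (fromCrs == "longlat" && toCrs == "eckert4")
    return(eckert4Forward(x, y))
  if (fromCrs == "eckert4" && toCrs == "longlat") {
    ll <- eckert4Inverse(x, y)
    return(cbind(x = ll[, "lon"], y = ll[, "lat"]))
  }
  stop("cannot transform from source CRS '", fromCrs, "' to '", toCrs, "'",
       call. = FALSE)
}

# Sample a raster at projected points in its own CRS.
# method "nearest": value of the containing cell (half-open convention).
# method "bilinear": interpolation on the four surrounding cell centers,
# clamped to the center hull at the edges; NA if any contributor is nodata.
.sampleRaster <- function(grid, x, y, method) {
  spec <- grid@spec
  v <- grid@values
  if (method == "nearest") {
    rc <- cellFromXY(spec, x, y)
    out <- rep(NA_real_, length(x))
    ok <- !is.na(rc[, 1L])
    out[ok] <- v[cbind(rc[ok, 1L], rc[ok, 2L])]
    return(out)
  }
  # bilinear on cell centers
  cs <- spec@cellSize
  gx <- (x - (spec@xmin + cs / 2)) / cs       # 0 at first column center
  gy <- ((spec@ymax - cs / 2) - y) / cs       # 0 at first row center
  inside <- x >= spec@xmin & x < spec@xmax & y > spec@ymin & y <= spec@ymax
  gx <- pmin(pmax(gx, 0), spec@ncols - 1)
  gy <- pmin(pmax(gy, 0), spec@nrows - 1)
  c0 <- pmin(floor(gx), spec@ncols - 2); c0 <- pmax(c0, 0)
  r0 <- pmin(floor(gy), spec@nrows - 2); r0 <- pmax(r0, 0)
  if (spec@ncols == 1L) c0 <- rep(0, length(gx))
  if (spec@nrows == 1L) r0 <- rep(0, length(gy))
  fx <- gx - c0; fy <- gy - r0
  c1 <- pmin(c0 + 1, spec@ncols - 1); r1 <- pmin(r0 + 1, spec@nrows - 1)
  v00 <- v[cbind(r0 + 1, c0 + 1)]; v01 <- v[cbind(r0 + 1, c1 + 1)]
  v10 <- v[cbind(r1 + 1, c0 + 1)]; v11 <- v[cbind(r1 + 1, c1 + 1)]
  out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
  out[!inside] <- NA_real_
  out
}

#' Resample a raster onto a target analysis grid
#'
#' Reprojects and resamples a source raster onto a target [GridSpec-class].
#' Continuous layers should use `"bilinear"`; discrete (categorical) layers
#' `"nearest"` or `"mode"`. Nodata propagates: a bilinear output cell is
#' nodata if any contributing source cell is nodata, and nearest/mode cells
#' inherit the source nodata.
#'
#' `"mode"` assigns each target cell the most frequent value among the source
#' cells whose centers fall inside it, falling back to nearest-neighbour
#' sampling where the target resolution is finer than the source.
#'
#' @param source a [RasterGrid-class] in any supported CRS (`"eckert4"`,
#'   `"local"`, `"longlat"`).
#' @param target a [GridSpec-class].
#' @param method `"nearest"`, `"bilinear"` or `"mode"`.
#' @return A [RasterGrid-class] on `target` with the source layer name.
#' @export
resampleToGrid <- function(source, target,
                           method = c("nearest", "bilinear", "mode")) {
  method <- match.arg(method)
  if (is(source, "GridSpec") && is(target, "RasterGrid")) {
    tmp <- source; source <- target; target <- tmp   # tolerate either order
  }
  srcSpec <- source@spec
  if (isTRUE(all.equal(srcSpec, target)))
    return(rasterGrid(source@values, target, name = source@name))

  ctr <- xyFromCell(target,
                    row = rep(seq_len(target@nrows), target@ncols),
                    col = rep(seq_len(target@ncols), each = target@nrows))
  src <- transformPoints(target@crs, srcSpec@crs, ctr[, "x"], ctr[, "y"])

  if (method %in% c("nearest", "bilinear")) {
    vals <- .sampleRaster(source, src[, 1L], src[, 2L], method)
    m <- matrix(vals, target@nrows, target@ncols)
    return(rasterGrid(m, target, name = source@name))
  }

  # mode: push source cell centers into target cells
  sctr <- xyFromCell(srcSpec,
                     row = rep(seq_len(srcSpec@nrows), srcSpec@ncols),
                     col = rep(seq_len(srcSpec@ncols), each = srcSpec@nrows))
  tpt <- transformPoints(srcSpec@crs, target@crs, sctr[, "x"], sctr[, "y"])
  rc <- cellFromXY(target, tpt[, 1L], tpt[, 2L])
  ok <- !is.na(rc[, 1L])
  idx <- (rc[ok, 2L] - 1L) * target@nrows + rc[ok, 1L]
  m <- matrix(NA_real_, target@nrows, target@ncols)
  agg <- tapply(as.vector(source@values)[ok], idx, statMode)
  m[as.integer(names(agg))] <- as.numeric(agg)
  # cells not covered by any source center: nearest-neighbour fallback
  empty <- which(is.na(m))
  if (length(empty)) {
    er <- ((empty - 1L) %% target@nrows) + 1L
    ec <- ((empty - 1L) %/% target@nrows) + 1L
    ectr <- xyFromCell(target, er, ec)
    esrc <- transformPoints(target@crs, srcSpec@crs, ectr[, "x"], ectr[, "y"])
    m[empty] <- .sampleRaster(source, esrc[, 1L], esrc[, 2L], "nearest")
  }
  rasterGrid(m, target, name = source@name)
}

#' Extract covariate values at sampling sites
#'
#' Looks up, for every site, the value of the cell containing its projected
#' coordinate in each layer of the stack (half-open cell convention, see
#' [cellFromXY()]). Sites falling outside the grid extent or on nodata cells
#' get `NA` for the affected layers, with a warning — extraction never fails
#' on individual points.
#'
#' @param stack a [CovariateStack-class].
#' @param points data.frame with columns `site_id`, `latitude`, `longitude`.
#'   Under a `"local"` stack CRS the coordinates are taken as projected
#'   metres (`longitude` = x, `latitude` = y); under `"eckert4"` they are
#'   WGS84 degrees and are projected first.
#' @return A data.frame: `site_id`, projected `x`, `y`, then one column per
#'   covariate layer.
#' @export
extractAtPoints <- function(stack, points) {
  spec <- stack@spec
  xy <- projectToSpec(spec, points$longitude, points$latitude)
  rc <- cellFromXY(spec, xy[, "x"], xy[, "y"])
  outside <- is.na(rc[, 1L])
  if (any(outside))
    warning(sum(outside), " point(s) fall outside the grid extent",
            call. = FALSE)
  out <- data.frame(site_id = points$site_id,
                    x = xy[, "x"], y = xy[, "y"])
  nodata <- FALSE
  for (nm in names(stack@layers)) {
    v <- rep(NA_real_, nrow(points))
    ok <- !outside
    v[ok] <- stack@layers[[nm]]@values[cbind(rc[ok, 1L], rc[ok, 2L])]
    nodata <- nodata | (ok & is.na(v))
    out[[nm]] <- v
  }
  if (any(nodata))
    warning(sum(nodata), " point(s) fall on nodata cells in at least one layer",
            call. = FALSE)
  out
}

#' Euclidean distance to the coast
#'
#' Computes, for every land cell, the Euclidean distance in kilometres from
#' its center to the nearest sea-cell center; sea cells get 0. Distances are
#' computed with an exact Euclidean distance transform
#' ([EBImage::distmap()]), in cell units, and scaled by the cell size.
#'
#' @param landMask a [RasterGrid-class] whose values are 1/`TRUE` on land and
#'   0/`FALSE` on sea (no nodata allowed).
#' @return A [RasterGrid-class] named `"r.distance"` with distances in km.
#' @export
distanceToCoast <- function(landMask) {
  m <- landMask@values
  if (anyNA(m))
    stop("land mask must not contain nodata cells", call. = FALSE)
  land <- m != 0
  if (all(land)) stop("mask is all land: no sea cells", call. = FALSE)
  if (!any(land)) stop("mask is all sea: no land cells", call. = FALSE)
  d <- EBImage::imageData(EBImage::distmap(land * 1))
  km <- matrix(as.numeric(d), nrow(m), ncol(m)) *
    landMask@spec@cellSize / 1000
  rasterGrid(km, landMask@spec, name = "r.distance")
}
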