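#' @import methods
NULL

#' Grid geometry of an equal-area analysis raster
#'
#' A `GridSpec` describes the georeferencing shared by every raster in an
#' analysis: coordinate reference system, cell size in metres, extent in
#' projected units and grid dimensions. Cells are stored row-major with the
#' origin at the upper-left corner. The grid is assumed equal-area, so cell
#' counts can stand in for areas.
#'
#' Three reference systems are supported: `"eckert4"`, the Eckert IV
#' equal-area projection of WGS84 longitude/latitude (the convention used for
#' continental isoscape work); `"local"`, an abstract plane in which point
#' coordinates are already expressed in projected metres (used by the
#' synthetic world); and `"longlat"`, unprojected WGS84 degrees, accepted only
#' as a source system for [resampleToGrid()] (a geographic grid is not
#' equal-area, so it cannot serve as an analysis grid).
#'
#' @slot crs character, `"eckert4"`, `"local"` or `"longlat"`.
#' @slot cellSize numeric, cell edge length in metres.
#' @slot xmin,ymin,xmax,ymax numeric, extent in projected metres; `ymax` is the
#'   top edge of the first row.
#' @slot nrows,ncols integer grid dimensions.
#' @export
setClass("GridSpec",
  representation(crs = "character", cellSize = "numeric",
                 xmin = "numeric", ymin = "numeric",
                 xmax = "numeric", ymax = "numeric",
                 nrows = "integer", ncols = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@crs %in% c("eckert4", "local", "longlat"))
      msg <- c(msg, "crs must be 'eckert4', 'local' or 'longlat'")
    if (object@cellSize <= 0) msg <- c(msg, "cellSize must be positive")
    if (object@nrows < 1L || object@ncols < 1L)
      msg <- c(msg, "grid must have at least one row and one column")
    tol <- 1e-6 * object@cellSize
    if (abs((object@xmax - object@xmin) - object@ncols * object@cellSize) > tol)
      msg <- c(msg, "x extent inconsistent with ncols * cellSize")
    if (abs((object@ymax - object@ymin) - object@nrows * object@cellSize) > tol)
      msg <- c(msg, "y extent inconsistent with nrows * cellSize")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a GridSpec
#'
#' @param nrows,ncols grid dimensions.
#' @param cellSize cell edge length in metres.
#' @param xmin x coordinate of the left edge (projected metres).
#' @param ymax y coordinate of the top edge (projected metres).
#' @param crs `"eckert4"` or `"local"`.
#' @return A [GridSpec-class] object.
#' @examples
#' GridSpec(120, 120, cellSize = 10000)
#' @export
GridSpec <- function(nrows, ncols, cellSize, xmin = 0,
                     ymax = nrows * cellSize, crs = "local") {
  new("GridSpec", crs = crs, cellSize = as.numeric(cellSize),
      xmin = as.numeric(xmin), ymax = as.numeric(ymax),
      xmax = as.numeric(xmin) + ncols * cellSize,
      ymin = as.numeric(ymax) - nrows * cellSize,
      nrows = as.integer(nrows), ncols = as.integer(ncols))
}

#' Single-band raster on an analysis grid
#'
#' Values are a `nrows x ncols` matrix; `NA` marks nodata cells (sea, missing
#' coverage). All non-`NA` values must be finite.
#'
#' @slot spec the [GridSpec-class] georeferencing.
#' @slot values numeric matrix of cell values, `NA` = nodata.
#' @slot name layer identifier (e.g. `"r.ssa"`, `"r.dust"`, `"r.bouguer"`).
#' @export
setClass("RasterGrid",
  representation(spec = "GridSpec", values = "matrix", name = "character"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@values),
                   c(object@spec@nrows, object@spec@ncols)))
      msg <- c(msg, "values dimensions do not match grid spec")
    v <- object@values
    if (any(!is.na(v) & !is.finite(v)))
      msg <- c(msg, "non-NA values must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a RasterGrid
#'
#' @param values numeric matrix (`NA` = nodata) or a scalar recycled over the
#'   grid.
#' @param spec a [GridSpec-class].
#' @param name layer name.
#' @return A [RasterGrid-class].
#' @export
rasterGrid <- function(values, spec, name = "layer") {
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), spec@nrows, spec@ncols)
  storage.mode(values) <- "double"
  new("RasterGrid", spec = spec, values = values, name = name)
}

#' Stack of aligned covariate rasters
#'
#' All layers share one [GridSpec-class] exactly; this is the regression
#' design space for isoscape fitting and the prediction domain for
#' [predictIsoscape()].
#'
#' @slot spec shared [GridSpec-class].
#' @slot layers named list of [RasterGrid-class] objects.
#' @export
setClass("CovariateStack",
  representation(spec = "GridSpec", layers = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@layers) == 0L) msg <- c(msg, "stack has no layers")
    nm <- names(object@layers)
    if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
      msg <- c(msg, "layers must have unique non-empty names")
    for (ly in object@layers) {
      if (!is(ly, "RasterGrid")) { msg <- c(msg, "layers must be RasterGrid"); break }
      if (!isTRUE(all.equal(ly@spec, object@spec)))
        { msg <- c(msg, "all layers must share the stack GridSpec"); break }
    }
    if (is.null(msg)) TRUE else msg
  })

#' Construct a CovariateStack
#'
#' @param layers named list of [RasterGrid-class] objects on one grid (names
#'   default to the layer names).
#' @return A [CovariateStack-class].
#' @export
covariateStack <- function(layers) {
  if (is.null(names(layers)))
    names(layers) <- vapply(layers, function(l) l@name, character(1))
  new("CovariateStack", spec = layers[[1L]]@spec, layers = layers)
}

#' Isoscape: paired mean and uncertainty surfaces for one isotope system
#'
#' The mean grid predicts the isotopic value of the tissue (or water) proxy at
#' each cell; the sd grid its 1-standard-deviation uncertainty. For the
#' random-forest sulfur isoscape the sd surface is constant and equal to the
#' cross-validation RMSE; external oxygen and strontium isoscapes carry
#' spatially varying sd.
#'
#' @slot system `"S"`, `"O"` or `"Sr"`.
#' @slot mean [RasterGrid-class] of predicted means (permil for S/O, ratio for
#'   Sr).
#' @slot sd [RasterGrid-class] of 1-sd uncertainties, same units and mask.
#' @slot note free-text provenance note.
#' @export
setClass("Isoscape",
  representation(system = "character", mean = "RasterGrid",
                 sd = "RasterGrid", note = "character"),
  validity = function(object) {
    msg <- NULL
    if (!object@system %in% c("S", "O", "Sr"))
      msg <- c(msg, "system must be 'S', 'O' or 'Sr'")
    if (!isTRUE(all.equal(object@mean@spec, object@sd@spec)))
      msg <- c(msg, "mean and sd must share a GridSpec")
    mm <- is.na(object@mean@values); ms <- is.na(object@sd@values)
    if (!identical(mm, ms))
      msg <- c(msg, "mean and sd must share the same nodata mask")
    if (any(object@sd@values[!ms] <= 0))
      msg <- c(msg, "sd must be strictly positive on valid cells")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an Isoscape
#'
#' @param system `"S"`, `"O"` or `"Sr"`.
#' @param mean [RasterGrid-class] of predicted means.
#' @param sd [RasterGrid-class] of 1-sd uncertainties, or a positive scalar
#'   expanded to a constant surface over the valid cells of `mean`.
#' @param note provenance note.
#' @return An [Isoscape-class].
#' @export
isoscape <- function(system, mean, sd, note = "") {
  if (is.numeric(sd) && length(sd) == 1L) {
    v <- matrix(as.numeric(sd), mean@spec@nrows, mean@spec@ncols)
    v[is.na(mean@values)] <- NA_real_
    sd <- rasterGrid(v, mean@spec, name = paste0(mean@name, ".sd"))
  }
  new("Isoscape", system = system, mean = mean, sd = sd, note = note)
}

#' Normalized probability-of-origin surface
#'
#' Per-cell posterior probability that an individual originated in that cell,
#' relative to all other valid cells. Probabilities sum to one over the valid
#' mask (within 1e-9); nodata cells are `NA`.
#'
#' @slot spec [GridSpec-class].
#' @slot probs numeric matrix of probabilities, `NA` on invalid cells.
#' @export
setClass("ProbabilitySurface",
  representation(spec = "GridSpec", probs = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@probs),
                   c(object@spec@nrows, object@spec@ncols)))
      msg <- c(msg, "probs dimensions do not match grid spec")
    p <- object@probs[!is.na(object@probs)]
    if (length(p) == 0L) msg <- c(msg, "no valid cells")
    else {
      if (any(p < 0)) msg <- c(msg, "probabilities must be nonnegative")
      if (abs(sum(p) - 1) > 1e-9)
        msg <- c(msg, "probabilities must sum to 1 over valid cells")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Binary high-probability-origin region
#'
#' The result of thresholding a [ProbabilitySurface-class] at cumulative
#' posterior mass `q`: the smallest set of cells, taken in decreasing order of
#' probability, whose summed probability reaches `q` (ties at the cut
#' included).
#'
#' @slot spec [GridSpec-class].
#' @slot included logical matrix, `TRUE` for cells inside the region.
#' @slot q the nominal mass threshold (default 1/3 in the assignment
#'   workflow).
#' @slot massCaptured achieved cumulative probability of the region.
#' @export
setClass("BinaryRegion",
  representation(spec = "GridSpec", included = "matrix",
                 q = "numeric", massCaptured = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.logical(object@included))
      msg <- c(msg, "included must be a logical matrix")
    if (!identical(dim(object@included),
                   c(object@spec@nrows, object@spec@ncols)))
      msg <- c(msg, "included dimensions do not match grid spec")
    if (object@q <= 0 || object@q >= 1) msg <- c(msg, "q must be in (0, 1)")
    if (object@massCaptured < object@q - 1e-9)
      msg <- c(msg, "massCaptured must reach the nominal q")
    if (is.null(msg)) TRUE else msg
  })

#' Tagged oxygen isotope values
#'
#' A vector of delta-18O values carrying their reference scale (VSMOW or
#' VPDB) and mineral/water fraction (structural carbonate, phosphate, or
#' drinking water). Conversion operators check the tags and refuse mismatched
#' inputs, so a carbonate value can never be fed accidentally into the
#' phosphate-to-water calibration.
#'
#' @slot value numeric vector, permil.
#' @slot scale `"VSMOW"` or `"VPDB"`.
#' @slot fraction `"carbonate"`, `"phosphate"` or `"water"`.
#' @slot sd numeric 1-sd uncertainty in permil (`NA` when not tracked), scalar
#'   or one per value.
#' @export
setClass("OxygenValues",
  representation(value = "numeric", scale = "character",
                 fraction = "character", sd = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@scale %in% c("VSMOW", "VPDB"))
      msg <- c(msg, "scale must be 'VSMOW' or 'VPDB'")
    if (!object@fraction %in% c("carbonate", "phosphate", "water"))
      msg <- c(msg, "fraction must be 'carbonate', 'phosphate' or 'water'")
    if (!length(object@sd) %in% c(1L, length(object@value)))
      msg <- c(msg, "sd must be scalar or one per value")
    if (is.null(msg)) TRUE else msg
  })

#' Construct tagged oxygen values
#'
#' @param value numeric vector of delta-18O values (permil).
#' @param scale `"VSMOW"` or `"VPDB"`.
#' @param fraction `"carbonate"`, `"phosphate"` or `"water"`.
#' @param sd optional 1-sd uncertainty (permil).
#' @return An [OxygenValues-class].
#' @examples
#' oxygenValues(-4.0, "VPDB", "carbonate")
#' @export
oxygenValues <- function(value, scale, fraction, sd = NA_real_) {
  new("OxygenValues", value = as.numeric(value), scale = scale,
      fraction = fraction, sd = as.numeric(sd))
}
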