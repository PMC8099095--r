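#' @include AllClasses.R
NULL

#' Accessors for grid objects
#'
#' `gridSpec` returns the [GridSpec-class] of a raster-like object;
#' `gridValues` its value matrix; `validMask` a logical matrix of valid
#' (non-nodata) cells; `layerNames` the layer names of a
#' [CovariateStack-class]; `getLayer` one named layer.
#'
#' @param x a grid object.
#' @param name layer name.
#' @return See the individual descriptions.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))
#' @rdname grid-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname grid-accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname grid-accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))
#' @rdname grid-accessors
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))

#' @rdname grid-accessors
#' @export
setMethod("gridSpec", "RasterGrid", function(x) x@spec)
#' @rdname grid-accessors
#' @export
setMethod("gridSpec", "CovariateStack", function(x) x@spec)
#' @rdname grid-accessors
#' @export
setMethod("gridSpec", "Isoscape", function(x) x@mean@spec)
#' @rdname grid-accessors
#' @export
setMethod("gridSpec", "ProbabilitySurface", function(x) x@spec)
#' @rdname grid-accessors
#' @export
setMethod("gridSpec", "BinaryRegion", function(x) x@spec)

#' @rdname grid-accessors
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)
#' @rdname grid-accessors
#' @export
setMethod("gridValues", "ProbabilitySurface", function(x) x@probs)

#' @rdname grid-accessors
#' @export
setMethod("validMask", "RasterGrid", function(x) !is.na(x@values))
#' @rdname grid-accessors
#' @export
setMethod("validMask", "ProbabilitySurface", function(x) !is.na(x@probs))
#' @rdname grid-accessors
#' @export
setMethod("validMask", "Isoscape", function(x) !is.na(x@mean@values))

#' @rdname grid-accessors
#' @export
setMethod("layerNames", "CovariateStack", function(x) names(x@layers))
#' @rdname grid-accessors
#' @export
setMethod("getLayer", "CovariateStack", function(x, name) {
  if (!name %in% names(x@layers))
    stop("no layer named '", name, "' in stack", call. = FALSE)
  x@layers[[name]]
})

#' Isoscape accessors
#'
#' @param x an [Isoscape-class].
#' @return `isoMean`/`isoSd` return the mean and sd [RasterGrid-class];
#'   `isoSystem` the isotope system tag.
#' @name isoscape-accessors
NULL

#' @rdname isoscape-accessors
#' @export
setGeneric("isoMean", function(x) standardGeneric("isoMean"))
#' @rdname isoscape-accessors
#' @export
setGeneric("isoSd", function(x) standardGeneric("isoSd"))
#' @rdname isoscape-accessors
#' @export
setGeneric("isoSystem", function(x) standardGeneric("isoSystem"))
#' @rdname isoscape-accessors
#' @export
setMethod("isoMean", "Isoscape", function(x) x@mean)
#' @rdname isoscape-accessors
#' @export
setMethod("isoSd", "Isoscape", function(x) x@sd)
#' @rdname isoscape-accessors
#' @export
setMethod("isoSystem", "Isoscape", function(x) x@system)

#' BinaryRegion accessors
#'
#' @param x a [BinaryRegion-class].
#' @return `includedCells` returns the logical inclusion matrix;
#'   `massCaptured` the achieved cumulative probability; `thresholdQ` the
#'   nominal mass threshold.
#' @name region-accessors
NULL

#' @rdname region-accessors
#' @export
setGeneric("includedCells", function(x) standardGeneric("includedCells"))
#' @rdname region-accessors
#' @export
setGeneric("massCaptured", function(x) standardGeneric("massCaptured"))
#' @rdname region-accessors
#' @export
setGeneric("thresholdQ", function(x) standardGeneric("thresholdQ"))
#' @rdname region-accessors
#' @export
setMethod("includedCells", "BinaryRegion", function(x) x@included)
#' @rdname region-accessors
#' @export
setMethod("massCaptured", "BinaryRegion", function(x) x@massCaptured)
#' @rdname region-accessors
#' @export
setMethod("thresholdQ", "BinaryRegion", function(x) x@q)

#' OxygenValues accessors
#'
#' @param x an [OxygenValues-class].
#' @return `oxValue` the numeric values (permil); `oxScale` the reference
#'   scale tag; `oxFraction` the fraction tag; `oxSd` the 1-sd uncertainty.
#' @name oxygen-accessors
NULL

#' @rdname oxygen-accessors
#' @export
setGeneric("oxValue", function(x) standardGeneric("oxValue"))
#' @rdname oxygen-accessors
#' @export
setGeneric("oxScale", function(x) standardGeneric("oxScale"))
#' @rdname oxygen-accessors
#' @export
setGeneric("oxFraction", function(x) standardGeneric("oxFraction"))
#' @rdname oxygen-accessors
#' @export
setGeneric("oxSd", function(x) standardGeneric("oxSd"))
#' @rdname oxygen-accessors
#' @export
setMethod("oxValue", "OxygenValues", function(x) x@value)
#' @rdname oxygen-accessors
#' @export
setMethod("oxScale", "OxygenValues", function(x) x@scale)
#' @rdname oxygen-accessors
#' @export
setMethod("oxFraction", "OxygenValues", function(x) x@fraction)
#' @rdname oxygen-accessors
#' @export
setMethod("oxSd", "OxygenValues", function(x) x@sd)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %.4g m, crs '%s'\n",
              object@nrows, object@ncols, object@cellSize, object@crs))
  cat(sprintf("  extent: x [%.4g, %.4g]  y [%.4g, %.4g]\n",
              object@xmin, object@xmax, object@ymin, object@ymax))
})

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  nv <- sum(!is.na(v))
  cat(sprintf("RasterGrid '%s': %d x %d, %d valid cells",
              object@name, nrow(v), ncol(v), nv))
  if (nv > 0)
    cat(sprintf(", range [%.4g, %.4g]", min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  cat("\n")
})

setMethod("show", "CovariateStack", function(object) {
  cat(sprintf("CovariateStack: %d layers on a %d x %d grid\n",
              length(object@layers), object@spec@nrows, object@spec@ncols))
  cat("  ", paste(names(object@layers), collapse = ", "), "\n", sep = "")
})

setMethod("show", "Isoscape", function(object) {
  v <- object@mean@values
  cat(sprintf("Isoscape [%s]: %d x %d, mean range [%.4g, %.4g], sd range [%.4g, %.4g]\n",
              object@system, nrow(v), ncol(v),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE),
              min(object@sd@values, na.rm = TRUE),
              max(object@sd@values, na.rm = TRUE)))
  if (nzchar(object@note)) cat("  note: ", object@note, "\n", sep = "")
})

setMethod("show", "ProbabilitySurface", function(object) {
  p <- object@probs
  cat(sprintf("ProbabilitySurface: %d x %d, %d valid cells, max p = %.3g\n",
              nrow(p), ncol(p), sum(!is.na(p)), max(p, na.rm = TRUE)))
})

setMethod("show", "BinaryRegion", function(object) {
  cat(sprintf("BinaryRegion: q = %.4g, %d cells included, mass captured %.4f\n",
              object@q, sum(object@included), object@massCaptured))
})

setMethod("show", "OxygenValues", function(object) {
  cat(sprintf("OxygenValues [%s, %s]: ", object@fraction, object@scale))
  cat(paste(signif(object@value, 6), collapse = ", "))
  if (!all(is.na(object@sd)))
    cat(" (sd ", paste(signif(object@sd, 4), collapse = ", "), ")", sep = "")
  cat(" permil\n")
})
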