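#' Oxygen conversion-chain parameters
#'
#' Coefficients of the affine calibration chain that turns tooth-enamel
#' structural-carbonate delta-18O into a drinking-water-equivalent value:
#'
#' * carbonate to phosphate: `d18Op = (d18Oc - 8.79 (+-0.79)) / 1.015 (+-0.043)`
#' * phosphate to water: `d18Ow = (d18Op - 21.28 (+-0.51)) / 0.68 (+-0.04)`
#' * VPDB to VSMOW scale: `d18O_SMOW = 1.03091 * d18O_PDB + 30.91`
#'
#' The combined uncertainty of the two calibrations is taken as a constant
#' `chainSd` of 1 permil; [chainUncertainty()] offers the first-order
#' analytic alternative propagated from the four coefficient SDs.
#'
#' @param eq3Intercept,eq3Slope carbonate-phosphate calibration (permil, -).
#' @param eq3InterceptSd,eq3SlopeSd their 1-sd uncertainties.
#' @param eq4Intercept,eq4Slope phosphate-water calibration.
#' @param eq4InterceptSd,eq4SlopeSd their 1-sd uncertainties.
#' @param chainSd summary 1-sd uncertainty of the full chain (permil).
#' @param pdbSmowSlope,pdbSmowOffset VPDB-to-VSMOW scale relation.
#' @return A named list of parameters.
#' @export
conversionParams <- function(eq3Intercept = 8.79, eq3InterceptSd = 0.79,
                             eq3Slope = 1.015, eq3SlopeSd = 0.043,
                             eq4Intercept = 21.28, eq4InterceptSd = 0.51,
                             eq4Slope = 0.68, eq4SlopeSd = 0.04,
                             chainSd = 1.0,
                             pdbSmowSlope = 1.03091, pdbSmowOffset = 30.91) {
  stopifnot(eq3Slope != 0, eq4Slope != 0, pdbSmowSlope != 0)
  list(eq3Intercept = eq3Intercept, eq3InterceptSd = eq3InterceptSd,
       eq3Slope = eq3Slope, eq3SlopeSd = eq3SlopeSd,
       eq4Intercept = eq4Intercept, eq4InterceptSd = eq4InterceptSd,
       eq4Slope = eq4Slope, eq4SlopeSd = eq4SlopeSd,
       chainSd = chainSd,
       pdbSmowSlope = pdbSmowSlope, pdbSmowOffset = pdbSmowOffset)
}

.checkTags <- function(v, scale = NULL, fraction = NULL) {
  if (!is(v, "OxygenValues"))
    stop("expected an OxygenValues object", call. = FALSE)
  if (!is.null(scale) && v@scale != scale)
    stop("expected scale '", scale, "', got '", v@scale, "'", call. = FALSE)
  if (!is.null(fraction) && v@fraction != fraction)
    stop("expected fraction '", fraction, "', got '", v@fraction, "'",
         call. = FALSE)
  invisible(v)
}

#' Inter-scale and inter-fraction oxygen conversions
#'
#' Each conversion is affine, strictly increasing and exactly invertible;
#' every operator checks the scale/fraction tags of its input and carries the
#' tags forward, so values can never silently cross scales.
#'
#' * `pdbToSmow` / `smowToPdb`: VPDB <-> VSMOW reference scale.
#' * `carbonateToPhosphate` / `phosphateToCarbonate`: structural carbonate
#'   <-> phosphate (both on VSMOW).
#' * `phosphateToWater` / `waterToPhosphate`: phosphate <-> drinking water.
#'
#' @param v an [OxygenValues-class] with the tags the operation requires.
#' @param params parameters from [conversionParams()].
#' @return An [OxygenValues-class] with converted values and updated tags;
#'   the `sd` slot is carried through unchanged (use [tissueToWater()] for
#'   the chain-level uncertainty).
#' @examples
#' pdbToSmow(oxygenValues(0, "VPDB", "carbonate"))   # 30.91 VSMOW
#' @export
pdbToSmow <- function(v, params = conversionParams()) {
  .checkTags(v, scale = "VPDB")
  oxygenValues(params$pdbSmowSlope * v@value + params$pdbSmowOffset,
               "VSMOW", v@fraction, v@sd)
}

#' @rdname pdbToSmow
#' @export
smowToPdb <- function(v, params = conversionParams()) {
  .checkTags(v, scale = "VSMOW")
  oxygenValues((v@value - params$pdbSmowOffset) / params$pdbSmowSlope,
               "VPDB", v@fraction, v@sd)
}

#' @rdname pdbToSmow
#' @export
carbonateToPhosphate <- function(v, params = conversionParams()) {
  .checkTags(v, scale = "VSMOW", fraction = "carbonate")
  oxygenValues((v@value - params$eq3Intercept) / params$eq3Slope,
               "VSMOW", "phosphate", v@sd)
}

#' @rdname pdbToSmow
#' @export
phosphateToCarbonate <- function(v, params = conversionParams()) {
  .checkTags(v, scale = "VSMOW", fraction = "phosphate")
  oxygenValues(v@value * params$eq3Slope + params$eq3Intercept,
               "VSMOW", "carbonate", v@sd)
}

#' @rdname pdbToSmow
#' @export
phosphateToWater <- function(v, params = conversionParams()) {
  .checkTags(v, fraction = "phosphate")
  oxygenValues((v@value - params$eq4Intercept) / params$eq4Slope,
               v@scale, "water", v@sd)
}

#' @rdname pdbToSmow
#' @export
waterToPhosphate <- function(v, params = conversionParams()) {
  .checkTags(v, fraction = "water")
  oxygenValues(v@value * params$eq4Slope + params$eq4Intercept,
               v@scale, "phosphate", v@sd)
}

#' Convert measured enamel carbonate d18O to drinking water
#'
#' Composes the full conversion chain on measured tooth-enamel
#' structural-carbonate values: reference-scale conversion (VPDB to VSMOW,
#' applied when `assumeInputScale = "VPDB"`, the scale on which enamel
#' carbonate is conventionally reported), then carbonate to phosphate, then
#' phosphate to drinking water. The result carries the summary chain
#' uncertainty `params$chainSd` (1 permil).
#'
#' @param d18Oc numeric vector of measured enamel carbonate values (permil),
#'   or an [OxygenValues-class] carbonate object.
#' @param params parameters from [conversionParams()].
#' @param assumeInputScale scale of numeric input: `"VPDB"` (default) or
#'   `"VSMOW"`.
#' @return An [OxygenValues-class], fraction `"water"`, scale `"VSMOW"`, with
#'   `sd = params$chainSd`.
#' @examples
#' oxValue(tissueToWater(-4.0))   # about -5.220 permil
#' @export
tissueToWater <- function(d18Oc, params = conversionParams(),
                          assumeInputScale = c("VPDB", "VSMOW")) {
  assumeInputScale <- match.arg(assumeInputScale)
  if (!is(d18Oc, "OxygenValues"))
    d18Oc <- oxygenValues(d18Oc, assumeInputScale, "carbonate")
  .checkTags(d18Oc, fraction = "carbonate")
  if (d18Oc@scale == "VPDB") d18Oc <- pdbToSmow(d18Oc, params)
  w <- phosphateToWater(carbonateToPhosphate(d18Oc, params), params)
  oxygenValues(w@value, "VSMOW", "water", sd = params$chainSd)
}

#' First-order analytic uncertainty of the conversion chain
#'
#' Propagates the printed coefficient SDs of the two calibrations through the
#' chain at a given carbonate value, as an alternative to the constant
#' summary `chainSd`. First-order (delta-method) propagation, treating the
#' four coefficients as independent.
#'
#' @param d18Oc numeric carbonate values on the VPDB scale (permil).
#' @param params parameters from [conversionParams()].
#' @return Numeric vector of 1-sd uncertainties (permil).
#' @export
chainUncertainty <- function(d18Oc, params = conversionParams()) {
  smow <- params$pdbSmowSlope * d18Oc + params$pdbSmowOffset
  p <- (smow - params$eq3Intercept) / params$eq3Slope
  varP <- (params$eq3InterceptSd^2 + p^2 * params$eq3SlopeSd^2) /
    params$eq3Slope^2
  w <- (p - params$eq4Intercept) / params$eq4Slope
  varW <- (varP + params$eq4InterceptSd^2 + w^2 * params$eq4SlopeSd^2) /
    params$eq4Slope^2
  sqrt(varW)
}

#' Combine precipitation-isoscape and conversion-chain uncertainty
#'
#' The drinking-water-equivalent tissue value is compared against a
#' precipitation isoscape whose own uncertainty must be widened by the
#' conversion-chain uncertainty. Default combination is in quadrature
#' (`sqrt(precipSd^2 + chainSd^2)`, independent errors); arithmetic addition
#' is available as a conservative alternative.
#'
#' @param precipSd a [RasterGrid-class] of precipitation-isoscape SDs, or a
#'   numeric vector.
#' @param chainSd scalar chain uncertainty (permil).
#' @param mode `"quadrature"` (default) or `"additive"`.
#' @return Same type as `precipSd`, with combined SDs.
#' @export
combineOxygenUncertainty <- function(precipSd, chainSd = 1.0,
                                     mode = c("quadrature", "additive")) {
  mode <- match.arg(mode)
  comb <- function(s) if (mode == "quadrature") sqrt(s^2 + chainSd^2)
    else s + chainSd
  if (is(precipSd, "RasterGrid"))
    rasterGrid(comb(precipSd@values), precipSd@spec, name = precipSd@name)
  else comb(precipSd)
}
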