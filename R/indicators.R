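# The five ecological component indicators and the water mask.
#
# Greenness  SAVI  = (1 + L)(b2 - b1) / (b1 + b2 + L)
# Humidity   SWCI  = (b6 - b7) / (b6 + b7)
# Dryness    NDBBI = (1.5 b6 - (b2 + b4)/2) / (1.5 b6 + (b2 + b4)/2)
# Heat       LST   = 0.02 DN - 273.15  (degrees Celsius)
# Salinity   CSI   = mean of min-max normalized SI-T, NDSI, SI4
# Water      MNDWI = (b4 - b6) / (b4 + b6), water where MNDWI > threshold
#
# Reflectance values outside the physically plausible window [-0.01, 1.6]
# are treated as nodata before any band math (sensor-artifact guard).

.reflectanceWindow <- c(-0.01, 1.6)

.bandClean <- function(stack, name) {
  v <- gridValues(stackBand(stack, name))
  v[v < .reflectanceWindow[1L] | v > .reflectanceWindow[2L]] <- NA_real_
  v
}

.asLayer <- function(stack, values) {
  setGridValues(stackBand(stack, "b1"), values)
}

#' Modified Normalized Difference Water Index
#'
#' MNDWI = (green - SWIR1) / (green + SWIR1); positive over open water.
#' Cells with a zero denominator are masked.
#'
#' @param stack a \linkS4class{BandStack}.
#' @return A \linkS4class{RasterGrid} of MNDWI values.
#' @export
computeMndwi <- function(stack) {
  b4 <- .bandClean(stack, "b4"); b6 <- .bandClean(stack, "b6")
  den <- b4 + b6
  out <- (b4 - b6) / den
  out[!is.na(den) & den == 0] <- NA_real_
  .asLayer(stack, out)
}

#' Derive the water mask from an MNDWI grid
#'
#' @param mndwi MNDWI \linkS4class{RasterGrid}.
#' @param threshold water where MNDWI > threshold (default 0, the standard
#'   MNDWI convention).
#' @return logical matrix, TRUE = water; NA cells are FALSE (unknown cells
#'   are handled by the nodata mask, not the water mask).
#' @export
waterMaskFromMndwi <- function(mndwi, threshold = 0) {
  v <- gridValues(mndwi)
  w <- !is.na(v) & v > threshold
  w
}

#' Soil Adjusted Vegetation Index
#'
#' SAVI = (1 + L)(NIR - red) / (red + NIR + L). The soil-adjustment constant
#' L damps bare-soil background; L = 0 reduces SAVI to NDVI.
#'
#' @param stack a \linkS4class{BandStack}.
#' @param L soil adjustment constant, >= 0 (default 0.5, the empirical value
#'   for sparse arid-region vegetation).
#' @return A \linkS4class{RasterGrid}.
#' @export
computeSavi <- function(stack, L = 0.5) {
  stopifnot(L >= 0)
  b1 <- .bandClean(stack, "b1"); b2 <- .bandClean(stack, "b2")
  den <- b1 + b2 + L
  out <- (1 + L) * (b2 - b1) / den
  out[!is.na(den) & den <= 0] <- NA_real_
  .asLayer(stack, out)
}

#' Surface Water Content Index
#'
#' SWCI = (SWIR1 - SWIR2) / (SWIR1 + SWIR2); exploits liquid-water
#' absorption in the shortwave infrared to track surface moisture.
#'
#' @param stack a \linkS4class{BandStack}.
#' @return A \linkS4class{RasterGrid}.
#' @export
computeSwci <- function(stack) {
  b6 <- .bandClean(stack, "b6"); b7 <- .bandClean(stack, "b7")
  den <- b6 + b7
  out <- (b6 - b7) / den
  out[!is.na(den) & den == 0] <- NA_real_
  .asLayer(stack, out)
}

#' Normalized Difference Bareness and Built-up Index
#'
#' Dryness indicator separating bare/built surfaces from vegetation and
#' water. The default grouping follows the original index definition,
#' NDBBI = (1.5 b6 - (b2 + b4)/2) / (1.5 b6 + (b2 + b4)/2);
#' \code{grouping = "whole"} uses (b2 + b4/2) in both numerator and
#' denominator instead, the alternative literal reading of the formula.
#'
#' @param stack a \linkS4class{BandStack}.
#' @param grouping \code{"half_sum"} (default) or \code{"whole"}.
#' @return A \linkS4class{RasterGrid}.
#' @export
computeNdbbi <- function(stack, grouping = c("half_sum", "whole")) {
  grouping <- match.arg(grouping)
  b2 <- .bandClean(stack, "b2"); b4 <- .bandClean(stack, "b4")
  b6 <- .bandClean(stack, "b6")
  vw <- if (grouping == "half_sum") (b2 + b4) / 2 else b2 + b4 / 2
  den <- 1.5 * b6 + vw
  out <- (1.5 * b6 - vw) / den
  out[!is.na(den) & den == 0] <- NA_real_
  .asLayer(stack, out)
}

#' Land Surface Temperature from digital numbers
#'
#' LST = scale * DN + offset; the defaults convert MODIS-style LST digital
#' numbers (Kelvin * 50) to degrees Celsius.
#'
#' @param stack a \linkS4class{BandStack}.
#' @param scale DN scale factor (default 0.02 K per DN).
#' @param offset additive offset (default -273.15, absolute zero in Celsius).
#' @return A \linkS4class{RasterGrid} in degrees Celsius.
#' @export
computeLst <- function(stack, scale = 0.02, offset = -273.15) {
  dn <- gridValues(stackBand(stack, "lst_dn"))
  setGridValues(stackBand(stack, "lst_dn"), scale * dn + offset)
}

#' Comprehensive Salinity Index
#'
#' Mean of three salinity sub-indices, each min-max normalized to [0, 1]
#' over the unmasked (land) cells of the scene:
#' SI-T = (b1 / b2) * 100, NDSI = (b1 - b2) / (b1 + b2), SI4 = b6 / b2.
#' The mean of three [0, 1] layers, CSI lies in [0, 1] by construction.
#'
#' @param stack a \linkS4class{BandStack}.
#' @param mask optional logical matrix, TRUE = exclude (typically water).
#' @return A \linkS4class{RasterGrid} in [0, 1].
#' @export
computeCsi <- function(stack, mask = NULL) {
  b1 <- .bandClean(stack, "b1"); b2 <- .bandClean(stack, "b2")
  b6 <- .bandClean(stack, "b6")
  bad <- !is.na(b2) & b2 == 0
  b2[bad] <- NA_real_
  sit  <- (b1 / b2) * 100
  ndsi <- (b1 - b2) / (b1 + b2)
  si4  <- b6 / b2
  ndsi[!is.na(b1 + b2) & (b1 + b2) == 0] <- NA_real_
  ref <- stackBand(stack, "b1")
  nrm <- function(v, nm) {
    gridValues(minmaxNormalize(setGridValues(ref, v), mask = mask,
                               layerName = nm))
  }
  csi <- (nrm(sit, "SI-T") + nrm(ndsi, "NDSI") + nrm(si4, "SI4")) / 3
  .asLayer(stack, csi)
}

#' Build the water-masked, normalized indicator set for one epoch
#'
#' Computes the MNDWI water mask, evaluates the five component indicators
#' with water cells excluded, then min-max normalizes each layer to [0, 1]
#' over the land cells, yielding the PCA-ready \linkS4class{IndicatorSet}.
#'
#' @param stack a \linkS4class{BandStack}.
#' @param waterThreshold MNDWI water threshold (default 0).
#' @param saviL SAVI soil-adjustment constant (default 0.5).
#' @param ndbbiGrouping see \code{\link{computeNdbbi}}.
#' @return An \linkS4class{IndicatorSet} with \code{normalized = TRUE}.
#' @export
buildIndicatorSet <- function(stack, waterThreshold = 0, saviL = 0.5,
                              ndbbiGrouping = "half_sum") {
  mndwi <- computeMndwi(stack)
  water <- waterMaskFromMndwi(mndwi, waterThreshold)
  land <- !water & !stackInvalidMask(stack)
  if (!any(land))
    stop("all-water (or all-nodata) scene: no land cells to assess")
  raw <- list(
    savi  = computeSavi(stack, L = saviL),
    swci  = computeSwci(stack),
    ndbbi = computeNdbbi(stack, grouping = ndbbiGrouping),
    lst   = computeLst(stack),
    csi   = computeCsi(stack, mask = water))
  norm <- lapply(names(raw), function(nm) {
    minmaxNormalize(raw[[nm]], mask = water, layerName = nm)
  })
  names(norm) <- names(raw)
  new("IndicatorSet", layers = norm, waterMask = water, normalized = TRUE)
}
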