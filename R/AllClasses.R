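#' @import methods
NULL

#' CTVolume: a calibrated 3-D CT scalar field
#'
#' Container for a three-dimensional CT volume in Hounsfield units (HU),
#' together with the voxel spacing that makes volumetric and gravimetric
#' computations unit-safe. The HU scale is assumed calibrated so that
#' water = 0 HU and air = -1000 HU.
#'
#' @slot data 3-D numeric array of HU values. All values must be finite.
#' @slot spacing Numeric vector of length 3, voxel edge lengths
#'   \code{(dx, dy, dz)} in millimetres; all strictly positive.
#' @slot affine 4x4 numeric matrix mapping voxel indices to world
#'   coordinates. Retained for provenance only; all analysis here is
#'   voxel-wise and orientation-agnostic.
#' @slot metadata Free-form list (source file, header fields, ...).
#'
#' @seealso [CTVolume()] for the user constructor, [readVolume()].
#' @export
setClass("CTVolume",
  representation(
    data = "array",
    spacing = "numeric",
    affine = "matrix",
    metadata = "list"
  )
)

setValidity("CTVolume", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, sprintf("data must be a 3-D array (got %d dimensions)",
                          length(dim(object@data))))
  if (length(object@spacing) != 3L)
    msg <- c(msg, "spacing must have length 3 (dx, dy, dz in mm)")
  else if (!all(is.finite(object@spacing)) || any(object@spacing <= 0))
    msg <- c(msg, "spacing components must be finite and strictly positive")
  bad <- which(!is.finite(object@data))
  if (length(bad) > 0) {
    idx <- arrayInd(bad[1L], dim(object@data))
    msg <- c(msg, sprintf(
      "HU values must be finite; first offending voxel at index [%s]",
      paste(idx, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CTVolume
#'
#' @param data 3-D numeric array of Hounsfield units.
#' @param spacing Voxel spacing \code{(dx, dy, dz)} in mm.
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a scaling
#'   matrix built from \code{spacing}.
#' @param metadata Optional provenance list.
#' @return A validated [CTVolume-class] object.
#' @examples
#' v <- CTVolume(array(-700, c(4, 4, 2)), spacing = c(1, 1, 5))
#' voxelVolumeMl(v)
#' @export
CTVolume <- function(data, spacing, affine = NULL, metadata = list()) {
  data <- as.array(data)
  storage.mode(data) <- "double"
  spacing <- as.numeric(spacing)
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  new("CTVolume", data = data, spacing = spacing, affine = affine,
      metadata = metadata)
}

.MASK_LABELS <- c("aerated", "opacified", "excluded")

#' LungMask: a binary lung segmentation
#'
#' Boolean 3-D mask congruent with a [CTVolume-class]. Optionally carries
#' per-voxel region labels (\code{"aerated"}, \code{"opacified"},
#' \code{"excluded"}) stored as an integer code array (0 = background).
#'
#' @slot data 3-D logical array, same dimensions as the paired volume.
#' @slot labels Integer array of region codes (same dim as \code{data}),
#'   or a zero-length array when the mask is unlabeled. Codes index into
#'   \code{c("aerated", "opacified", "excluded")}.
#' @slot metadata Free-form list (e.g. voxel-removal bookkeeping).
#' @export
setClass("LungMask",
  representation(
    data = "array",
    labels = "array",
    metadata = "list"
  ),
  prototype(labels = array(integer(0), dim = c(0, 0, 0)))
)

setValidity("LungMask", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "mask data must be a 3-D array")
  if (!is.logical(object@data))
    msg <- c(msg, "mask data must be logical")
  if (length(object@labels) > 0) {
    if (!identical(dim(object@labels), dim(object@data)))
      msg <- c(msg, "label array must have the same dimensions as the mask")
    lab <- object@labels[object@labels != 0L]
    if (length(lab) && (any(lab < 1L) || any(lab > length(.MASK_LABELS))))
      msg <- c(msg, "label codes must be 0 (background) or 1..3")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LungMask
#'
#' @param data 3-D array; nonzero entries become \code{TRUE}.
#' @param labels Optional character or integer array of region labels
#'   (\code{"aerated"}, \code{"opacified"}, \code{"excluded"}), congruent
#'   with \code{data}.
#' @param metadata Optional list.
#' @return A validated [LungMask-class].
#' @export
LungMask <- function(data, labels = NULL, metadata = list()) {
  d <- as.array(data)
  m <- array(d != 0, dim = dim(d))
  if (is.null(labels)) {
    lab <- array(integer(0), dim = c(0, 0, 0))
  } else if (is.character(labels)) {
    code <- match(labels, .MASK_LABELS)
    code[is.na(labels) | labels == ""] <- 0L
    if (anyNA(code))
      stop("unknown region label(s): ",
           paste(unique(labels[is.na(code)]), collapse = ", "))
    lab <- array(as.integer(code), dim = dim(d))
  } else {
    lab <- array(as.integer(labels), dim = dim(as.array(labels)))
  }
  new("LungMask", data = m, labels = lab, metadata = metadata)
}

#' DensityModel: affine HU-to-density conversion
#'
#' The standard quantitative-CT relation
#' \deqn{\rho(HU) = \rho_{ref} (HU + 1000)/1000,}
#' the unique affine map with \eqn{\rho(-1000) = 0} (gas) and
#' \eqn{\rho(0) = \rho_{ref}} (water).
#'
#' @slot rhoRef Reference density of water in g/ml. Default 1.0; the
#'   physical value at 22 degrees C, 0.99777 g/ml, is available for
#'   phantom validation work.
#' @slot huAir HU of pure gas (-1000).
#' @slot huMax Upper bound of the analyzable HU window (+100).
#' @export
setClass("DensityModel",
  representation(rhoRef = "numeric", huAir = "numeric", huMax = "numeric"),
  prototype(rhoRef = 1.0, huAir = -1000, huMax = 100)
)

setValidity("DensityModel", function(object) {
  msg <- character(0)
  if (object@rhoRef <= 0) msg <- c(msg, "rhoRef must be positive")
  if (object@huAir >= object@huMax) msg <- c(msg, "huAir must be < huMax")
  if (length(msg)) msg else TRUE
})

#' @rdname DensityModel-class
#' @param rhoRef reference water density, g/ml
#' @param huAir HU value assigned zero density
#' @param huMax upper analyzable HU bound
#' @export
densityModel <- function(rhoRef = 1.0, huAir = -1000, huMax = 100) {
  new("DensityModel", rhoRef = rhoRef, huAir = huAir, huMax = huMax)
}

#' CompartmentScheme: HU ranges of the aeration compartments
#'
#' Ordered, disjoint HU bins covering exactly \eqn{[-1000, +100]} HU, one
#' per aeration compartment. The defaults reproduce the integer-worded
#' clinical ranges (nonaerated \eqn{-100..+100}, poorly aerated
#' \eqn{-101..-500}, normally aerated \eqn{-501..-900}, hyperaerated
#' \eqn{-901..-1000}) as half-open real intervals with boundaries at the
#' integer midpoints, so every integer HU maps to its printed compartment
#' and non-integer reconstructions are handled deterministically.
#'
#' @slot labels Compartment names, ordered from most to least aerated.
#' @slot breaks Numeric vector of length \code{length(labels) + 1}; bin i
#'   is \code{[breaks[i], breaks[i+1])}, the last bin closed on the right.
#' @export
setClass("CompartmentScheme",
  representation(labels = "character", breaks = "numeric"),
  prototype(
    labels = c("hyperaerated", "normally_aerated", "poorly_aerated",
               "nonaerated"),
    breaks = c(-1000, -900.5, -500.5, -100.5, 100)
  )
)

setValidity("CompartmentScheme", function(object) {
  msg <- character(0)
  if (length(object@breaks) != length(object@labels) + 1L)
    msg <- c(msg, "breaks must have one more element than labels")
  if (any(diff(object@breaks) <= 0))
    msg <- c(msg, "breaks must be strictly increasing (bins disjoint)")
  if (length(msg)) msg else TRUE
})

#' @rdname CompartmentScheme-class
#' @param labels compartment names (most to least aerated)
#' @param breaks bin edges, length \code{length(labels) + 1}
#' @export
compartmentScheme <- function(labels = c("hyperaerated", "normally_aerated",
                                         "poorly_aerated", "nonaerated"),
                              breaks = c(-1000, -900.5, -500.5, -100.5, 100)) {
  new("CompartmentScheme", labels = labels, breaks = breaks)
}

#' AerationSummary: per-scan lung mass, volume and compartment partition
#'
#' Result of [summarizeAeration()]: total lung volume V_lung (ml), total
#' lung mass M_lung (g), per-compartment masses (g) and mass percentages
#' (% of M_lung), and voxel bookkeeping. Compartment masses always sum to
#' M_lung; percentages sum to 100 when M_lung > 0.
#'
#' The hyperaerated compartment is computed but is flagged as
#' scanner-dependent in reports: its value is sensitive to the
#' reconstruction kernel and should not be compared across scanners.
#'
#' @slot vLung Total lung volume, ml.
#' @slot mLung Total lung mass, g.
#' @slot compartmentMass Named numeric, per-compartment mass in g.
#' @slot compartmentPercent Named numeric, per-compartment % of M_lung.
#' @slot nVoxelsUsed In-mask voxels inside the HU window.
#' @slot nVoxelsExcluded In-mask voxels outside \eqn{[-1000, +100]} HU,
#'   excluded from all quantities.
#' @slot voxelVolumeMl Volume of a single voxel, ml.
#' @export
setClass("AerationSummary",
  representation(
    vLung = "numeric",
    mLung = "numeric",
    compartmentMass = "numeric",
    compartmentPercent = "numeric",
    nVoxelsUsed = "integer",
    nVoxelsExcluded = "integer",
    voxelVolumeMl = "numeric"
  )
)

#' ReferenceInterval: population reference limits for a measurand
#'
#' @slot lower,upper Reference limits (same unit as the input, g for
#'   lung mass).
#' @slot coverage Fraction of the reference population the interval is
#'   meant to cover (0.95 for the conventional 95% interval).
#' @slot method \code{"robust"}, \code{"nonparametric"} or
#'   \code{"parametric"}.
#' @slot n Number of reference subjects.
#' @export
setClass("ReferenceInterval",
  representation(lower = "numeric", upper = "numeric", coverage = "numeric",
                 method = "character", n = "integer")
)

setValidity("ReferenceInterval", function(object) {
  msg <- character(0)
  if (object@lower > object@upper) msg <- c(msg, "lower must be <= upper")
  if (object@coverage <= 0 || object@coverage >= 1)
    msg <- c(msg, "coverage must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' AgreementResult: percent-difference Bland-Altman statistics
#'
#' @slot biasPercent Mean paired percent difference (bias), %.
#' @slot loaLowPercent,loaHighPercent Limits of agreement,
#'   bias +/- 1.96 SD, %.
#' @slot sdPercent SD of the paired percent differences.
#' @slot nPairs Number of pairs.
#' @slot differences The per-pair percent differences.
#' @export
setClass("AgreementResult",
  representation(biasPercent = "numeric", loaLowPercent = "numeric",
                 loaHighPercent = "numeric", sdPercent = "numeric",
                 nPairs = "integer", differences = "numeric")
)

setValidity("AgreementResult", function(object) {
  if (object@loaLowPercent > object@biasPercent + 1e-12 ||
      object@biasPercent > object@loaHighPercent + 1e-12)
    "limits of agreement must bracket the bias" else TRUE
})

#' RegressionReport: hierarchical (blockwise) OLS with variance retention
#'
#' @slot blockStats One row per predictor block: cumulative R-squared,
#'   R-squared change on entry, F and p for the change, and whether the
#'   block is retained under the variance-retention rule.
#' @slot coefficients Coefficients of the final (retained-blocks) model
#'   with confidence limits.
#' @slot retentionThreshold Minimum R-squared change for retention.
#' @slot level Confidence level for coefficient intervals.
#' @slot n Observations used.
#' @export
setClass("RegressionReport",
  representation(blockStats = "data.frame", coefficients = "data.frame",
                 retentionThreshold = "numeric", level = "numeric",
                 n = "integer")
)

#' ClassificationRule: mass cut-offs for posttraumatic lung dysfunction
#'
#' Patients with lung mass at or below \code{upperReference} (the upper
#' limit of the normal-lung reference interval) are classified as having
#' atelectasis; above it, as above the reference range; above
#' \code{consolidationCut} (a literature-derived lower bound of lung mass
#' in consolidated lungs), additionally as consolidation. Consolidation is
#' a nested subset of above-reference.
#'
#' @slot upperReference Upper reference limit, g (study value 1164 g).
#' @slot consolidationCut Consolidation cut-off, g (study value 1380 g).
#' @slot metadata Provenance (screen exclusions, interval method, ...).
#' @export
setClass("ClassificationRule",
  representation(upperReference = "numeric", consolidationCut = "numeric",
                 metadata = "list")
)

setValidity("ClassificationRule", function(object) {
  if (!(object@upperReference < object@consolidationCut))
    "upperReference must be strictly below consolidationCut" else TRUE
})

#' @rdname ClassificationRule-class
#' @param upperReference upper reference limit, g
#' @param consolidationCut consolidation cut-off, g
#' @param metadata provenance list
#' @export
classificationRule <- function(upperReference = 1164,
                               consolidationCut = 1380,
                               metadata = list()) {
  new("ClassificationRule", upperReference = upperReference,
      consolidationCut = consolidationCut, metadata = metadata)
}

#' RefinementConfig: parameters of boundary partial-volume exclusion
#'
#' @slot thresholdHu HU threshold above which boundary-band voxels are
#'   excluded from aerated lung (default -350 HU, the conventional
#'   black-white display interface for aerated parenchyma).
#' @slot bandWidthVoxels Width of the morphological boundary band in
#'   voxels (mask minus its erosion by this many steps).
#' @slot sliceWise If TRUE, the band is computed with 2-D (in-plane,
#'   4-connected) erosion per slice, mimicking slice-based manual work;
#'   otherwise 3-D 6-connected erosion.
#' @export
setClass("RefinementConfig",
  representation(thresholdHu = "numeric", bandWidthVoxels = "integer",
                 sliceWise = "logical"),
  prototype(thresholdHu = -350, bandWidthVoxels = 2L, sliceWise = FALSE)
)

setValidity("RefinementConfig", function(object) {
  msg <- character(0)
  if (object@thresholdHu <= -1000 || object@thresholdHu >= 100)
    msg <- c(msg, "thresholdHu must lie strictly inside (-1000, 100)")
  if (object@bandWidthVoxels < 1L)
    msg <- c(msg, "bandWidthVoxels must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname RefinementConfig-class
#' @param thresholdHu exclusion threshold, HU
#' @param bandWidthVoxels boundary band width, voxels
#' @param sliceWise use 2-D slice-wise erosion
#' @export
refinementConfig <- function(thresholdHu = -350, bandWidthVoxels = 2,
                             sliceWise = FALSE) {
  new("RefinementConfig", thresholdHu = thresholdHu,
      bandWidthVoxels = as.integer(bandWidthVoxels), sliceWise = sliceWise)
}

#' PhantomSpec: recipe for a synthetic thoracic CT phantom
#'
#' Describes a synthetic thorax: a soft-tissue body containing two
#' ellipsoidal lungs whose voxels are drawn from a configurable mixture of
#' aeration compartments, with optional Gaussian HU noise, a
#' partial-volume rim (linear HU blending toward neighbouring tissue over
#' a given width), a water-bottle cylinder beside the thorax, a dense
#' (opacified) lesion inside one lung, and a count of deliberately
#' out-of-range voxels (mimicking contrast-bright vessels).
#'
#' @slot dim Grid dimensions (voxels).
#' @slot spacing Voxel spacing (mm).
#' @slot lungVolumeMl Target total lung volume, ml (both lungs); the
#'   realized voxelized volume is recorded in the ground truth.
#' @slot fractions Named volume fractions of the aeration compartments
#'   (\code{hyperaerated}, \code{normally_aerated}, \code{poorly_aerated},
#'   \code{nonaerated}); must sum to 1.
#' @slot huDistribution \code{"uniform"} (default) or \code{"gaussian"}
#'   within each compartment's HU range.
#' @slot fixedHu Optional named numeric: compartments listed here get this
#'   constant HU instead of a sampled one.
#' @slot noiseSd Gaussian HU noise SD added after ground-truth bookkeeping.
#' @slot rimWidth Partial-volume rim width in voxels (0 = no rim).
#' @slot chestWallHu HU of the soft-tissue body (+40), the blend target
#'   for lung rims.
#' @slot includeBottle,bottleRadiusMm,bottleLengthMm,bottleHu Water-bottle
#'   cylinder beside the thorax; its rim blends toward surrounding air.
#' @slot lesionVolumeMl,lesionHuRange Dense lesion (0 = none); HU sampled
#'   uniformly in the given range within \eqn{[-100, +100]}.
#' @slot nOutOfRange Number of lung voxels set to +250 HU (out of the
#'   analyzable window).
#' @slot seed RNG seed; generation is a pure function of (spec, seed).
#' @export
setClass("PhantomSpec",
  representation(
    dim = "integer", spacing = "numeric", lungVolumeMl = "numeric",
    fractions = "numeric", huDistribution = "character",
    fixedHu = "numeric", noiseSd = "numeric", rimWidth = "integer",
    chestWallHu = "numeric", includeBottle = "logical",
    bottleRadiusMm = "numeric", bottleLengthMm = "numeric",
    bottleHu = "numeric", lesionVolumeMl = "numeric",
    lesionHuRange = "numeric", nOutOfRange = "integer", seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (length(object@dim) != 3L || any(object@dim < 8L))
    msg <- c(msg, "dim must be 3 integers, each >= 8")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive numbers (mm)")
  if (abs(sum(object@fractions) - 1) > 1e-8)
    msg <- c(msg, "compartment volume fractions must sum to 1")
  if (any(object@fractions < 0))
    msg <- c(msg, "compartment volume fractions must be nonnegative")
  if (!all(names(object@fractions) %in%
           c("hyperaerated", "normally_aerated", "poorly_aerated",
             "nonaerated")))
    msg <- c(msg, "fractions must be named after the four compartments")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@rimWidth < 0L) msg <- c(msg, "rimWidth must be >= 0")
  if (object@lesionVolumeMl < 0)
    msg <- c(msg, "lesionVolumeMl must be >= 0")
  if (object@lesionHuRange[1] < -100.5 || object@lesionHuRange[2] > 100)
    msg <- c(msg, "lesionHuRange must lie within the nonaerated range")
  if (length(msg)) msg else TRUE
})

#' @rdname PhantomSpec-class
#' @param dim,spacing,lungVolumeMl,fractions,huDistribution,fixedHu,noiseSd
#'   see slot documentation
#' @param rimWidth,chestWallHu,includeBottle,bottleRadiusMm,bottleLengthMm
#'   see slot documentation
#' @param bottleHu,lesionVolumeMl,lesionHuRange,nOutOfRange,seed
#'   see slot documentation
#' @export
phantomSpec <- function(dim = c(96L, 96L, 48L),
                        spacing = c(2.5, 2.5, 5),
                        lungVolumeMl = 3000,
                        fractions = c(hyperaerated = 0.02,
                                      normally_aerated = 0.90,
                                      poorly_aerated = 0.06,
                                      nonaerated = 0.02),
                        huDistribution = c("uniform", "gaussian"),
                        fixedHu = numeric(0),
                        noiseSd = 0,
                        rimWidth = 0,
                        chestWallHu = 40,
                        includeBottle = FALSE,
                        bottleRadiusMm = 40,
                        bottleLengthMm = 150,
                        bottleHu = 0,
                        lesionVolumeMl = 0,
                        lesionHuRange = c(-100, 100),
                        nOutOfRange = 0,
                        seed = 1L) {
  huDistribution <- match.arg(huDistribution)
  new("PhantomSpec",
      dim = as.integer(dim), spacing = as.numeric(spacing),
      lungVolumeMl = lungVolumeMl, fractions = fractions,
      huDistribution = huDistribution, fixedHu = fixedHu,
      noiseSd = noiseSd, rimWidth = as.integer(rimWidth),
      chestWallHu = chestWallHu, includeBottle = includeBottle,
      bottleRadiusMm = bottleRadiusMm, bottleLengthMm = bottleLengthMm,
      bottleHu = bottleHu, lesionVolumeMl = lesionVolumeMl,
      lesionHuRange = lesionHuRange, nOutOfRange = as.integer(nOutOfRange),
      seed = as.integer(seed))
}

#' GroundTruth: exact bookkeeping for a synthetic phantom
#'
#' Mass and volume totals computed by the generator by direct summation
#' over the assigned pre-noise HU field -- an independent code path from
#' the analysis in [summarizeAeration()], so the two can cross-validate.
#'
#' @slot totalVolumeMl,totalMassG Analyzable lung volume (ml) and mass (g).
#' @slot compartmentVolumeMl,compartmentMassG Named per-compartment totals.
#' @slot bottleMassG,bottleVolumeMl Water-bottle totals (0 if absent).
#' @slot lesionMassG,lesionVolumeMl Dense-lesion totals (0 if absent).
#' @slot nOutOfRange Lung voxels outside the HU window (excluded from the
#'   analyzable totals).
#' @slot params Generative parameters actually used.
#' @export
setClass("GroundTruth",
  representation(
    totalVolumeMl = "numeric", totalMassG = "numeric",
    compartmentVolumeMl = "numeric", compartmentMassG = "numeric",
    bottleMassG = "numeric", bottleVolumeMl = "numeric",
    lesionMassG = "numeric", lesionVolumeMl = "numeric",
    nOutOfRange = "integer", params = "list"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  if (abs(sum(object@compartmentMassG) - object@totalMassG) >
      1e-9 * max(1, object@totalMassG))
    msg <- c(msg, "compartment masses must sum to the total mass")
  if (abs(sum(object@compartmentVolumeMl) - object@totalVolumeMl) >
      1e-9 * max(1, object@totalVolumeMl))
    msg <- c(msg, "compartment volumes must sum to the total volume")
  if (length(msg)) msg else TRUE
})
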