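#' Convert Hounsfield units to tissue density
#'
#' The quantitative-CT density relation
#' \eqn{\rho(HU) = \rho_{ref}(HU + 1000)/1000}: the unique affine map with
#' zero density for pure gas (-1000 HU) and the reference water density at
#' 0 HU. Values outside the analyzable window are an error by default --
#' filtering out-of-range voxels is the caller's responsibility and silent
#' clamping would bias mass estimates; an explicit clamp mode exists for
#' sensitivity analyses.
#'
#' @param hu Numeric vector of HU values.
#' @param model A [DensityModel-class].
#' @param clamp If TRUE, clamp out-of-range values to the window instead
#'   of erroring.
#' @return Densities in g/ml.
#' @examples
#' huToDensity(c(-1000, -500, 0))  # 0, 0.5, 1.0 g/ml
#' @export
huToDensity <- function(hu, model = densityModel(), clamp = FALSE) {
  stopifnot(is(model, "DensityModel"))
  out <- hu < model@huAir | hu > model@huMax
  if (any(out)) {
    if (!clamp)
      stop(sprintf(
        "HU value %.6g outside [%g, %g]; filter or use clamp = TRUE",
        hu[which(out)[1]], model@huAir, model@huMax))
    hu <- pmin(pmax(hu, model@huAir), model@huMax)
  }
  model@rhoRef * (hu - model@huAir) / (-model@huAir)
}

#' Classify HU values into aeration compartments
#'
#' Maps each HU value in the analyzable window to exactly one compartment
#' of a [CompartmentScheme-class]. With the default scheme, integer HU
#' reproduce the conventional clinical ranges: nonaerated -100..+100,
#' poorly aerated -101..-500, normally aerated -501..-900, hyperaerated
#' -901..-1000.
#'
#' @param hu Numeric vector of HU values.
#' @param scheme A [CompartmentScheme-class].
#' @return Factor of compartment labels (levels in scheme order).
#' @examples
#' classifyCompartment(c(-950, -700, -300, 0))
#' @export
classifyCompartment <- function(hu, scheme = compartmentScheme()) {
  stopifnot(is(scheme, "CompartmentScheme"))
  lo <- scheme@breaks[1]
  hi <- scheme@breaks[length(scheme@breaks)]
  out <- hu < lo | hu > hi
  if (any(out))
    stop(sprintf("HU value %.6g outside [%g, %g]",
                 hu[which(out)[1]], lo, hi))
  idx <- findInterval(hu, scheme@breaks, rightmost.closed = TRUE)
  factor(scheme@labels[idx], levels = scheme@labels)
}

#' Voxel-wise lung aeration summary
#'
#' The central computation: every in-mask voxel with HU inside
#' \eqn{[-1000, +100]} contributes its voxel volume to V_lung and its
#' voxel volume times converted density to M_lung and to its
#' compartment's mass; in-mask voxels outside the window (typically
#' contrast-bright vessels caught by a generous mask) are excluded and
#' counted, never clamped, unless \code{clampOutOfRange} is set.
#' Compartment masses are also reported as percentages of M_lung.
#'
#' @param volume A [CTVolume-class].
#' @param mask A [LungMask-class] congruent with \code{volume}.
#' @param model A [DensityModel-class].
#' @param scheme A [CompartmentScheme-class].
#' @param clampOutOfRange Sensitivity-analysis flag: clamp out-of-window
#'   HU to the window instead of excluding those voxels.
#' @return An [AerationSummary-class].
#' @examples
#' v <- CTVolume(array(-700, c(10, 10, 10)), spacing = c(10, 10, 10))
#' m <- LungMask(array(TRUE, c(10, 10, 10)))
#' summarizeAeration(v, m)  # 1000 ml at 0.3 g/ml -> 300 g
#' @export
summarizeAeration <- function(volume, mask, model = densityModel(),
                              scheme = compartmentScheme(),
                              clampOutOfRange = FALSE) {
  stopifnot(is(volume, "CTVolume"), is(mask, "LungMask"),
            is(model, "DensityModel"), is(scheme, "CompartmentScheme"))
  if (!identical(dim(volume@data), dim(mask@data)))
    stop(sprintf("mask shape (%s) does not match volume shape (%s)",
                 paste(dim(mask@data), collapse = "x"),
                 paste(dim(volume@data), collapse = "x")))
  hu <- volume@data[mask@data]
  if (length(hu) == 0) stop("empty mask: no voxels to analyze")

  inWindow <- hu >= model@huAir & hu <= model@huMax
  nExcluded <- sum(!inWindow)
  if (clampOutOfRange) {
    hu <- pmin(pmax(hu, model@huAir), model@huMax)
    inWindow <- rep(TRUE, length(hu))
    nExcluded <- 0L
  }
  hu <- hu[inWindow]
  if (length(hu) == 0)
    stop("no analyzable lung voxels: all in-mask HU outside [",
         model@huAir, ", ", model@huMax, "]")

  vv <- voxelVolumeMl(volume)
  dens <- huToDensity(hu, model)
  massPerVoxel <- dens * vv
  comp <- classifyCompartment(hu, scheme)

  mComp <- vapply(scheme@labels,
                  function(l) sum(massPerVoxel[comp == l]), numeric(1))
  # total defined as the sum of its parts: conservation holds exactly
  mTot <- sum(mComp)
  pComp <- if (mTot > 0) 100 * mComp / mTot else mComp * NA_real_

  new("AerationSummary",
      vLung = length(hu) * vv,
      mLung = mTot,
      compartmentMass = mComp,
      compartmentPercent = pComp,
      nVoxelsUsed = length(hu),
      nVoxelsExcluded = as.integer(nExcluded),
      voxelVolumeMl = vv)
}
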