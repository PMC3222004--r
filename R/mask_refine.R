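# --- binary morphology helpers (6-connected 3-D, 4-connected 2-D) -------

.shift3d <- function(m, axis, by) {
  d <- dim(m)
  out <- array(FALSE, d)
  n <- d[axis]
  if (n < 2L) return(out)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (by > 0) {
    dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1)
  } else {
    dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

# one erosion step; voxels outside the grid count as background
.erodeOnce <- function(m, axes = 1:3) {
  out <- m
  for (ax in axes) {
    out <- out & .shift3d(m, ax, 1L) & .shift3d(m, ax, -1L)
  }
  out
}

#' Erode a binary 3-D mask
#'
#' Iterated binary erosion with a face-connected structuring element:
#' 6-connected in 3-D, or 4-connected within each axial slice when
#' \code{sliceWise} (matching slice-based manual segmentation work).
#' Voxels beyond the grid edge are treated as background.
#'
#' @param mask 3-D logical array.
#' @param steps Number of erosion iterations.
#' @param sliceWise Erode in-plane only.
#' @return Eroded logical array.
#' @export
erodeMask <- function(mask, steps = 1, sliceWise = FALSE) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, steps >= 0)
  axes <- if (sliceWise) 1:2 else 1:3
  out <- mask
  for (i in seq_len(steps)) out <- .erodeOnce(out, axes)
  out
}

#' Exclude partial-volume voxels at aerated lung boundaries
#'
#' Operationalizes threshold-guided boundary cleanup: within the
#' morphological boundary band of the aerated lung (the mask minus its
#' erosion by \code{bandWidthVoxels}), voxels brighter than
#' \code{thresholdHu} (default -350 HU) are removed from the mask. These
#' are the voxels that straddle the interface with chest wall,
#' mediastinum, heart or diaphragm and take intermediate HU through the
#' partial volume effect. Interior voxels and opacified-labeled regions
#' are never touched; the result is always a subset of the input mask.
#'
#' Exclusion is repeated until the boundary settles: removing a bright
#' band voxel can expose another bright voxel to the new boundary band,
#' so the band is recomputed and the rule reapplied until no voxel
#' changes -- the segmentation line comes to rest where the boundary is
#' dark. This fixpoint makes the operation idempotent on every input.
#' \code{maxPasses = 1} restricts removal to the band of the input mask
#' for sensitivity analyses.
#'
#' When the mask carries region labels, only \code{"aerated"} voxels are
#' eligible for removal; a labeled mask without any aerated voxels is an
#' error.
#'
#' @param volume A [CTVolume-class].
#' @param mask A [LungMask-class].
#' @param config A [RefinementConfig-class].
#' @param maxPasses Cap on band re-evaluations (default unlimited, i.e.
#'   run to the fixpoint).
#' @return A refined [LungMask-class]; \code{metadata$nRemoved} records
#'   the total number of excluded voxels and \code{metadata$nPasses} the
#'   passes used.
#' @export
refineAeratedBoundary <- function(volume, mask,
                                  config = refinementConfig(),
                                  maxPasses = Inf) {
  stopifnot(is(volume, "CTVolume"), is(mask, "LungMask"),
            is(config, "RefinementConfig"))
  if (!identical(dim(volume@data), dim(mask@data)))
    stop("mask and volume shapes differ")
  if (!any(mask@data)) stop("empty mask")

  hasLabels <- length(mask@labels) > 0
  if (hasLabels && !any(mask@data & mask@labels == 1L))
    stop("labeled mask has no 'aerated' region to refine")

  cur <- mask@data
  labels <- mask@labels
  totalRemoved <- 0L
  passes <- 0L
  repeat {
    aerated <- if (hasLabels) cur & labels == 1L else cur
    if (!any(aerated)) break
    band <- aerated & !erodeMask(aerated, config@bandWidthVoxels,
                                 sliceWise = config@sliceWise)
    drop <- band & volume@data > config@thresholdHu
    passes <- passes + 1L
    if (!any(drop) || passes > maxPasses) {
      if (passes > maxPasses) passes <- passes - 1L
      break
    }
    cur <- cur & !drop
    if (hasLabels) labels[drop] <- 0L
    totalRemoved <- totalRemoved + sum(drop)
    if (passes >= maxPasses) break
  }
  meta <- mask@metadata
  meta$nRemoved <- totalRemoved
  meta$nPasses <- passes
  new("LungMask", data = cur, labels = labels, metadata = meta)
}

#' Restrict a mask to the analyzable HU window
#'
#' Removes in-mask voxels with HU outside \eqn{[-1000, +100]} (e.g.
#' contrast-bright vessels) and records how many were removed in
#' \code{metadata$nRemoved}. An empty result is allowed here; downstream
#' analysis calls will refuse it.
#'
#' @param volume A [CTVolume-class].
#' @param mask A [LungMask-class].
#' @param range HU window, default \code{c(-1000, 100)}.
#' @return Filtered [LungMask-class].
#' @export
filterHuRange <- function(volume, mask, range = c(-1000, 100)) {
  stopifnot(is(volume, "CTVolume"), is(mask, "LungMask"))
  if (!identical(dim(volume@data), dim(mask@data)))
    stop("mask and volume shapes differ")
  if (!any(mask@data)) stop("empty mask")
  keep <- volume@data >= range[1] & volume@data <= range[2]
  drop <- mask@data & !keep
  newData <- mask@data & keep
  newLabels <- mask@labels
  if (length(newLabels) > 0) newLabels[drop] <- 0L
  meta <- mask@metadata
  meta$nRemoved <- sum(drop)
  new("LungMask", data = newData, labels = newLabels, metadata = meta)
}
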