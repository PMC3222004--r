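#' Accessor generics
#'
#' Small accessor family for the imaging containers: \code{ctData} returns
#' the raw HU array, \code{spacing} the voxel spacing in mm,
#' \code{voxelVolumeMl} the volume of one voxel in ml, \code{maskArray}
#' the logical mask, \code{maskLabels} the character label array (or NULL
#' when unlabeled), and \code{mLung} / \code{vLung} /
#' \code{compartmentMasses} / \code{compartmentPercents} the summary
#' quantities.
#'
#' @param x The object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ctData", function(x) standardGeneric("ctData"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("voxelVolumeMl", function(x) standardGeneric("voxelVolumeMl"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

#' @rdname accessors
#' @export
setGeneric("mLung", function(x) standardGeneric("mLung"))

#' @rdname accessors
#' @export
setGeneric("vLung", function(x) standardGeneric("vLung"))

#' @rdname accessors
#' @export
setGeneric("compartmentMasses", function(x) standardGeneric("compartmentMasses"))

#' @rdname accessors
#' @export
setGeneric("compartmentPercents", function(x) standardGeneric("compartmentPercents"))
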