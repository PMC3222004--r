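#' @rdname accessors
#' @aliases ctData,CTVolume-method
setMethod("ctData", "CTVolume", function(x) x@data)

#' @rdname accessors
setMethod("spacing", "CTVolume", function(x) x@spacing)

#' @rdname accessors
setMethod("voxelVolumeMl", "CTVolume", function(x) prod(x@spacing) / 1000)

#' @rdname accessors
setMethod("maskArray", "LungMask", function(x) x@data)

#' @rdname accessors
setMethod("maskLabels", "LungMask", function(x) {
  if (length(x@labels) == 0) return(NULL)
  out <- array(NA_character_, dim = dim(x@labels))
  nz <- x@labels != 0L
  out[nz] <- .MASK_LABELS[x@labels[nz]]
  out
})

#' @rdname accessors
setMethod("mLung", "AerationSummary", function(x) x@mLung)

#' @rdname accessors
setMethod("vLung", "AerationSummary", function(x) x@vLung)

#' @rdname accessors
setMethod("compartmentMasses", "AerationSummary", function(x) x@compartmentMass)

#' @rdname accessors
setMethod("compartmentPercents", "AerationSummary",
          function(x) x@compartmentPercent)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("CTVolume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f], voxel volume %.5f ml\n",
              min(object@data), max(object@data),
              prod(object@spacing) / 1000))
})

setMethod("show", "LungMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("LungMask: %d x %d x %d voxels, %d in mask\n",
              d[1], d[2], d[3], sum(object@data)))
  lab <- maskLabels(object)
  if (!is.null(lab)) {
    tab <- table(lab[object@data])
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab),
                           collapse = ", "), "\n")
  }
})

setMethod("show", "AerationSummary", function(object) {
  cat("AerationSummary\n")
  cat(sprintf("  V_lung: %.1f ml   M_lung: %.1f g\n",
              object@vLung, object@mLung))
  for (nm in names(object@compartmentMass)) {
    flag <- if (nm == "hyperaerated") "  [scanner-dependent]" else ""
    cat(sprintf("  %-17s %8.1f g  (%5.1f %%)%s\n", nm,
                object@compartmentMass[nm], object@compartmentPercent[nm],
                flag))
  }
  cat(sprintf("  voxels used: %d, excluded (out of HU window): %d\n",
              object@nVoxelsUsed, object@nVoxelsExcluded))
})

setMethod("show", "ReferenceInterval", function(object) {
  cat(sprintf("%.0f%% reference interval (%s, n = %d): %.1f to %.1f\n",
              100 * object@coverage, object@method, object@n,
              object@lower, object@upper))
})

setMethod("show", "AgreementResult", function(object) {
  cat(sprintf(
    "Bland-Altman (percent differences, n = %d):\n  bias %.2f%%, limits of agreement %.2f%% to %.2f%%\n",
    object@nPairs, object@biasPercent, object@loaLowPercent,
    object@loaHighPercent))
})

setMethod("show", "RegressionReport", function(object) {
  cat(sprintf("Hierarchical regression (n = %d, retain if dR2 >= %.2f)\n",
              object@n, object@retentionThreshold))
  print(object@blockStats, row.names = FALSE)
  cat("Final model coefficients:\n")
  print(object@coefficients, row.names = FALSE)
})

setMethod("show", "ClassificationRule", function(object) {
  cat(sprintf(
    "ClassificationRule: atelectasis <= %.0f g < above-reference; consolidation > %.0f g\n",
    object@upperReference, object@consolidationCut))
})

#' Flatten an AerationSummary to a one-row data frame
#'
#' One scan per row: V_lung, M_lung, the four compartment masses and
#' percentages, and voxel bookkeeping. Suitable for appending to a CSV.
#'
#' @param x An [AerationSummary-class].
#' @param row.names,optional,... Passed for S3 compatibility; ignored.
#' @return A one-row \code{data.frame}.
#' @export
as.data.frame.AerationSummary <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  cm <- as.list(x@compartmentMass)
  names(cm) <- paste0("m_", names(cm), "_g")
  cp <- as.list(x@compartmentPercent)
  names(cp) <- paste0("m_", names(cp), "_pct")
  data.frame(v_lung_ml = x@vLung, m_lung_g = x@mLung, cm, cp,
             n_voxels_used = x@nVoxelsUsed,
             n_voxels_excluded = x@nVoxelsExcluded,
             stringsAsFactors = FALSE)
}

#' Write an aeration report
#'
#' Serializes an [AerationSummary-class] as JSON or as a one-row CSV.
#'
#' @param x An [AerationSummary-class].
#' @param path Output file path.
#' @param format \code{"json"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeAerationReport <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  df <- as.data.frame.AerationSummary(x)
  if (format == "json") {
    obj <- as.list(df)
    obj$note <- "hyperaerated compartment is scanner-dependent"
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
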