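#' Read a CT volume
#'
#' Reads a 3-D CT volume in Hounsfield units from NIfTI-1
#' (\code{.nii}/\code{.nii.gz}; rescale slope/intercept applied by the
#' reader) or from the package's raw+JSON sidecar dialect (a little-endian
#' binary array next to a JSON file with \code{shape}, \code{spacing},
#' \code{dtype} and \code{data_file}), which exists so that fixtures can
#' be plain text plus a small generated binary at run time.
#'
#' @param path Path to a \code{.nii}, \code{.nii.gz} or \code{.json}
#'   sidecar file.
#' @return A [CTVolume-class].
#' @details Loading fails hard on non-3-D data, missing/invalid voxel
#'   spacing, and non-finite HU values (the first offending voxel index is
#'   named).
#' @seealso [writeVolume()], [readMask()]
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path)) {
    return(.readRawSidecar(path))
  }
  img <- RNifti::readNifti(path)
  arr <- array(as.double(img), dim = dim(img))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(arr)), " dimensions")
  sp <- RNifti::pixdim(img)[1:3]
  if (length(sp) < 3L || any(!is.finite(sp)) || any(sp <= 0))
    stop("volume header has missing or invalid voxel spacing: ",
         paste(sp, collapse = ", "))
  CTVolume(arr, spacing = sp, affine = .niftiAffine(img),
           metadata = list(source = path, format = "nifti"))
}

.niftiAffine <- function(img) {
  aff <- tryCatch(structure(RNifti::xform(img), class = NULL),
                  error = function(e) NULL)
  if (is.null(aff) || !is.matrix(aff) || !all(dim(aff) == c(4, 4)))
    aff <- diag(c(RNifti::pixdim(img)[1:3], 1))
  dimnames(aff) <- NULL
  aff
}

.readRawSidecar <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("shape", "spacing", "dtype", "data_file")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stop("sidecar is missing field(s): ", paste(missing, collapse = ", "))
  shape <- as.integer(meta$shape)
  if (length(shape) != 3L)
    stop("expected a 3-D volume, sidecar shape has length ", length(shape))
  sp <- as.numeric(meta$spacing)
  if (length(sp) != 3L || any(!is.finite(sp)) || any(sp <= 0))
    stop("sidecar has missing or invalid voxel spacing")
  rawPath <- file.path(dirname(path), meta$data_file)
  n <- prod(shape)
  vals <- switch(meta$dtype,
    int16 = readBin(rawPath, "integer", n = n, size = 2, signed = TRUE,
                    endian = "little"),
    float64 = readBin(rawPath, "double", n = n, size = 8,
                      endian = "little"),
    stop("unsupported dtype: ", meta$dtype))
  if (length(vals) != n)
    stop("raw file holds ", length(vals), " values, expected ", n)
  arr <- array(as.double(vals), dim = shape)
  CTVolume(arr, spacing = sp,
           metadata = list(source = path, format = "raw+json"))
}

#' Write a CT volume
#'
#' Writes NIfTI-1 (double precision, so HU round-trip bit-identically) or
#' the raw+JSON sidecar dialect, chosen by the file extension
#' (\code{.nii}/\code{.nii.gz} vs \code{.json}).
#'
#' @param volume A [CTVolume-class].
#' @param path Output path.
#' @param dtype For the sidecar dialect: \code{"float64"} (lossless,
#'   default) or \code{"int16"}.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(volume, path, dtype = c("float64", "int16")) {
  stopifnot(is(volume, "CTVolume"))
  if (grepl("\\.json$", path)) {
    dtype <- match.arg(dtype)
    rawName <- sub("\\.json$", ".raw", basename(path))
    rawPath <- file.path(dirname(path), rawName)
    vals <- as.vector(volume@data)
    if (dtype == "int16") {
      if (any(vals != round(vals)))
        stop("int16 dtype requires integer-valued HU data")
      writeBin(as.integer(vals), rawPath, size = 2, endian = "little")
    } else {
      writeBin(as.double(vals), rawPath, size = 8, endian = "little")
    }
    jsonlite::write_json(
      list(shape = dim(volume@data), spacing = volume@spacing,
           dtype = dtype, data_file = rawName),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    img <- RNifti::asNifti(volume@data)
    RNifti::pixdim(img) <- volume@spacing
    RNifti::writeNifti(img, path, datatype = "double")
  }
  invisible(path)
}

#' Read a lung mask
#'
#' Reads a binary (or label-coded) mask congruent with a reference volume.
#' Nonzero voxels become \code{TRUE}; with \code{labeled = TRUE} the
#' integer codes 1/2/3 are interpreted as aerated/opacified/excluded.
#'
#' @param path Mask file (NIfTI or raw+JSON sidecar).
#' @param reference The paired [CTVolume-class]; shapes must match.
#' @param labeled Interpret voxel values as region label codes.
#' @return A [LungMask-class].
#' @export
readMask <- function(path, reference, labeled = FALSE) {
  stopifnot(is(reference, "CTVolume"))
  vol <- readVolume(path)
  if (!identical(dim(vol@data), dim(reference@data)))
    stop(sprintf("mask shape (%s) does not match volume shape (%s)",
                 paste(dim(vol@data), collapse = "x"),
                 paste(dim(reference@data), collapse = "x")))
  if (labeled) {
    LungMask(vol@data != 0, labels = array(as.integer(round(vol@data)),
                                           dim = dim(vol@data)),
             metadata = list(source = path))
  } else {
    LungMask(vol@data, metadata = list(source = path))
  }
}

#' Write a lung mask
#'
#' Binary masks are written as 0/1; labeled masks as their integer region
#' codes (1 aerated, 2 opacified, 3 excluded).
#'
#' @param mask A [LungMask-class].
#' @param volume The paired [CTVolume-class] supplying spacing.
#' @param path Output path (NIfTI or \code{.json} sidecar).
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, volume, path) {
  stopifnot(is(mask, "LungMask"), is(volume, "CTVolume"))
  if (length(mask@labels) > 0) {
    arr <- array(as.double(mask@labels), dim = dim(mask@data))
  } else {
    arr <- array(as.double(mask@data), dim = dim(mask@data))
  }
  writeVolume(CTVolume(arr, spacing = volume@spacing), path,
              dtype = "int16")
}

.COHORT_NUMERIC <- c("m_lung_g", "v_lung_ml", "height_cm", "weight_kg",
                     "age_yr", "days_ventilated", "days_in_icu",
                     "m_non_pct", "pao2_fio2")

#' Read a cohort table
#'
#' Reads a per-patient CSV with locale-tolerant numeric parsing (thousands
#' separators such as \code{"1,088"} are accepted in known numeric
#' columns). Canonical columns are \code{patient_id}, \code{m_lung_g},
#' \code{v_lung_ml}, \code{height_cm}, \code{weight_kg}, \code{sex}
#' (male/female; male is the regression reference level), \code{age_yr},
#' \code{days_ventilated}, \code{days_in_icu}, \code{m_non_pct},
#' \code{subgroup}; unknown columns are preserved untouched as opaque
#' covariates. Only the columns actually present are validated, so e.g. a
#' missing \code{sex} column surfaces at the regression call, not at load.
#'
#' @param path CSV path with a header row.
#' @param required Columns that must be present (default
#'   \code{"m_lung_g"}).
#' @return A validated \code{data.frame}.
#' @export
readCohort <- function(path, required = "m_lung_g") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cohort file is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (col in intersect(.COHORT_NUMERIC, names(df))) {
    df[[col]] <- .parseNumeric(df[[col]], col)
  }
  validateCohort(df)
}

.parseNumeric <- function(x, col) {
  if (is.numeric(x)) return(x)
  cleaned <- gsub("[, ]", "", trimws(as.character(x)))
  out <- suppressWarnings(as.numeric(cleaned))
  bad <- which(!is.na(cleaned) & cleaned != "" & is.na(out))
  if (length(bad))
    stop(sprintf("column '%s': unparseable numeric value '%s' in row %d",
                 col, x[bad[1]], bad[1]))
  out
}

#' Validate a cohort table
#'
#' Row-level range checks for the canonical columns: lung mass and volume
#' nonnegative, height positive, sex limited to male/female (converted to
#' a factor with male as the reference level, matching the dummy coding
#' male = 0 used downstream).
#'
#' @param df A cohort \code{data.frame}.
#' @return The validated (possibly type-converted) \code{data.frame}.
#' @export
validateCohort <- function(df) {
  .rowCheck <- function(col, bad, what) {
    if (any(bad, na.rm = TRUE))
      stop(sprintf("cohort column '%s': %s in row(s) %s", col, what,
                   paste(utils::head(which(bad), 5), collapse = ", ")))
  }
  if ("m_lung_g" %in% names(df))
    .rowCheck("m_lung_g", df$m_lung_g < 0, "negative lung mass")
  if ("v_lung_ml" %in% names(df))
    .rowCheck("v_lung_ml", df$v_lung_ml < 0, "negative lung volume")
  if ("height_cm" %in% names(df))
    .rowCheck("height_cm", df$height_cm <= 0, "nonpositive height")
  if ("sex" %in% names(df)) {
    sx <- tolower(trimws(as.character(df$sex)))
    .rowCheck("sex", !is.na(sx) & !(sx %in% c("male", "female")),
              "sex must be 'male' or 'female'")
    df$sex <- factor(sx, levels = c("male", "female"))
  }
  df
}

#' Write a cohort table
#'
#' CSV with numeric columns serialized at 17 significant digits, so a
#' write/read round trip preserves every double exactly.
#'
#' @param df Cohort \code{data.frame}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
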