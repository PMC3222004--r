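#' Classify patients by lung mass
#'
#' Applies a [ClassificationRule-class] to lung masses: atelectasis when
#' \eqn{M_{lung} \le} upper reference limit (the mass is normal, so the
#' airless lung must be collapsed rather than filled), above-reference
#' when it exceeds the limit, and additionally consolidation when it
#' exceeds the consolidation cut-off (mass increased into the range
#' reported for consolidated, injured lungs). The categories are nested:
#' every consolidation patient is also above-reference.
#'
#' @param mLung Numeric vector of lung masses, g (\eqn{\ge 0}).
#' @param rule A [ClassificationRule-class].
#' @return Data frame of logical columns \code{atelectasis},
#'   \code{above_reference}, \code{consolidation}, one row per patient.
#' @examples
#' classifyMlung(c(899, 1200, 1930), classificationRule())
#' @export
classifyMlung <- function(mLung, rule = classificationRule()) {
  stopifnot(is(rule, "ClassificationRule"))
  if (any(mLung < 0, na.rm = TRUE)) stop("lung mass must be >= 0")
  data.frame(
    atelectasis = mLung <= rule@upperReference,
    above_reference = mLung > rule@upperReference,
    consolidation = mLung > rule@consolidationCut
  )
}

#' Derive a classification rule from a reference cohort
#'
#' Screens the reference cohort for truly normal lungs (nonaerated mass
#' percentage at most \code{mNonCap}; patients failing the screen are
#' excluded and reported), then sets the atelectasis/above-reference
#' boundary to the upper limit of the reference interval of lung mass.
#' The consolidation cut-off is not derivable from normal lungs; it is a
#' literature constant supplied via \code{consolidationCut}.
#'
#' @param referenceCohort Cohort data frame with \code{m_lung_g} and
#'   optionally \code{m_non_pct}.
#' @param method \code{"robust"} (default, recommended for n < 120) or
#'   \code{"nonparametric"}.
#' @param coverage Reference-interval coverage.
#' @param mNonCap Maximum nonaerated mass percentage for a patient to
#'   count as normal-lung (default 5).
#' @param consolidationCut Consolidation cut-off in g (default 1380).
#' @return A [ClassificationRule-class]; \code{metadata} records the
#'   fitted interval and any screen exclusions.
#' @export
deriveReferenceRule <- function(referenceCohort,
                                method = c("robust", "nonparametric"),
                                coverage = 0.95, mNonCap = 5,
                                consolidationCut = 1380) {
  method <- match.arg(method)
  if (!"m_lung_g" %in% names(referenceCohort))
    stop("reference cohort needs column 'm_lung_g'")
  df <- referenceCohort
  excluded <- integer(0)
  if ("m_non_pct" %in% names(df)) {
    bad <- which(df$m_non_pct > mNonCap)
    if (length(bad)) {
      ids <- if ("patient_id" %in% names(df)) df$patient_id[bad] else bad
      warning("excluded from reference fit (m_non_pct > ", mNonCap,
              "%): ", paste(ids, collapse = ", "))
      excluded <- bad
      df <- df[-bad, , drop = FALSE]
    }
  }
  x <- df$m_lung_g
  ri <- if (length(unique(x)) == 1L) {
    # degenerate cohort: rule collapses to the constant
    new("ReferenceInterval", lower = x[1], upper = x[1],
        coverage = coverage, method = method, n = as.integer(length(x)))
  } else if (method == "robust") {
    robustReferenceInterval(x, coverage = coverage)
  } else {
    nonparametricReferenceInterval(x, coverage = coverage)
  }
  upper <- ri@upper
  if (upper >= consolidationCut)
    stop("reference upper limit (", round(upper),
         " g) is not below the consolidation cut-off (", consolidationCut,
         " g); check the cohort or supply a different cut")
  new("ClassificationRule", upperReference = upper,
      consolidationCut = consolidationCut,
      metadata = list(interval = ri, screenExcluded = excluded,
                      mNonCap = mNonCap))
}

#' Support-free days within a follow-up window
#'
#' Days alive and free of mechanical ventilation (or ICU treatment)
#' within a fixed window: \code{max(0, window - daysOnSupport)}. By
#' default deaths are not penalized (observed support days are counted as
#' is); set \code{zeroOnDeath} to assign zero free days to patients who
#' died within the window.
#'
#' @param daysOnSupport Nonnegative days on support.
#' @param window Follow-up window in days (default 28).
#' @param died Optional logical vector.
#' @param zeroOnDeath Apply the zero-free-days-on-death convention.
#' @return Free days (same length as \code{daysOnSupport}).
#' @examples
#' freeDays(c(28, 11, 0))  # 0, 17, 28
#' @export
freeDays <- function(daysOnSupport, window = 28, died = NULL,
                     zeroOnDeath = FALSE) {
  if (any(daysOnSupport < 0, na.rm = TRUE))
    stop("days on support must be >= 0")
  out <- pmax(0, window - daysOnSupport)
  if (zeroOnDeath && !is.null(died)) out[died] <- 0
  out
}

#' Estimated body weight from height
#'
#' The bedside estimate used when actual weight is unmeasurable in
#' emergency patients: weight in kg equals height in cm minus 100.
#'
#' @param heightCm Height in cm; must exceed 100.
#' @return Estimated weight in kg.
#' @examples
#' estimatedBodyWeight(176)  # 76
#' @export
estimatedBodyWeight <- function(heightCm) {
  if (any(heightCm <= 100, na.rm = TRUE))
    stop("height must exceed 100 cm for the height-minus-100 estimate")
  heightCm - 100
}

.STUDY_VARS <- c("age_yr", "pao2_fio2", "v_lung_ml", "m_lung_g",
                 "m_non_pct", "vent_free_days", "icu_free_days")

#' Build study subgroup tables
#'
#' Classifies a cohort by lung mass and emits per-subgroup summaries
#' (n, %, median and quartiles of each available study variable) plus
#' rank-based comparisons between the atelectasis and consolidation
#' subgroups. Because consolidation is nested inside above-reference,
#' the above-reference column is reported in both the nested variant
#' (including consolidation patients) and the disjoint variant
#' (consolidation patients removed).
#'
#' Summaries retain full precision; rounding (e.g. medians to integers)
#' is a presentation concern, applied by [formatStudyTable()] only.
#'
#' @param cohort Cohort data frame with \code{m_lung_g}; additional study
#'   variables (see Details) are summarized when present.
#' @param rule A [ClassificationRule-class].
#' @param variables Columns to summarize; defaults to the study set
#'   intersected with what the cohort provides.
#' @return A list: \code{counts} (per-subgroup n and percent),
#'   \code{summary} (long data frame: subgroup, variable, n, median, q1,
#'   q3), \code{comparisons} (atelectasis vs consolidation tests; NA and
#'   a notice when a subgroup is empty or a singleton).
#' @export
buildStudyTables <- function(cohort, rule = classificationRule(),
                             variables = NULL) {
  if (!"m_lung_g" %in% names(cohort))
    stop("cohort needs column 'm_lung_g'")
  if (is.null(variables))
    variables <- intersect(.STUDY_VARS, names(cohort))
  cls <- classifyMlung(cohort$m_lung_g, rule)
  n <- nrow(cohort)
  groups <- list(
    atelectasis = cls$atelectasis,
    above_reference = cls$above_reference,
    above_reference_only = cls$above_reference & !cls$consolidation,
    consolidation = cls$consolidation
  )
  counts <- data.frame(
    subgroup = names(groups),
    n = vapply(groups, sum, integer(1)),
    percent = round(100 * vapply(groups, sum, integer(1)) / n),
    row.names = NULL, stringsAsFactors = FALSE)

  summ <- do.call(rbind, lapply(names(groups), function(gn) {
    idx <- groups[[gn]]
    do.call(rbind, lapply(variables, function(v) {
      xi <- cohort[[v]][idx]
      xi <- xi[!is.na(xi)]
      if (length(xi) == 0) {
        data.frame(subgroup = gn, variable = v, n = 0L,
                   median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                   stringsAsFactors = FALSE)
      } else {
        q <- stats::quantile(xi, c(0.25, 0.5, 0.75), names = FALSE)
        data.frame(subgroup = gn, variable = v, n = length(xi),
                   median = q[2], q1 = q[1], q3 = q[3],
                   stringsAsFactors = FALSE)
      }
    }))
  }))

  atel <- groups$atelectasis
  cons <- groups$consolidation
  comparisons <- do.call(rbind, lapply(variables, function(v) {
    xa <- cohort[[v]][atel]
    xc <- cohort[[v]][cons]
    if (sum(!is.na(xa)) < 2 || sum(!is.na(xc)) < 2) {
      message("comparison skipped for '", v,
              "': a subgroup has fewer than 2 observations")
      return(data.frame(variable = v, test = NA_character_,
                        statistic = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    d <- data.frame(value = c(xa, xc),
                    grp = rep(c("atelectasis", "consolidation"),
                              c(length(xa), length(xc))))
    ct <- compareGroups(d, "value", "grp")
    data.frame(variable = v, test = ct$test, statistic = ct$statistic,
               p = ct$p.value, stringsAsFactors = FALSE)
  }))

  list(counts = counts, summary = summ, comparisons = comparisons)
}

#' Format a study table for display
#'
#' Renders the output of [buildStudyTables()] with the conventional
#' presentation: medians and quartiles rounded to integers, counts as
#' "n (percent%)".
#'
#' @param tables Result of [buildStudyTables()].
#' @return A data frame of formatted strings, variables in rows and
#'   subgroups in columns.
#' @export
formatStudyTable <- function(tables) {
  s <- tables$summary
  subgroups <- unique(s$subgroup)
  vars <- unique(s$variable)
  out <- data.frame(variable = vars, stringsAsFactors = FALSE)
  for (gn in subgroups) {
    col <- vapply(vars, function(v) {
      r <- s[s$subgroup == gn & s$variable == v, ]
      if (nrow(r) == 0 || is.na(r$median)) return("-")
      sprintf("%d (%d to %d)", round(r$median), round(r$q1), round(r$q3))
    }, character(1))
    out[[gn]] <- col
  }
  hdr <- tables$counts
  cnt <- c("n (%)", vapply(subgroups, function(gn) {
    r <- hdr[hdr$subgroup == gn, ]
    sprintf("%d (%d%%)", r$n, r$percent)
  }, character(1)))
  rbind(stats::setNames(as.data.frame(as.list(cnt),
                                      stringsAsFactors = FALSE),
                        names(out)), out)
}

#' Run the full cohort pipeline
#'
#' End-to-end replica of the study workflow: derive the classification
#' rule from a reference cohort, classify the patient cohort, and emit
#' the subgroup tables together with a run manifest (inputs, rule,
#' parameters) for reproducibility.
#'
#' @param cohort Patient cohort data frame (e.g. from [readCohort()]).
#' @param referenceCohort Reference (normal-lung) cohort data frame.
#' @param consolidationCut Literature consolidation cut-off, g.
#' @param method Reference-interval method.
#' @return A list: \code{rule}, \code{classification}, \code{tables},
#'   \code{manifest}.
#' @export
runCohortPipeline <- function(cohort, referenceCohort,
                              consolidationCut = 1380,
                              method = c("robust", "nonparametric")) {
  method <- match.arg(method)
  rule <- deriveReferenceRule(referenceCohort, method = method,
                              consolidationCut = consolidationCut)
  cls <- classifyMlung(cohort$m_lung_g, rule)
  tables <- buildStudyTables(cohort, rule)
  manifest <- list(
    n_cohort = nrow(cohort),
    n_reference = nrow(referenceCohort),
    method = method,
    upper_reference_g = rule@upperReference,
    consolidation_cut_g = rule@consolidationCut,
    screen_excluded = rule@metadata$screenExcluded,
    package_version = as.character(utils::packageVersion("qctlung"))
  )
  list(rule = rule, classification = cls, tables = tables,
       manifest = manifest)
}
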