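#' Robust reference interval (CLSI C28-A3 style)
#'
#' Outlier-resistant reference limits recommended when the reference
#' sample is smaller than 120 subjects. The procedure follows the
#' Horn/Pesce biweight construction: a Tukey biweight location estimate
#' iterated from the median with MAD-based standardization (tuning
#' constant \code{locationC}), a biweight spread estimate combining a
#' wide-constant scale (\code{spreadC}, approximating the population SD)
#' with the standard error of the robust location, and limits
#' \deqn{T_{bi} \pm t_{(1+coverage)/2,\,n-1}
#'       \sqrt{s_{bi}(spreadC)^2 + s_{bi}(locationC)^2 / n}.}
#' Every constant is an argument so that guideline variants can be
#' explored.
#'
#' @param values Numeric sample (e.g. lung masses in g); requires
#'   \eqn{n \ge 20}, warns below 40.
#' @param coverage Fraction of the population the interval should span.
#' @param locationC Biweight tuning constant for the location iteration
#'   and its standard error (3.7).
#' @param spreadC Wide tuning constant for the population-spread estimate
#'   (205.6).
#' @param tol Absolute convergence tolerance of the location iteration.
#' @param maxIter Iteration cap; non-convergence is an error reporting
#'   the iteration trace.
#' @return A [ReferenceInterval-class] with \code{method = "robust"}.
#' @seealso [nonparametricReferenceInterval()]
#' @export
robustReferenceInterval <- function(values, coverage = 0.95,
                                    locationC = 3.7, spreadC = 205.6,
                                    tol = 1e-6, maxIter = 100) {
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("values must be finite")
  n <- length(x)
  if (n < 20) stop("robust reference interval requires n >= 20 (got ",
                   n, ")")
  if (n < 40)
    warning("n < 40: robust reference limits will be imprecise")
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")

  med <- stats::median(x)
  if (all(x == x[1])) {
    warning("all values identical: degenerate reference interval")
    return(new("ReferenceInterval", lower = med, upper = med,
               coverage = coverage, method = "robust", n = as.integer(n)))
  }
  scale <- stats::median(abs(x - med)) / 0.6745
  if (scale == 0) {
    warning("MAD is zero; falling back to SD-based standardization")
    scale <- stats::sd(x)
  }

  # biweight location, iterated from the median
  Tbi <- med
  trace <- numeric(0)
  converged <- FALSE
  for (i in seq_len(maxIter)) {
    u <- (x - Tbi) / (locationC * scale)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) stop("all observations downweighted to zero")
    TbiNew <- sum(w * x) / sum(w)
    trace <- c(trace, TbiNew)
    if (abs(TbiNew - Tbi) < tol) {
      Tbi <- TbiNew
      converged <- TRUE
      break
    }
    Tbi <- TbiNew
  }
  if (!converged)
    stop("biweight location did not converge in ", maxIter,
         " iterations; last estimates: ",
         paste(sprintf("%.6f", utils::tail(trace, 5)), collapse = ", "))

  sbi <- function(cc) {
    u <- (x - med) / (cc * scale)
    keep <- abs(u) < 1
    num <- sqrt(n * sum(((x - med)[keep])^2 * (1 - u[keep]^2)^4))
    den <- abs(sum((1 - u[keep]^2) * (1 - 5 * u[keep]^2)))
    num / den
  }
  spread <- sqrt(sbi(spreadC)^2 + sbi(locationC)^2 / n)
  tmult <- stats::qt(1 - (1 - coverage) / 2, df = n - 1)
  new("ReferenceInterval",
      lower = Tbi - tmult * spread, upper = Tbi + tmult * spread,
      coverage = coverage, method = "robust", n = as.integer(n))
}

#' Nonparametric reference interval
#'
#' Empirical percentile limits (the guideline's comparison baseline for
#' large samples): the \eqn{(1-coverage)/2} and \eqn{(1+coverage)/2}
#' sample quantiles. The default interpolation is R's type 7 (linear on
#' the order statistics with plotting position \eqn{(k-1)/(n-1)}); the
#' rank-based convention \eqn{(n+1)p} is available as \code{type = 6}.
#'
#' @param values Numeric sample, \eqn{n \ge 2}.
#' @param coverage Central coverage fraction.
#' @param type Quantile interpolation type passed to
#'   [stats::quantile()].
#' @return A [ReferenceInterval-class] with
#'   \code{method = "nonparametric"}.
#' @export
nonparametricReferenceInterval <- function(values, coverage = 0.95,
                                           type = 7) {
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("values must be finite")
  if (length(x) < 2) stop("need at least 2 values")
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  a <- (1 - coverage) / 2
  q <- stats::quantile(x, probs = c(a, 1 - a), type = type, names = FALSE)
  new("ReferenceInterval", lower = q[1], upper = q[2],
      coverage = coverage, method = "nonparametric",
      n = as.integer(length(x)))
}

#' Confidence interval for a reported mean
#'
#' t-based confidence limits \eqn{\bar x \pm t_{1-\alpha/2, n-1}\,
#' s/\sqrt n} for means reported in the literature with their SD and n --
#' used to compare one's own reference sample against previously
#' published normal values.
#'
#' @param mean Reported mean.
#' @param sd Reported standard deviation (\eqn{\ge 0}).
#' @param n Sample size (\eqn{\ge 2}).
#' @param level Confidence level.
#' @return Numeric \code{c(lower, upper)}.
#' @examples
#' ciOfMean(100, 10, 25)  # 100 +/- 2.0639 * 2
#' @export
ciOfMean <- function(mean, sd, n, level = 0.95) {
  if (n < 2) stop("n must be >= 2")
  if (sd < 0) stop("sd must be >= 0")
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * sd / sqrt(n)
  c(lower = mean - half, upper = mean + half)
}

#' Percent-difference Bland-Altman agreement
#'
#' For paired measurements of the same quantity by two methods, computes
#' per-pair percent differences
#' \eqn{d_i = 100\,(A_i - B_i) / ((A_i + B_i)/2)} (the pairwise-mean
#' denominator; a global-mean denominator is available by flag), the mean
#' difference (bias) and the limits of agreement
#' \eqn{bias \pm 1.96\,SD(d)}.
#'
#' @param a,b Positive paired measurements (method A, method B).
#' @param denominator \code{"pairwise"} (default) or \code{"global"}.
#' @return An [AgreementResult-class].
#' @export
blandAltmanPercent <- function(a, b,
                               denominator = c("pairwise", "global")) {
  denominator <- match.arg(denominator)
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  if (any(a <= 0) || any(b <= 0))
    stop("all paired measurements must be positive")
  denom <- switch(denominator,
                  pairwise = (a + b) / 2,
                  global = mean((a + b) / 2))
  d <- 100 * (a - b) / denom
  bias <- mean(d)
  s <- stats::sd(d)
  new("AgreementResult", biasPercent = bias,
      loaLowPercent = bias - 1.96 * s, loaHighPercent = bias + 1.96 * s,
      sdPercent = s, nPairs = as.integer(length(a)), differences = d)
}

#' Geometric ROI mass
#'
#' Reference mass of a region of interest computed without densitometry:
#' ROI area times slice thickness times the volumetric mass density of
#' water (0.99777 g/ml at 22 degrees C). Serves as the independent oracle
#' when validating the voxel-wise mass estimate against a water-filled
#' bottle placed beside the thorax.
#'
#' @param areaCm2 ROI area in cm^2 (\eqn{\ge 0}).
#' @param thicknessMm Slice thickness in mm (> 0).
#' @param density Water density in g/ml.
#' @return Mass in g.
#' @examples
#' geometricRoiMass(2, 5)  # 0.99777 g
#' @export
geometricRoiMass <- function(areaCm2, thicknessMm, density = 0.99777) {
  if (any(areaCm2 < 0)) stop("ROI area must be >= 0")
  if (any(thicknessMm <= 0)) stop("slice thickness must be > 0")
  areaCm2 * thicknessMm / 10 * density
}

#' Hierarchical regression with a variance-retention rule
#'
#' Ordinary least squares fitted block by block in a prespecified order
#' (e.g. height; then sex; then age; then group). Each added block is
#' judged by the increase in R-squared it brings and the F test for that
#' change; a block is kept in the final model only if its R-squared
#' change meets \code{retentionThreshold} (the a priori rule that a
#' variable must explain at least 5\% of the variance). Factors are
#' expanded by the usual treatment contrasts, so a \code{sex} factor with
#' levels male/female yields the dummy coding male = 0, female = 1.
#'
#' @param data Data frame (e.g. a cohort table).
#' @param response Response column name (e.g. \code{"m_lung_g"}).
#' @param blocks Ordered list of character vectors of predictor column
#'   names; a single character vector is treated as one block per
#'   element.
#' @param retentionThreshold Minimum R-squared change for retention
#'   (default 0.05).
#' @param level Confidence level for coefficient intervals.
#' @return A [RegressionReport-class].
#' @export
hierarchicalRegression <- function(data, response, blocks,
                                   retentionThreshold = 0.05,
                                   level = 0.95) {
  if (!is.list(blocks)) blocks <- as.list(blocks)
  vars <- unlist(blocks)
  if (anyDuplicated(vars))
    stop("predictor(s) appear in more than one block: ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "))
  missingCols <- setdiff(c(response, vars), names(data))
  if (length(missingCols))
    stop("column(s) not in data: ", paste(missingCols, collapse = ", "))
  used <- data[, c(response, vars), drop = FALSE]
  if (anyNA(used))
    stop("missing values in response or predictor columns")
  n <- nrow(used)
  if (n <= length(vars) + 2)
    stop("need n > number of predictors + 2")

  fits <- vector("list", length(blocks) + 1)
  fits[[1]] <- stats::lm(stats::reformulate("1", response), data = data)
  r2 <- 0
  blockNames <- vapply(blocks, paste, character(1), collapse = "+")
  stats_df <- data.frame(block = blockNames, r_squared = NA_real_,
                         delta_r_squared = NA_real_, f = NA_real_,
                         p = NA_real_, retained = NA,
                         stringsAsFactors = FALSE)
  for (k in seq_along(blocks)) {
    terms_k <- unlist(blocks[seq_len(k)])
    fit <- stats::lm(stats::reformulate(terms_k, response), data = data)
    if (any(is.na(stats::coef(fit))))
      stop("perfect collinearity introduced by block '", blockNames[k],
           "'")
    r2new <- summary(fit)$r.squared
    an <- stats::anova(fits[[k]], fit)
    stats_df$r_squared[k] <- r2new
    stats_df$delta_r_squared[k] <- r2new - r2
    stats_df$f[k] <- an$F[2]
    stats_df$p[k] <- an$`Pr(>F)`[2]
    stats_df$retained[k] <- (r2new - r2) >= retentionThreshold
    fits[[k + 1]] <- fit
    r2 <- r2new
  }

  kept <- unlist(blocks[stats_df$retained])
  finalFit <- if (length(kept)) {
    stats::lm(stats::reformulate(kept, response), data = data)
  } else {
    fits[[1]]
  }
  cf <- stats::coef(finalFit)
  ci <- stats::confint(finalFit, level = level)
  coefs <- data.frame(term = names(cf), estimate = unname(cf),
                      ci_lower = ci[, 1], ci_upper = ci[, 2],
                      row.names = NULL, stringsAsFactors = FALSE)
  new("RegressionReport", blockStats = stats_df, coefficients = coefs,
      retentionThreshold = retentionThreshold, level = level,
      n = as.integer(n))
}

#' Rank-based group comparison
#'
#' Two groups are compared with the two-sided Mann-Whitney U test, more
#' than two with the Kruskal-Wallis test. Ties are handled by midranks
#' with the normal approximation and tie correction; with both groups of
#' size at most \code{exactMax} and no ties, the exact Mann-Whitney
#' distribution is used. No multiplicity correction is applied; p-values
#' are reported unadjusted and two-sided.
#'
#' @param data Data frame.
#' @param variable Name of the numeric column to compare.
#' @param grouping Name of the grouping column.
#' @param exactMax Largest per-group n for the exact two-group test.
#' @return A list: \code{test}, \code{statistic}, \code{p.value}, and a
#'   per-group \code{summary} data frame (n, median, quartiles).
#' @export
compareGroups <- function(data, variable, grouping, exactMax = 20) {
  if (!all(c(variable, grouping) %in% names(data)))
    stop("column(s) not in data: ",
         paste(setdiff(c(variable, grouping), names(data)),
               collapse = ", "))
  x <- data[[variable]]
  g <- factor(data[[grouping]])
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes == 0)) stop("every group must be nonempty")
  if (any(sizes < 2))
    warning("group(s) with fewer than 2 observations: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))

  summ <- do.call(rbind, lapply(levels(g), function(l) {
    xi <- x[g == l]
    q <- stats::quantile(xi, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = l, n = length(xi), median = q[2], q1 = q[1],
               q3 = q[3], stringsAsFactors = FALSE)
  }))

  if (nlevels(g) == 2) {
    xa <- x[g == levels(g)[1]]
    xb <- x[g == levels(g)[2]]
    exact <- max(sizes) <= exactMax && !anyDuplicated(x)
    ht <- suppressWarnings(
      stats::wilcox.test(xa, xb, alternative = "two.sided",
                         exact = exact, correct = !exact))
    list(test = "mann-whitney", statistic = unname(ht$statistic),
         p.value = ht$p.value, summary = summ)
  } else {
    ht <- stats::kruskal.test(x, g)
    list(test = "kruskal-wallis", statistic = unname(ht$statistic),
         p.value = ht$p.value, summary = summ)
  }
}
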