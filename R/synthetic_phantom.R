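# Generators are pure functions of (spec, seed): RNG state is saved and
# restored around every draw.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

.COMP_RANGES <- list(
  hyperaerated = c(-1000, -901),
  normally_aerated = c(-900, -501),
  poorly_aerated = c(-500, -101),
  nonaerated = c(-100, 100)
)

# voxel-center coordinate grids in mm, as vectors along each axis
.axisCoords <- function(dim, spacing) {
  lapply(1:3, function(k) (seq_len(dim[k]) - 0.5) * spacing[k])
}

.ellipsoidMask <- function(dim, spacing, center, semi) {
  co <- .axisCoords(dim, spacing)
  ux <- (co[[1]] - center[1]) / semi[1]
  uy <- (co[[2]] - center[2]) / semi[2]
  uz <- (co[[3]] - center[3]) / semi[3]
  q <- outer(outer(ux^2, uy^2, `+`), uz^2, `+`)
  q <= 1
}

#' Generate a synthetic thoracic CT phantom
#'
#' Builds a deterministic synthetic thorax from a [PhantomSpec-class]: an
#' air background, a soft-tissue body, two ellipsoidal lungs whose voxels
#' are drawn from the requested mixture of aeration compartments, plus
#' the optional water bottle, dense lesion, partial-volume rim and
#' out-of-range voxels. Ground-truth mass and volume are computed by
#' direct summation over the assigned pre-noise HU field -- a code path
#' independent of [summarizeAeration()] -- before Gaussian HU noise is
#' added, so the phantom carries its own oracle.
#'
#' @param spec A [PhantomSpec-class].
#' @param seed Overrides \code{spec@seed} when given.
#' @return A list with elements \code{volume} ([CTVolume-class]),
#'   \code{mask} ([LungMask-class], aerated/opacified labels),
#'   \code{truth} ([GroundTruth-class]) and, when a bottle is present,
#'   \code{bottleMask} (logical array).
#' @export
makeThoraxPhantom <- function(spec = phantomSpec(), seed = NULL) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  if (is.null(seed)) seed <- spec@seed
  .withSeed(seed, .buildPhantom(spec))
}

.buildPhantom <- function(spec) {
  dm <- spec@dim
  sp <- spec@spacing
  extent <- dm * sp
  vv <- prod(sp) / 1000

  hu <- array(-1000, dim = dm)  # air background

  # soft-tissue body: elliptic cylinder through all slices
  bodyC <- c(0.50, 0.62) * extent[1:2]
  bodyR <- c(0.38, 0.30) * extent[1:2]
  co <- .axisCoords(dm, sp)
  bodyXY <- outer(((co[[1]] - bodyC[1]) / bodyR[1])^2,
                  ((co[[2]] - bodyC[2]) / bodyR[2])^2, `+`) <= 1
  body <- array(bodyXY, dim = dm)
  hu[body] <- spec@chestWallHu

  # two ellipsoidal lungs sized to the target total volume
  aspect <- c(0.8, 1.1, 1.45)
  s <- (spec@lungVolumeMl * 1000 /
          (2 * (4 / 3) * pi * prod(aspect)))^(1 / 3)
  semi <- aspect * s
  centers <- list(
    c(0.26 * extent[1], 0.62 * extent[2], 0.5 * extent[3]),
    c(0.74 * extent[1], 0.62 * extent[2], 0.5 * extent[3])
  )
  for (ctr in centers) {
    if (any(ctr - semi < 0.5 * sp) || any(ctr + semi > extent - 0.5 * sp))
      stop("lung ellipsoid overlaps the grid edge; ",
           "enlarge dim or reduce lungVolumeMl")
  }
  lung <- .ellipsoidMask(dm, sp, centers[[1]], semi) |
          .ellipsoidMask(dm, sp, centers[[2]], semi)
  lungIdx <- which(lung)
  nL <- length(lungIdx)
  if (nL == 0) stop("phantom lungs contain no voxels")

  # compartment assignment and in-compartment HU sampling
  labs <- names(.COMP_RANGES)
  fr <- spec@fractions[labs]
  compIdx <- sample.int(4L, nL, replace = TRUE, prob = fr)
  huLung <- numeric(nL)
  for (k in 1:4) {
    sel <- compIdx == k
    if (!any(sel)) next
    rg <- .COMP_RANGES[[k]]
    if (labs[k] %in% names(spec@fixedHu)) {
      huLung[sel] <- spec@fixedHu[[labs[k]]]
    } else if (spec@huDistribution == "uniform") {
      huLung[sel] <- stats::runif(sum(sel), rg[1], rg[2])
    } else {
      mid <- mean(rg)
      huLung[sel] <- pmin(pmax(
        stats::rnorm(sum(sel), mid, diff(rg) / 6), rg[1]), rg[2])
    }
  }
  hu[lungIdx] <- huLung

  # dense (opacified) lesion: sphere inside the right lung
  lesion <- array(FALSE, dim = dm)
  if (spec@lesionVolumeMl > 0) {
    rLes <- (spec@lesionVolumeMl * 1000 / ((4 / 3) * pi))^(1 / 3)
    lesC <- centers[[2]]
    lesion <- .ellipsoidMask(dm, sp, lesC, rep(rLes, 3)) & lung
    nLes <- sum(lesion)
    if (nLes == 0) stop("lesion volume too small for this grid")
    hu[lesion] <- stats::runif(nLes, spec@lesionHuRange[1],
                               spec@lesionHuRange[2])
  }

  # optional water bottle: cylinder in the air gap in front of the body
  bottle <- NULL
  if (spec@includeBottle) {
    r <- spec@bottleRadiusMm
    len <- spec@bottleLengthMm
    bc <- c(0.5 * extent[1], bodyC[2] - bodyR[2] - r - 2 * max(sp[1:2]),
            0.5 * extent[3])
    if (bc[2] - r < 0.5 * sp[2] || bc[3] - len / 2 < 0.5 * sp[3] ||
        bc[3] + len / 2 > extent[3] - 0.5 * sp[3])
      stop("bottle overlaps the grid edge; ",
           "reduce bottleRadiusMm/bottleLengthMm or enlarge dim")
    discXY <- outer((co[[1]] - bc[1])^2, (co[[2]] - bc[2])^2, `+`) <= r^2
    inZ <- abs(co[[3]] - bc[3]) <= len / 2
    bottle <- array(FALSE, dim = dm)
    bottle[, , which(inZ)] <- discXY
    hu[bottle] <- spec@bottleHu
  }

  # partial-volume rim: linear blending over rimWidth boundary layers,
  # lungs toward soft tissue, bottle toward surrounding air
  if (spec@rimWidth > 0) {
    hu <- .blendRim(hu, lung, spec@rimWidth, spec@chestWallHu)
    if (!is.null(bottle))
      hu <- .blendRim(hu, bottle, spec@rimWidth, -1000)
  }

  # deliberately out-of-range voxels (contrast-bright vessels)
  if (spec@nOutOfRange > 0) {
    if (spec@nOutOfRange > nL)
      stop("nOutOfRange exceeds the number of lung voxels")
    oor <- sample(lungIdx, spec@nOutOfRange)
    hu[oor] <- 250
  }

  truth <- .bookkeepTruth(hu, lung, lesion, bottle, vv, spec)

  if (spec@noiseSd > 0) {
    hu <- hu + stats::rnorm(length(hu), 0, spec@noiseSd)
  }

  labels <- array(0L, dim = dm)
  labels[lung] <- 1L
  labels[lesion] <- 2L
  out <- list(
    volume = CTVolume(hu, spacing = sp,
                      metadata = list(generator = "makeThoraxPhantom",
                                      seed = spec@seed)),
    mask = LungMask(lung, labels = labels),
    truth = truth
  )
  if (!is.null(bottle)) out$bottleMask <- bottle
  out
}

.blendRim <- function(hu, mask, rimWidth, targetHu) {
  eroded <- mask
  for (l in seq_len(rimWidth)) {
    inner <- .erodeOnce(eroded)
    layer <- eroded & !inner
    alpha <- (rimWidth - l + 1) / (rimWidth + 1)
    hu[layer] <- (1 - alpha) * hu[layer] + alpha * targetHu
    eroded <- inner
  }
  hu
}

# ground-truth bookkeeping: direct summation over the pre-noise HU field,
# deliberately not calling summarizeAeration()
.bookkeepTruth <- function(hu, lung, lesion, bottle, vv, spec) {
  huL <- hu[lung]
  inWin <- huL >= -1000 & huL <= 100
  huIn <- huL[inWin]
  dens <- (huIn + 1000) / 1000  # rhoRef = 1 g/ml bookkeeping convention
  breaks <- c(-1000, -900.5, -500.5, -100.5, 100)
  labs <- names(.COMP_RANGES)
  bin <- findInterval(huIn, breaks, rightmost.closed = TRUE)
  compVol <- vapply(1:4, function(k) sum(bin == k) * vv, numeric(1))
  compMass <- vapply(1:4, function(k) sum(dens[bin == k]) * vv,
                     numeric(1))
  names(compVol) <- names(compMass) <- labs

  lesMass <- lesVol <- 0
  if (any(lesion)) {
    huLes <- hu[lesion]
    ok <- huLes >= -1000 & huLes <= 100
    lesVol <- sum(ok) * vv
    lesMass <- sum((huLes[ok] + 1000) / 1000) * vv
  }
  botMass <- botVol <- 0
  if (!is.null(bottle)) {
    huB <- hu[bottle]
    botVol <- sum(bottle) * vv
    botMass <- sum((huB + 1000) / 1000) * vv
  }
  new("GroundTruth",
      totalVolumeMl = sum(compVol), totalMassG = sum(compMass),
      compartmentVolumeMl = compVol, compartmentMassG = compMass,
      bottleMassG = botMass, bottleVolumeMl = botVol,
      lesionMassG = lesMass, lesionVolumeMl = lesVol,
      nOutOfRange = as.integer(sum(!inWin)),
      params = list(spec = spec, voxelVolumeMl = vv,
                    rhoRef = 1.0))
}

#' Simulate the water-bottle validation study
#'
#' Reproduces the design of the mass-estimator validation: a water-filled
#' bottle is imaged beside the thorax and, for a number of regions of
#' interest inside it, the voxel-wise densitometric mass is compared with
#' the geometric mass (ROI area x slice thickness x water density). With
#' \code{roiMode = "interior"}, ROIs are random rectangles placed deep
#' inside the bottle (any candidate escaping the safe interior is
#' resampled and logged); with \code{roiMode = "edge"}, each ROI is a
#' full bottle cross-section including the partial-volume rim, which
#' biases the voxel-wise mass low, as at real bottle boundaries.
#'
#' @param nRois Number of ROIs (the original validation used 27).
#' @param spec A [PhantomSpec-class]; must have \code{includeBottle}.
#' @param roiMode \code{"interior"} or \code{"edge"}.
#' @param model [DensityModel-class] for the voxel-wise mass; defaults to
#'   the physical water density so both methods share the same density.
#' @param seed RNG seed for ROI placement (defaults to
#'   \code{spec@seed + 1}).
#' @return Data frame with one row per ROI: \code{voxel_mass_g},
#'   \code{geometric_mass_g}, \code{slice}, \code{n_voxels}.
#' @seealso [blandAltmanPercent()]
#' @export
makeBottleValidationSet <- function(nRois = 27,
                                    spec = phantomSpec(
                                      includeBottle = TRUE,
                                      bottleRadiusMm = 25),
                                    roiMode = c("interior", "edge"),
                                    model = densityModel(rhoRef = 0.99777),
                                    seed = NULL) {
  roiMode <- match.arg(roiMode)
  if (nRois < 2) stop("need at least 2 ROIs")
  if (!spec@includeBottle) stop("spec must include a bottle")
  if (is.null(seed)) seed <- spec@seed + 1L

  ph <- makeThoraxPhantom(spec)
  vol <- ph$volume
  bottle <- ph$bottleMask
  vv <- voxelVolumeMl(vol)
  dz <- spacing(vol)[3]
  pixAreaCm2 <- prod(spacing(vol)[1:2]) / 100

  interior <- erodeMask(bottle, spec@rimWidth + 1L)
  zHas <- which(apply(bottle, 3, any))
  zDeep <- which(apply(interior, 3, any))

  .withSeed(seed, {
    rows <- vector("list", nRois)
    nResampled <- 0L
    for (i in seq_len(nRois)) {
      if (roiMode == "edge") {
        z <- sample(zHas, 1)
        roi <- array(FALSE, dim = dim(bottle))
        roi[, , z] <- bottle[, , z]
      } else {
        repeat {
          z <- sample(zDeep, 1)
          cand <- which(interior[, , z], arr.ind = TRUE)
          ctr <- cand[sample.int(nrow(cand), 1), ]
          hx <- sample(2:5, 1); hy <- sample(2:5, 1)
          xs <- (ctr[1] - hx):(ctr[1] + hx)
          ys <- (ctr[2] - hy):(ctr[2] + hy)
          inGrid <- all(xs >= 1 & xs <= dim(bottle)[1]) &&
                    all(ys >= 1 & ys <= dim(bottle)[2])
          if (inGrid && all(interior[xs, ys, z])) break
          nResampled <- nResampled + 1L
        }
        roi <- array(FALSE, dim = dim(bottle))
        roi[xs, ys, z] <- TRUE
      }
      nVox <- sum(roi)
      summ <- summarizeAeration(vol, LungMask(roi), model = model)
      geo <- geometricRoiMass(nVox * pixAreaCm2, dz,
                              density = model@rhoRef)
      rows[[i]] <- data.frame(roi = i, slice = z, n_voxels = nVox,
                              voxel_mass_g = mLung(summ),
                              geometric_mass_g = geo)
    }
    if (nResampled > 0)
      message(nResampled, " ROI candidate(s) escaped the bottle ",
              "interior and were resampled")
    do.call(rbind, rows)
  })
}

#' Generate a synthetic reference (normal-lung) cohort
#'
#' Emulates a cohort of trauma patients with normal lungs: heights and
#' sexes are drawn first, lung mass follows the generative regression
#' \eqn{M_{lung} = intercept + slope \cdot height + offset \cdot
#' [female] + \epsilon} with a right-skewed (shifted-lognormal,
#' median-zero) or Gaussian residual, and the intercept and residual
#' scale are calibrated once so the population median and IQR match the
#' requested targets (defaults: median 885 g, IQR 771--973 g, n = 74).
#' All generative parameters are recorded in
#' \code{attr(value, "generator")}.
#'
#' @param n Number of subjects (default 74; at least 20).
#' @param targetMedian,targetIqr Population targets for lung mass, g.
#' @param heightSlope Generative height coefficient, g/cm (default 7.2).
#' @param sexOffset Generative female offset, g (default -88.6; male is
#'   the reference level).
#' @param epsSd Residual SD in g; by default calibrated from the targets
#'   (an error if the targets are infeasible given the predictor spread).
#' @param family Residual family: \code{"lognormal"} (right-skewed,
#'   default) or \code{"gaussian"}.
#' @param seed RNG seed.
#' @return A cohort \code{data.frame} in the dialect [readCohort()]
#'   understands.
#' @export
makeReferenceCohort <- function(n = 74, targetMedian = 885,
                                targetIqr = c(771, 973),
                                heightSlope = 7.2, sexOffset = -88.6,
                                epsSd = NULL,
                                family = c("lognormal", "gaussian"),
                                seed = 1) {
  family <- match.arg(family)
  if (n < 20) stop("need n >= 20")
  hMale <- c(mean = 178, sd = 7)
  hFemale <- c(mean = 166, sd = 7)
  pFemale <- 0.5
  hVar <- pFemale * (1 - pFemale) * (hMale["mean"] - hFemale["mean"])^2 +
    (1 - pFemale) * hMale["sd"]^2 + pFemale * hFemale["sd"]^2
  predVar <- heightSlope^2 * hVar +
    sexOffset^2 * pFemale * (1 - pFemale)
  if (is.null(epsSd)) {
    totalSd <- (targetIqr[2] - targetIqr[1]) / (2 * stats::qnorm(0.75))
    epsVar <- totalSd^2 - predVar
    if (epsVar <= 0)
      stop("infeasible calibration: target IQR narrower than the ",
           "spread implied by the height/sex regression")
    epsSd <- sqrt(epsVar)
  }
  meanHeight <- (1 - pFemale) * hMale["mean"] + pFemale * hFemale["mean"]
  intercept <- targetMedian - heightSlope * meanHeight -
    sexOffset * pFemale
  tau <- 0.4  # lognormal shape of the skewed residual

  .withSeed(seed, {
    female <- stats::rbinom(n, 1, pFemale)
    height <- round(ifelse(female == 1,
                           stats::rnorm(n, hFemale["mean"], hFemale["sd"]),
                           stats::rnorm(n, hMale["mean"], hMale["sd"])), 1)
    eps <- if (epsSd == 0) {
      numeric(n)
    } else if (family == "gaussian") {
      stats::rnorm(n, 0, epsSd)
    } else {
      lnSd <- sqrt((exp(tau^2) - 1) * exp(tau^2))
      epsSd * (stats::rlnorm(n, 0, tau) - 1) / lnSd
    }
    m <- intercept + heightSlope * height + sexOffset * female + eps
    m <- pmax(m, 150)  # physical floor, essentially never active
    v <- pmax(m * 4.2 + stats::rnorm(n, 0, 300), 500)
    df <- data.frame(
      patient_id = sprintf("REF%03d", seq_len(n)),
      sex = factor(ifelse(female == 1, "female", "male"),
                   levels = c("male", "female")),
      height_cm = height,
      weight_kg = round(height - 100 + stats::rnorm(n, 0, 8), 1),
      age_yr = round(pmin(pmax(stats::rnorm(n, 40, 15), 18), 85)),
      m_lung_g = m,
      v_lung_ml = v,
      m_non_pct = pmin(stats::rlnorm(n, log(1), 0.6), 5),
      group = "reference",
      stringsAsFactors = FALSE)
    attr(df, "generator") <- list(
      n = n, targetMedian = targetMedian, targetIqr = targetIqr,
      heightSlope = heightSlope, sexOffset = sexOffset,
      intercept = unname(intercept), epsSd = unname(epsSd),
      family = family, tau = tau, pFemale = pFemale,
      heightMale = hMale, heightFemale = hFemale, seed = seed)
    df
  })
}

# truncated-lognormal draw by inverse CDF
.rlnormTrunc <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  pl <- stats::plnorm(lower, meanlog, sdlog)
  pu <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, pl, pu), meanlog, sdlog)
}

#' Generate a synthetic posttraumatic lung-injury cohort
#'
#' Emulates the structure of an early posttraumatic acute-lung-injury
#' cohort: a fixed fraction of patients has lung mass in the normal
#' (atelectasis) range, hard-truncated at the upper reference cut, and
#' the remainder lies above it, with the heaviest falling in the
#' consolidation range. Correlated covariates (smaller lung volume,
#' lower nonaerated percentage and more support-free days in the
#' atelectasis component) follow the printed subgroup summaries. True
#' component labels are stored in \code{true_subgroup} for oracle
#' comparisons, and generative parameters in
#' \code{attr(value, "generator")}.
#'
#' @param n Cohort size (default 78).
#' @param mixtureFraction Fraction at or below the upper reference cut
#'   (default 46/78).
#' @param rule [ClassificationRule-class] supplying the truncation cuts.
#' @param seed RNG seed.
#' @return A cohort \code{data.frame} with a \code{true_subgroup} column.
#' @export
makeAliCohort <- function(n = 78, mixtureFraction = 46 / 78,
                          rule = classificationRule(), seed = 1) {
  if (mixtureFraction < 0 || mixtureFraction > 1)
    stop("mixtureFraction must be in [0, 1]")
  nBelow <- round(mixtureFraction * n)
  nAbove <- n - nBelow
  cut <- rule@upperReference

  .withSeed(seed, {
    mBelow <- .rlnormTrunc(nBelow, log(899), 0.21, upper = cut)
    mAbove <- .rlnormTrunc(nAbove, log(1398), 0.33, lower = cut + 1e-9)
    m <- c(mBelow, mAbove)
    lab <- rep(c("atelectasis", "above_reference"), c(nBelow, nAbove))
    ord <- sample.int(n)
    m <- m[ord]; lab <- lab[ord]
    atel <- lab == "atelectasis"

    vRatio <- ifelse(atel, 3.15, 2.73)
    v <- m * vRatio * stats::rlnorm(n, 0, 0.12)
    mnon <- pmin(ifelse(atel,
                        stats::rlnorm(n, log(16), 0.5),
                        stats::rlnorm(n, log(36), 0.45)), 95)
    ventFree <- round(pmin(pmax(ifelse(atel,
                                       stats::rnorm(n, 18, 8),
                                       stats::rnorm(n, 12, 9)), 0), 28))
    icuFree <- round(pmin(pmax(ifelse(atel,
                                      stats::rnorm(n, 13, 9),
                                      stats::rnorm(n, 5, 7)), 0), 28))
    female <- stats::rbinom(n, 1, 0.25)
    height <- ifelse(female == 1, stats::rnorm(n, 166, 7),
                     stats::rnorm(n, 178, 7))
    df <- data.frame(
      patient_id = sprintf("ALI%03d", seq_len(n)),
      sex = factor(ifelse(female == 1, "female", "male"),
                   levels = c("male", "female")),
      height_cm = round(height, 1),
      age_yr = round(pmin(pmax(ifelse(atel, stats::rnorm(n, 44, 14),
                                      stats::rnorm(n, 31, 15)), 16), 90)),
      pao2_fio2 = round(pmin(pmax(ifelse(atel,
                                         stats::rnorm(n, 190, 70),
                                         stats::rnorm(n, 150, 80)),
                                  40), 299)),
      m_lung_g = m,
      v_lung_ml = v,
      m_non_pct = mnon,
      days_ventilated = 28 - ventFree,
      days_in_icu = 28 - icuFree,
      true_subgroup = lab,
      stringsAsFactors = FALSE)
    attr(df, "generator") <- list(
      n = n, mixtureFraction = mixtureFraction, nBelow = nBelow,
      upperReference = cut, consolidationCut = rule@consolidationCut,
      seed = seed)
    df
  })
}
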