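test_that("phantom generation is a pure function of spec and seed", {
  p1 <- makeThoraxPhantom(smallSpec(noiseSd = 15, seed = 42))
  p2 <- makeThoraxPhantom(smallSpec(noiseSd = 15, seed = 42))
  expect_identical(ctData(p1$volume), ctData(p2$volume))
  expect_identical(maskArray(p1$mask), maskArray(p2$mask))
  p3 <- makeThoraxPhantom(smallSpec(noiseSd = 15, seed = 43))
  expect_false(identical(ctData(p1$volume), ctData(p3$volume)))
  # generation does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(makeThoraxPhantom(smallSpec(seed = 9)))
  expect_identical(runif(1), before)
})

test_that("a pure normally-aerated phantom at -700 HU has closed-form mass", {
  sp <- smallSpec(
    fractions = c(hyperaerated = 0, normally_aerated = 1,
                  poorly_aerated = 0, nonaerated = 0),
    fixedHu = c(normally_aerated = -700), seed = 5)
  ph <- makeThoraxPhantom(sp)
  tr <- ph$truth
  # density at -700 HU is 0.3 g/ml: mass is 0.3 x realized volume
  expect_equal(tr@totalMassG, 0.3 * tr@totalVolumeMl, tolerance = 1e-12)
  # voxelization puts the realized volume close to the requested one
  expect_rel_equal(tr@totalVolumeMl, 2000, 0.05)
  summ <- summarizeAeration(ph$volume, ph$mask)
  expect_rel_equal(mLung(summ), tr@totalMassG, 0.001)
  expect_equal(unname(compartmentPercents(summ)["normally_aerated"]),
               100)
})

test_that("ground truth is an independent, self-consistent ledger", {
  ph <- makeThoraxPhantom(smallSpec(lesionVolumeMl = 80, seed = 13))
  tr <- ph$truth
  expect_equal(sum(tr@compartmentMassG), tr@totalMassG)
  expect_equal(sum(tr@compartmentVolumeMl), tr@totalVolumeMl)
  expect_gt(tr@lesionMassG, 0)
  # lesion voxels are labeled opacified in the mask
  expect_equal(sum(maskLabels(ph$mask) == "opacified", na.rm = TRUE),
               round(tr@lesionVolumeMl / voxelVolumeMl(ph$volume)))
})

test_that("the water bottle has water mass and per-slice geometric parity", {
  sp <- phantomSpec(dim = c(96, 96, 48), spacing = c(2.5, 2.5, 5),
                    lungVolumeMl = 2500, includeBottle = TRUE,
                    bottleRadiusMm = 25, bottleLengthMm = 120, seed = 2)
  ph <- makeThoraxPhantom(sp)
  tr <- ph$truth
  # 0 HU water: bookkeeping density 1 g/ml, mass = volume exactly
  expect_equal(tr@bottleMassG, tr@bottleVolumeMl, tolerance = 1e-12)
  # one full cross-section: voxel mass against the geometric formula
  bottle <- ph$bottleMask
  z <- which(apply(bottle, 3, any))[3]
  roi <- array(FALSE, dim = dim(bottle)); roi[, , z] <- bottle[, , z]
  model <- densityModel(rhoRef = 0.99777)
  voxelMass <- mLung(summarizeAeration(ph$volume, LungMask(roi), model))
  areaCm2 <- sum(roi) * prod(spacing(ph$volume)[1:2]) / 100
  geo <- geometricRoiMass(areaCm2, spacing(ph$volume)[3])
  expect_equal(voxelMass, geo, tolerance = 1e-12)
})

test_that("interior bottle ROIs agree; rim-touching ROIs read low", {
  sp <- phantomSpec(dim = c(96, 96, 48), spacing = c(2.5, 2.5, 5),
                    lungVolumeMl = 2500, includeBottle = TRUE,
                    bottleRadiusMm = 25, seed = 3)
  clean <- makeBottleValidationSet(10, sp, roiMode = "interior")
  baClean <- blandAltmanPercent(clean$voxel_mass_g,
                                clean$geometric_mass_g)
  expect_lt(abs(baClean@biasPercent), 1e-9)

  spRim <- phantomSpec(dim = c(96, 96, 48), spacing = c(2.5, 2.5, 5),
                       lungVolumeMl = 2500, includeBottle = TRUE,
                       bottleRadiusMm = 25, rimWidth = 1, seed = 3)
  edge <- makeBottleValidationSet(27, spRim, roiMode = "edge")
  baEdge <- blandAltmanPercent(edge$voxel_mass_g,
                               edge$geometric_mass_g)
  expect_lt(baEdge@biasPercent, 0)

  # modest HU noise keeps interior ROIs within 1% of the oracle
  spN <- phantomSpec(dim = c(96, 96, 48), spacing = c(2.5, 2.5, 5),
                     lungVolumeMl = 2500, includeBottle = TRUE,
                     bottleRadiusMm = 25, noiseSd = 10, seed = 3)
  noisy <- makeBottleValidationSet(27, spN, roiMode = "interior")
  baNoisy <- blandAltmanPercent(noisy$voxel_mass_g,
                                noisy$geometric_mass_g)
  expect_lt(abs(baNoisy@biasPercent), 1)
})

test_that("zero-mean HU noise leaves the expected phantom mass unchanged", {
  sp0 <- smallSpec(seed = 1)
  truth <- makeThoraxPhantom(sp0)$truth@totalMassG
  errs <- vapply(1:50, function(s) {
    ph <- makeThoraxPhantom(smallSpec(noiseSd = 20, seed = s))
    mLung(summarizeAeration(ph$volume, ph$mask)) -
      ph$truth@totalMassG
  }, numeric(1))
  expect_lt(abs(mean(errs)) / truth, 0.005)
})

test_that("reference cohort generator hits its calibration targets", {
  ref <- makeReferenceCohort(n = 74, seed = 21)
  expect_rel_equal(median(ref$m_lung_g), 885, 0.05)
  gen <- attr(ref, "generator")
  expect_equal(gen$heightSlope, 7.2)
  # noise-free limit: regression recovery is exact
  ref0 <- makeReferenceCohort(n = 74, epsSd = 0, seed = 22)
  # an exact linear fit makes summary.lm grumble about perfect fits
  r <- suppressWarnings(
    hierarchicalRegression(ref0, "m_lung_g", list("height_cm", "sex"),
                           retentionThreshold = 0))
  expect_equal(
    r@coefficients$estimate[r@coefficients$term == "height_cm"], 7.2,
    tolerance = 1e-8)
  expect_equal(max(r@blockStats$r_squared), 1, tolerance = 1e-10)
  # different seeds: different data, same schema
  refB <- makeReferenceCohort(n = 74, seed = 23)
  expect_false(identical(ref$m_lung_g, refB$m_lung_g))
  expect_identical(names(ref), names(refB))
  # infeasible targets are refused
  expect_error(makeReferenceCohort(n = 74, targetIqr = c(880, 890)),
               "infeasible")
})

test_that("injury cohort mixture is hard-truncated at the reference cut", {
  ali <- makeAliCohort(n = 78, mixtureFraction = 46 / 78, seed = 31)
  cl <- classifyMlung(ali$m_lung_g)
  expect_equal(sum(cl$atelectasis), 46)
  expect_identical(cl$atelectasis, ali$true_subgroup == "atelectasis")

  expect_true(all(classifyMlung(
    makeAliCohort(20, mixtureFraction = 0, seed = 1)$m_lung_g
  )$above_reference))
  expect_true(all(classifyMlung(
    makeAliCohort(20, mixtureFraction = 1, seed = 1)$m_lung_g
  )$atelectasis))
})

test_that("phantom geometry errors are caught before generation", {
  expect_error(makeThoraxPhantom(
    phantomSpec(dim = c(24, 24, 16), spacing = c(2, 2, 2),
                lungVolumeMl = 3000)), "grid edge")
  expect_error(phantomSpec(fractions = c(hyperaerated = 0.5,
                                         normally_aerated = 0.6,
                                         poorly_aerated = 0,
                                         nonaerated = 0)), "sum to 1")
  expect_error(makeThoraxPhantom(smallSpec(nOutOfRange = 1e7)),
               "exceeds")
})
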