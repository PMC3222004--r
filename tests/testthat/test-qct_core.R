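test_that("HU-to-density is the affine gas/water map", {
  expect_equal(huToDensity(0), 1.0)
  expect_equal(huToDensity(-1000), 0.0)
  expect_equal(huToDensity(-500), 0.5)
  expect_equal(huToDensity(0, densityModel(rhoRef = 0.99777)), 0.99777)
  # strictly increasing and affine on the window
  hu <- seq(-1000, 100, by = 50)
  d <- huToDensity(hu)
  expect_true(all(diff(d) > 0))
  expect_equal(diff(d), rep(d[2] - d[1], length(d) - 1))
})

test_that("out-of-window HU error unless explicitly clamped", {
  expect_error(huToDensity(101), "outside")
  expect_error(huToDensity(-1001), "outside")
  expect_equal(huToDensity(250, clamp = TRUE), huToDensity(100))
  expect_error(classifyCompartment(150), "outside")
})

test_that("compartment classification reproduces the printed HU ranges", {
  got <- classifyCompartment(c(-950, -700, -300, 0))
  expect_equal(as.character(got),
               c("hyperaerated", "normally_aerated", "poorly_aerated",
                 "nonaerated"))
  # integer boundaries of the worded ranges fall on the printed side
  bounds <- c(-1000, -901, -900, -501, -500, -101, -100, 100)
  expect_equal(as.character(classifyCompartment(bounds)),
               c("hyperaerated", "hyperaerated",
                 "normally_aerated", "normally_aerated",
                 "poorly_aerated", "poorly_aerated",
                 "nonaerated", "nonaerated"))
})

test_that("every in-window HU maps to exactly one compartment", {
  hu <- seq(-1000, 100, by = 0.25)
  lab <- classifyCompartment(hu)
  expect_false(anyNA(lab))
  expect_equal(nlevels(lab), 4)
})

test_that("uniform fields give the closed-form mass and volume", {
  # 3000 ml of -700 HU: density 0.3 g/ml -> 900 g, all normally aerated
  v <- uniformVolume(-700, dim = c(10, 10, 30), spacing = c(10, 10, 10))
  s <- summarizeAeration(v, fullMask(c(10, 10, 30)))
  expect_equal(vLung(s), 3000)
  expect_equal(mLung(s), 900)
  expect_equal(unname(compartmentPercents(s)["normally_aerated"]), 100)
})

test_that("a zero-density gas voxel adds volume but no mass", {
  arr <- array(c(-1000, 0), c(2, 1, 1))
  v <- CTVolume(arr, spacing = c(10, 10, 10))
  s <- summarizeAeration(v, fullMask(c(2, 1, 1)))
  expect_equal(vLung(s), 2)
  expect_equal(mLung(s), 1.0)
  expect_equal(unname(compartmentPercents(s)["nonaerated"]), 100)
  expect_equal(unname(compartmentMasses(s)["hyperaerated"]), 0)
})

test_that("out-of-window voxels are excluded, not clamped, by default", {
  arr <- array(c(-700, 250, -700, -1500), c(4, 1, 1))
  v <- CTVolume(arr, spacing = c(10, 10, 10))
  s <- summarizeAeration(v, fullMask(c(4, 1, 1)))
  expect_equal(s@nVoxelsUsed, 2L)
  expect_equal(s@nVoxelsExcluded, 2L)
  expect_equal(vLung(s), 2)
  sClamp <- summarizeAeration(v, fullMask(c(4, 1, 1)),
                              clampOutOfRange = TRUE)
  expect_equal(sClamp@nVoxelsUsed, 4L)
  expect_gt(mLung(sClamp), mLung(s))
  vAllOut <- CTVolume(array(500, c(2, 2, 2)), spacing = c(1, 1, 1))
  expect_error(summarizeAeration(vAllOut, fullMask(c(2, 2, 2))),
               "no analyzable lung voxels")
})

test_that("compartment masses conserve the total on random phantoms", {
  for (s in 1:25) {
    ph <- makeThoraxPhantom(smallSpec(
      fractions = local({
        set.seed(s); f <- runif(4) + 0.05
        names(f) <- c("hyperaerated", "normally_aerated",
                      "poorly_aerated", "nonaerated")
        f / sum(f)
      }),
      noiseSd = (s %% 3) * 10, rimWidth = s %% 2, seed = s))
    summ <- summarizeAeration(ph$volume, ph$mask)
    expect_rel_equal(sum(compartmentMasses(summ)), mLung(summ), 1e-9)
    expect_equal(sum(compartmentPercents(summ)), 100, tolerance = 1e-9)
    expect_equal(vLung(summ),
                 summ@nVoxelsUsed * voxelVolumeMl(ph$volume))
  }
})

test_that("raising an in-mask HU never lowers mass or changes volume", {
  set.seed(21)
  arr <- array(runif(27, -900, -200), c(3, 3, 3))
  v <- CTVolume(arr, spacing = c(5, 5, 5))
  s0 <- summarizeAeration(v, fullMask(c(3, 3, 3)))
  for (i in 1:10) {
    arr2 <- arr
    idx <- sample(27, 1)
    arr2[idx] <- min(arr2[idx] + runif(1, 0, 300), 100)
    s1 <- summarizeAeration(CTVolume(arr2, spacing = c(5, 5, 5)),
                            fullMask(c(3, 3, 3)))
    expect_gte(mLung(s1), mLung(s0) - 1e-12)
    expect_equal(vLung(s1), vLung(s0))
  }
})

test_that("summaries are additive over any partition of the mask", {
  ph <- makeThoraxPhantom(smallSpec(seed = 9))
  m <- maskArray(ph$mask)
  set.seed(9)
  split <- array(runif(length(m)) < 0.5, dim = dim(m))
  mA <- LungMask(m & split)
  mB <- LungMask(m & !split)
  sAll <- summarizeAeration(ph$volume, ph$mask)
  sA <- summarizeAeration(ph$volume, mA)
  sB <- summarizeAeration(ph$volume, mB)
  expect_equal(mLung(sA) + mLung(sB), mLung(sAll), tolerance = 1e-9)
  expect_equal(vLung(sA) + vLung(sB), vLung(sAll), tolerance = 1e-12)
  expect_equal(compartmentMasses(sA) + compartmentMasses(sB),
               compartmentMasses(sAll), tolerance = 1e-9)
  # percentages recombine mass-weighted
  recomb <- 100 * (compartmentMasses(sA) + compartmentMasses(sB)) /
    (mLung(sA) + mLung(sB))
  expect_equal(recomb, compartmentPercents(sAll), tolerance = 1e-9)
})

test_that("doubling slice thickness doubles volume and mass exactly", {
  set.seed(3)
  arr <- array(runif(60, -950, 50), c(5, 4, 3))
  s1 <- summarizeAeration(CTVolume(arr, spacing = c(1, 1, 2)),
                          fullMask(c(5, 4, 3)))
  s2 <- summarizeAeration(CTVolume(arr, spacing = c(1, 1, 4)),
                          fullMask(c(5, 4, 3)))
  expect_equal(vLung(s2), 2 * vLung(s1))
  expect_equal(mLung(s2), 2 * mLung(s1))
})

test_that("the flat summary row carries masses, percents and bookkeeping", {
  ph <- makeThoraxPhantom(smallSpec(nOutOfRange = 5, seed = 2))
  summ <- summarizeAeration(ph$volume, ph$mask)
  row <- as.data.frame(summ)
  expect_equal(nrow(row), 1)
  expect_equal(row$m_lung_g, mLung(summ))
  expect_equal(row$n_voxels_excluded, 5L)
  td <- withr::local_tempdir()
  writeAerationReport(summ, file.path(td, "report.json"))
  rj <- jsonlite::read_json(file.path(td, "report.json"),
                            simplifyVector = TRUE)
  expect_equal(rj$m_lung_g, mLung(summ))
  expect_match(rj$note, "scanner-dependent")
})
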