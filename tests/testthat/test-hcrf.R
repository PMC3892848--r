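makeIrr <- function(times, wl, fun) {
  IrradianceSeries(lapply(seq_along(times), function(i)
    Spectrum(wl, fun(i), kind = "irradiance", timestamp = times[i])))
}

test_that("cDiff is the irradiance ratio and matches the closed-form drift", {
  wl <- testGrid
  t0 <- parseTimestamp("2012-07-09T13:48:00-08:00")
  times <- t0 + (0:62) * 24
  constIrr <- makeIrr(times, wl, function(i) rep(1.5, length(wl)))
  expect_equal(cDiff(constIrr, t0, times[30]), rep(1, length(wl)))

  doubled <- makeIrr(times, wl, function(i)
    if (i == 40) rep(3, length(wl)) else rep(1.5, length(wl)))
  expect_equal(cDiff(doubled, t0, times[40]), rep(2, length(wl)))

  # E(t) = E0 * (1 + 0.004 t[min]): weight has a closed form
  drift <- makeIrr(times, wl, function(i)
    rep(1.5, length(wl)) * (1 + 0.004 * (i - 1) * 24 / 60))
  tx <- times[50]
  expected <- 1 + 0.004 * as.numeric(difftime(tx, t0, units = "mins"))
  expect_equal(cDiff(drift, t0, tx), rep(expected, length(wl)),
               tolerance = 1e-12)

  expect_error(cDiff(constIrr, t0 - 3600, times[3]), "range")
  zeroIrr <- makeIrr(times, wl, function(i) rep(0, length(wl)))
  expect_error(cDiff(zeroIrr, t0, times[3]), "non-positive")
})

test_that("hcrf is the element-wise ratio with drift and panel factors", {
  wl <- testGrid
  Lref <- Spectrum(wl, runif(length(wl), 0.3, 0.5), kind = "panel_radiance")
  cdiff <- runif(length(wl), 0.9, 1.1)
  cref <- runif(length(wl), 0.95, 1.02)
  Lr <- Spectrum(wl, values(Lref) * cdiff * cref, kind = "target_radiance")
  expect_equal(hcrf(Lr, Lref, cdiff, cref), rep(1, length(wl)))

  half <- Spectrum(wl, 0.5 * values(Lref), kind = "target_radiance")
  expect_equal(hcrf(half, Lref), rep(0.5, length(wl)))

  # scale invariance under joint rescaling of Lr and Lref
  a <- 17.3
  LrA <- Spectrum(wl, a * values(Lr), kind = "target_radiance")
  LrefA <- Spectrum(wl, a * values(Lref), kind = "panel_radiance")
  expect_equal(hcrf(LrA, LrefA, cdiff, cref), hcrf(Lr, Lref, cdiff, cref))

  # values above 1 are not clipped
  bright <- Spectrum(wl, 2 * values(Lref), kind = "target_radiance")
  expect_equal(hcrf(bright, Lref), rep(2, length(wl)))

  expect_error(hcrf(Lr, Lref, cdiff, rep(0, length(wl))), "domain")
  LrefShort <- Spectrum(wl[-1], values(Lref)[-1], kind = "panel_radiance")
  expect_error(hcrf(Lr, LrefShort), "alignment")
})

test_that("brfPanel matches Eq.-2 algebra and equals hcrf with cdiff=1", {
  wl <- testGrid
  Lref <- Spectrum(wl, rep(0.4, length(wl)), kind = "panel_radiance")
  expect_equal(brfPanel(Lref, Lref, 1), rep(1, length(wl)))
  expect_equal(brfPanel(Lref, Lref, 0.99), rep(1 / 0.99, length(wl)))
  Lr <- Spectrum(wl, runif(length(wl), 0.1, 0.6), kind = "target_radiance")
  rref <- runif(length(wl), 0.95, 1.0)
  expect_identical(brfPanel(Lr, Lref, rref), hcrf(Lr, Lref, 1, rref))
})

test_that("cRef interpolates the panel anisotropy grid over sun zenith", {
  wl <- testGrid
  pc <- syntheticPanelCalibration(wl)
  expect_equal(cRef(PanelCalibration(wl, 0.99), 47), rep(0.99, length(wl)))
  c40 <- cRef(pc, 40); c50 <- cRef(pc, 50)
  expect_equal(cRef(pc, 45), (c40 + c50) / 2)  # linear between grid rows
  expect_true(all(c50 < c40))                  # falloff with sun zenith
})

test_that("anif is nadir-normalized and detects the backscatter pattern", {
  fx <- quickSession(lambertian = FALSE, driftSlope = 0)
  hem <- processSession(fx$session, panel = fx$acq@panel)
  pos <- positions(hem)
  an <- anifValues(hem)
  nadir <- which(pos$zenith == 0)
  expect_equal(unname(an[nadir, ]), rep(1, length(wavelengths(hem))))
  # backward PP directions brighter than nadir, forward darker (visible)
  visIdx <- which(wavelengths(hem) < 680 & wavelengths(hem) > 420)
  back30 <- which(pos$zenith == 30 & pos$azimuth == 0)
  fwd30 <- which(pos$zenith == 30 & pos$azimuth == 180)
  expect_true(all(an[back30, visIdx] > 1))
  expect_true(all(an[fwd30, visIdx] < 1))
  expect_error(anif(hcrfValues(hem)[-nadir, ], nadirIndex = integer()),
               "structural")
})

test_that("a Lambertian scene gives ANIF 1 and ANIX 1 within noise", {
  fx <- quickSession(lambertian = TRUE, driftSlope = 0.002, noiseSd = 0.002,
                     jitterSd = 0.03, ppSd = 1.75, seed = 5)
  hem <- processSession(fx$session, panel = fx$acq@panel)
  expect_equal(max(abs(anifValues(hem) - 1)), 0, tolerance = 0.02)
  ax <- anix(hem, c(0, 180))
  expect_true(all(ax$anix >= 1))
  expect_lt(max(ax$anix), 1.03)
})

test_that("anix is max/min per wavelength on the requested plane", {
  fx <- quickSession(lambertian = FALSE, driftSlope = 0)
  hem <- processSession(fx$session, panel = fx$acq@panel)
  # direct oracle on the principal plane at one wavelength
  pos <- positions(hem)
  inPP <- pos$zenith == 0 | pos$azimuth %in% c(0, 180)
  k <- 10
  oracle <- max(hcrfValues(hem)[inPP, k]) / min(hcrfValues(hem)[inPP, k])
  ax <- anix(hem, c(0, 180))
  expect_equal(unname(ax$anix[k]), oracle)
  expect_true(all(ax$anix >= 1))
  # PP anisotropy dominates the orthogonal plane on the backscatter scene
  axO <- anix(hem, c(90, 270))
  expect_true(ax$visMean > axO$visMean)
  expect_true(ax$nirMean > axO$nirMean)
  expect_true(all(ax$anix >= axO$anix - 1e-9))
  expect_error(anix(hem, c(37, 217), tolerance = 0.01), "structural")
})

test_that("anix of a constant hemisphere is exactly 1 and the {.2,.25,.3} case gives 1.5", {
  fx <- quickSession(lambertian = TRUE, driftSlope = 0)
  hem <- processSession(fx$session, panel = fx$acq@panel)
  ax <- anix(hem, c(0, 180))
  expect_equal(unname(ax$anix), rep(1, length(ax$anix)))
  expect_equal(max(c(0.2, 0.25, 0.3)) / min(c(0.2, 0.25, 0.3)), 1.5)
})

test_that("drift indicator localizes a step change and scores the session", {
  wl <- testGrid
  # constant irradiance, identical panels -> all zero
  fx0 <- quickSession(lambertian = TRUE, driftSlope = 0)
  hem0 <- processSession(fx0$session, panel = fx0$acq@panel)
  expect_equal(unname(driftIndicators(hem0)),
               rep(0, nrow(positions(hem0))))
  expect_equal(sessionScore(hem0), 0)

  # step change during the 10-degree ring (positions 14..29): those and all
  # later positions need interpolation; the largest indicators appear after
  # the step, none before (outside the smoothing window of the drift fit)
  fx <- quickSession(lambertian = TRUE, driftSlope = 0,
                     stepTime = 8, stepFactor = 1.08)
  hem <- processSession(fx$session, panel = fx$acq@panel)
  ind <- unname(driftIndicators(hem))
  pos <- positions(hem)
  stepAt <- as.numeric(parseTimestamp(caseStart)) + 8 * 60
  margin <- 4 * 24  # half the 7-sample fit window at the 24 s cadence
  before <- as.numeric(pos$timestamp) < stepAt - margin
  after <- as.numeric(pos$timestamp) > stepAt + margin
  expect_equal(max(ind[before]), 0)
  expect_true(all(ind[after] > 0.07))
  expect_true(any(grepl("caution", qualityFlags(hem)[after])))
  # the raw two-sample weight localizes the step sharply
  diNear <- processSession(fx$session, panel = fx$acq@panel,
                           driftMethod = "nearest")
  indN <- unname(driftIndicators(diNear))
  rawBefore <- as.numeric(pos$timestamp) < stepAt
  expect_equal(max(indN[rawBefore]), 0)
  expect_true(all(indN[!rawBefore] > 0.07))

  # purely multiplicative, spectrally uniform drift -> session score 0
  fx2 <- quickSession(lambertian = TRUE, driftSlope = 0.004)
  hem2 <- processSession(fx2$session, panel = fx2$acq@panel)
  expect_equal(sessionScore(hem2), 0, tolerance = 1e-10)
  expect_gt(max(driftIndicators(hem2)), 0.05)

  # missing end panel -> score NA
  ses3 <- fx2$session
  keep <- !(manifest(ses3)@acquisitions$id %in% c("PAN2", "IRR063"))
  acq3 <- manifest(ses3)@acquisitions[keep, ]
  man3 <- SessionManifest("p", caseLat, caseLon, -8, acq3)
  ses3@manifest <- man3
  hem3 <- processSession(ses3, panel = fx2$acq@panel)
  expect_true(is.na(sessionScore(hem3)))
})

test_that("angular NDVI surface behaves per construction", {
  fx <- quickSession(lambertian = FALSE, driftSlope = 0)
  hem <- processSession(fx$session, panel = fx$acq@panel)
  vi <- viAngular(hem)
  pos <- positions(hem)
  nadir <- which(pos$zenith == 0)
  expect_equal(vi$ndviNorm[nadir], 1)
  # stronger red than NIR anisotropy: NDVI up forward, down backward
  back30 <- which(pos$zenith == 30 & pos$azimuth == 0)
  fwd30 <- which(pos$zenith == 30 & pos$azimuth == 180)
  expect_gt(vi$ndvi[fwd30], vi$ndvi[nadir])
  expect_lt(vi$ndvi[back30], vi$ndvi[nadir])

  # equal red and NIR HCRF -> NDVI 0 (flat spectrum scene)
  flat <- SceneModel(wavelengths = testGrid,
                     baseReflectance = rep(0.35, length(testGrid)),
                     lambertian = TRUE)
  acq <- AcquisitionModel(wavelengths = testGrid, driftSlope = 0,
                          noiseSd = 0, pointingJitterSd = 0,
                          ppMisalignmentSd = 0)
  hemF <- processSession(simulateSession(flat, acq), panel = acq@panel)
  viF <- viAngular(hemF)
  expect_equal(viF$ndvi, rep(0, nrow(viF)))
  expect_error(viAngular(hem, redBand = 200), "band centre")
})

test_that("hemisphere tabular serialization round-trips", {
  fx <- quickSession(lambertian = FALSE, noiseSd = 0.005, seed = 9)
  hem <- processSession(fx$session, panel = fx$acq@panel)
  f <- tempfile(fileext = ".tsv")
  writeHemisphere(hem, f)
  r <- readHemisphere(f)
  expect_equal(hcrfValues(r), hcrfValues(hem), tolerance = 1e-12)
  expect_equal(unname(sunGeometry(r)["zenith"]),
               unname(sunGeometry(hem)["zenith"]), tolerance = 1e-6)
  expect_equal(qualityFlags(r), qualityFlags(hem))
})
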