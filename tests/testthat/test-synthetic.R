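test_that("a simulated session has the full acquisition complement", {
  fx <- quickSession(lambertian = TRUE)
  acq <- manifest(fx$session)@acquisitions
  expect_equal(sum(acq$kind == "target_radiance"), 61)
  expect_equal(sum(acq$kind == "panel_radiance"), 2)
  expect_equal(sum(acq$kind == "irradiance"), 63)
  expect_equal(length(sessionSpectra(fx$session)), 126)
  # panels bracket the targets; one irradiance per radiance acquisition
  expect_equal(acq$kind[1], "panel_radiance")
  rad <- acq[acq$kind != "irradiance", ]
  expect_equal(rad$kind[nrow(rad)], "panel_radiance")
  expect_equal(sum(acq$kind == "irradiance"),
               sum(acq$kind != "irradiance"))
  # ~25 minutes from start panel to end panel at the default cadence
  expect_equal(diff(range(as.numeric(acq$timestamp))) / 60, 24.8)
})

test_that("identical seeds give byte-identical sessions", {
  a <- quickSession(noiseSd = 0.005, jitterSd = 0.03, ppSd = 1.75, seed = 21)
  b <- quickSession(noiseSd = 0.005, jitterSd = 0.03, ppSd = 1.75, seed = 21)
  for (id in names(sessionSpectra(a$session)))
    expect_identical(values(sessionSpectra(a$session)[[id]]),
                     values(sessionSpectra(b$session)[[id]]))
  c <- quickSession(noiseSd = 0.005, jitterSd = 0.03, ppSd = 1.75, seed = 22)
  expect_false(identical(values(sessionSpectra(a$session)$P05),
                         values(sessionSpectra(c$session)$P05)))
  # written session directories are byte-identical too
  d1 <- tempfile(); d2 <- tempfile()
  writeSession(a$session, d1); writeSession(b$session, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(quickSession(noiseSd = 0.01, seed = 4))
  expect_identical(runif(3), before)
})

test_that("noiseless Lambertian pipeline recovers the base spectrum exactly", {
  fx <- quickSession(lambertian = TRUE, driftSlope = 0)
  hem <- processSession(fx$session, panel = fx$acq@panel)
  expect_equal(max(abs(hcrfValues(hem) -
                         groundTruth(fx$session)$brf)), 0,
               tolerance = 1e-12)
})

test_that("drift correction is exact without noise and biased without correction", {
  for (slope in c(0.0004, 0.002, 0.004)) {  # 1%, 5%, 10% over the session
    fx <- quickSession(lambertian = TRUE, driftSlope = slope)
    hem <- processSession(fx$session, panel = fx$acq@panel)
    truth <- groundTruth(fx$session)$brf
    expect_equal(max(abs(hcrfValues(hem) - truth)), 0, tolerance = 1e-10)
    # uncorrected: each position is off by exactly the drift factor
    hemU <- processSession(fx$session, panel = fx$acq@panel,
                           driftCorrection = FALSE)
    tMin <- (1:61) * 24 / 60
    expected <- truth * (1 + slope * tMin)
    expect_equal(hcrfValues(hemU), expected, tolerance = 1e-10)
  }
})

test_that("corrected HCRF beats uncorrected for all tested drift amplitudes", {
  # truth-relative RMS: sensor errors are multiplicative
  rmsErr <- function(hem, truth)
    sqrt(mean(((hcrfValues(hem) - truth) / truth)^2))
  errU <- numeric(0)
  for (slope in c(0.0004, 0.002, 0.004)) {
    fx <- quickSession(driftSlope = slope, noiseSd = 0.005, seed = 13)
    truth <- groundTruth(fx$session)$brf
    eC <- rmsErr(processSession(fx$session, panel = fx$acq@panel), truth)
    eU <- rmsErr(processSession(fx$session, panel = fx$acq@panel,
                                driftCorrection = FALSE), truth)
    expect_lt(eC, eU)
    expect_lt(eC, 0.01)                 # corrected RMS below 1% of truth
    errU <- c(errU, eU)
  }
  expect_true(all(diff(errU) > 0))      # uncorrected error grows with drift
})

test_that("pointing jitter within spec is invisible on a homogeneous scene", {
  base <- quickSession(lambertian = FALSE, driftSlope = 0, seed = 31)
  jit <- quickSession(lambertian = FALSE, driftSlope = 0, jitterSd = 0.03,
                      seed = 31)
  hemB <- processSession(base$session, panel = base$acq@panel)
  hemJ <- processSession(jit$session, panel = jit$acq@panel)
  # scene properties vary only with view angle; a <=6 cm displacement shifts
  # the effective angle by <2 deg, changing HCRF by less than the 0.5% noise
  # floor of the sensor model
  relDiff <- abs(hcrfValues(hemJ) - hcrfValues(hemB)) / hcrfValues(hemB)
  expect_lt(median(relDiff), 0.005)
})

test_that("DN quantization round-trips through the calibration table", {
  wl <- testGrid
  gain <- rep(1e-4, length(wl))
  scene <- SceneModel(wavelengths = wl, lambertian = TRUE)
  acq <- AcquisitionModel(wavelengths = wl, driftSlope = 0, noiseSd = 0,
                          pointingJitterSd = 0, ppMisalignmentSd = 0,
                          dnGain = gain)
  ses <- simulateSession(scene, acq, startTime = caseStart,
                         latitude = caseLat, longitude = caseLon)
  expect_true(all(vapply(sessionSpectra(ses)[positions(defaultScheme())$id],
                         function(s) spectrumKind(s) == "dn", logical(1))))
  cal <- CalibrationTable(wl, gain)
  hem <- processSession(ses, panel = acq@panel, calibration = cal)
  # quantization error bounded by half a DN through the ratio
  expect_equal(max(abs(hcrfValues(hem) - groundTruth(ses)$brf)), 0,
               tolerance = 0.01)
  expect_error(processSession(ses, panel = acq@panel), "calibration")
})

test_that("conical average reduces to the constant and the analytic cone integral", {
  expect_equal(conicalAverage(function(z, a) 0.42, 15, 90, nRays = 50), 0.42)
  # linear-in-offset-angle f over the cone: closed-form solid-angle average
  b <- 0.3
  f <- function(z, a) 1 + b * sqrt((z - 20)^2)  # |offset| from 20-deg axis
  # average of |beta| over the spherical cap of half-angle alpha:
  alpha <- 8.5 / 2 * pi / 180
  analytic <- 1 + b * 180 / pi * (sin(alpha) - alpha * cos(alpha)) /
    (1 - cos(alpha))
  # evaluate on the principal plane through the axis so |beta| = |z - 20|
  # only holds approximately off-plane; use a rotationally symmetric f via
  # the angle to the axis instead
  axis <- c(sin(20 * pi / 180), 0, cos(20 * pi / 180))
  fSym <- function(z, a) {
    d <- c(sin(z * pi / 180) * cos(a * pi / 180),
           sin(z * pi / 180) * sin(a * pi / 180), cos(z * pi / 180))
    1 + b * 180 / pi * acos(min(1, sum(d * axis)))
  }
  mc <- conicalAverage(fSym, 20, 0, ifov = 8.5, nRays = 20000, seed = 2)
  expect_equal(mc, analytic, tolerance = 2e-3)
  # ifov -> 0 limit converges to the directional value
  expect_equal(conicalAverage(fSym, 20, 0, ifov = 1e-3, nRays = 200), 1,
               tolerance = 1e-4)
})

test_that("session directories round-trip including ground truth", {
  fx <- quickSession(noiseSd = 0.003, seed = 17)
  d <- tempfile()
  writeSession(fx$session, d)
  expect_true(file.exists(file.path(d, "truth_synthetic.tsv")))
  r <- readSession(d)
  expect_equal(length(sessionSpectra(r)), 126)
  for (id in c("P01", "P30", "PAN1", "IRR050"))
    expect_identical(values(sessionSpectra(r)[[id]]),
                     values(sessionSpectra(fx$session)[[id]]))
  expect_equal(unname(groundTruth(r)$brf), unname(groundTruth(fx$session)$brf),
               tolerance = 1e-12)
  hem1 <- processSession(r, panel = fx$acq@panel)
  hem2 <- processSession(fx$session, panel = fx$acq@panel)
  expect_equal(hcrfValues(hem1), hcrfValues(hem2), tolerance = 1e-9)
})
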