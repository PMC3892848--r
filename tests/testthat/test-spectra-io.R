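test_that("spectrum read preserves length and metadata", {
  wl <- seq(350, 1049, by = 1.5)
  s <- Spectrum(wl, runif(length(wl)), kind = "target_radiance",
                timestamp = "2012-07-09T13:48:00-08:00", id = "T001")
  expect_equal(length(wavelengths(s)), 467)
  f <- tempfile(fileext = ".txt")
  writeSpectrum(s, f)
  r <- readSpectrum(f)
  expect_equal(length(wavelengths(r)), 467)
  expect_identical(spectrumKind(r), "target_radiance")
  expect_identical(r@id, "T001")
  expect_equal(as.numeric(acquisitionTime(r)), as.numeric(acquisitionTime(s)))
  expect_equal(r@utcOffset, -8)
})

test_that("read/write round-trip is exact on random spectra", {
  set.seed(42)
  for (k in 1:5) {
    n <- sample(10:500, 1)
    wl <- sort(runif(n, 350, 1050))
    wl <- wl[c(TRUE, diff(wl) > 0)]
    s <- Spectrum(wl, runif(length(wl), 0, 1e-6), kind = "irradiance",
                  timestamp = "2012-07-09T10:00:00+00:00")
    f <- tempfile(fileext = ".txt")
    writeSpectrum(s, f)
    r <- readSpectrum(f)
    expect_identical(values(r), values(s))
    expect_identical(wavelengths(r), wavelengths(s))
  }
})

test_that("malformed files give named parse errors", {
  f <- tempfile()
  writeLines(c("# kind: dn", "# timestamp: 2012-07-09T10:00:00Z",
               "350 1", "351 oops", "352 3"), f)
  expect_error(readSpectrum(f), "line 4")
  writeLines(c("# kind: dn", "# timestamp: 2012-07-09T10:00:00Z",
               "350 1", "349 2"), f)
  expect_error(readSpectrum(f), "not strictly increasing")
  writeLines(c("# kind: dn", "350 1", "351 2"), f)
  expect_error(readSpectrum(f), "timestamp")
  # plain fallback dialect needs no header
  writeLines(c("350 1", "351 2"), f)
  expect_equal(values(readSpectrum(f, dialect = "plain")), c(1, 2))
})

test_that("dnToRadiance applies gain*DN+offset and is linear", {
  wl <- seq(400, 900, by = 10)
  cal <- CalibrationTable(wl, gain = 2.0e-10)
  zero <- Spectrum(wl, rep(0, length(wl)), kind = "dn")
  expect_true(all(values(dnToRadiance(zero, cal)) == 0))
  s100 <- Spectrum(wl, rep(100, length(wl)), kind = "dn")
  expect_equal(values(dnToRadiance(s100, cal)), rep(2.0e-8, length(wl)))

  # brute-force per-wavelength oracle on a random table
  set.seed(7)
  gain <- runif(length(wl), 1e-10, 5e-10)
  offs <- runif(length(wl), 0, 1e-9)
  cal2 <- CalibrationTable(wl, gain, offs)
  dn <- Spectrum(wl, sample(0:4095, length(wl), replace = TRUE), kind = "dn")
  oracle <- vapply(seq_along(wl), function(i)
    gain[i] * values(dn)[i] + offs[i], numeric(1))
  expect_equal(values(dnToRadiance(dn, cal2)), oracle)

  # linearity when offset = 0
  a <- 3.7
  dnA <- Spectrum(wl, a * values(dn), kind = "dn")
  expect_equal(values(dnToRadiance(dnA, CalibrationTable(wl, gain))),
               a * values(dnToRadiance(dn, CalibrationTable(wl, gain))))
})

test_that("dnToRadiance interpolates the calibration grid and checks coverage", {
  wl <- seq(400, 500, by = 1.5)
  calCoarse <- CalibrationTable(seq(390, 510, by = 10),
                                gain = seq(1e-10, 2e-10, length.out = 13))
  s <- Spectrum(wl, rep(1000, length(wl)), kind = "dn")
  out <- dnToRadiance(s, calCoarse)
  expect_equal(values(out),
               1000 * approx(calCoarse@wavelengths, calCoarse@gain, wl)$y)
  calNarrow <- CalibrationTable(seq(420, 480, by = 10), gain = 1e-10)
  expect_error(dnToRadiance(s, calNarrow), "coverage")
})

test_that("manifest YAML round-trips", {
  fx <- quickSession(lambertian = TRUE)
  man <- manifest(fx$session)
  f <- tempfile(fileext = ".yml")
  writeManifest(man, f)
  r <- readManifest(f)
  expect_equal(r@latitude, man@latitude)
  expect_equal(nrow(r@acquisitions), nrow(man@acquisitions))
  expect_equal(as.numeric(r@acquisitions$timestamp),
               as.numeric(man@acquisitions$timestamp))
  expect_equal(r@acquisitions$zenith, man@acquisitions$zenith)
})

test_that("manifest validity enforces panel-first and geometry rules", {
  fx <- quickSession(lambertian = TRUE)
  man <- manifest(fx$session)
  bad <- man@acquisitions
  bad$zenith[bad$kind == "panel_radiance"][1] <- 10
  expect_error(SessionManifest("p", 0, 0, 0, bad), "nadir")
  bad2 <- man@acquisitions[bad$kind != "panel_radiance", ]
  expect_error(SessionManifest("p", 0, 0, 0, bad2), "panel")
})

test_that("quality screen flags scaled outliers and noisy spectra", {
  # instrument wavelength grid: the default noise threshold is calibrated
  # for clean spectra at 1.5 nm sampling
  fx <- quickSession(lambertian = TRUE, driftSlope = 0,
                     wl = seq(350, 1049, by = 1.5))
  man <- manifest(fx$session)
  spectra <- sessionSpectra(fx$session)
  flags <- qualityScreen(man, spectra)
  tgt <- man@acquisitions$id[man@acquisitions$kind == "target_radiance"]
  nadirId <- man@acquisitions$id[man@acquisitions$kind == "target_radiance" &
                                   man@acquisitions$zenith == 0]
  expect_true(all(flags[setdiff(tgt, nadirId)] == "ok"))
  expect_equal(unname(flags[nadirId]), "untestable")  # singleton ring

  # one spectrum scaled x5 in a 16-member ring -> outlier (direct MAD oracle)
  ring30 <- man@acquisitions[man@acquisitions$kind == "target_radiance" &
                               man@acquisitions$zenith == 30, ]
  victim <- ring30$spectrumRef[4]
  sp2 <- spectra
  sp2[[victim]]@values <- 5 * sp2[[victim]]@values
  lv <- vapply(ring30$spectrumRef, function(r) mean(values(sp2[[r]])),
               numeric(1))
  expect_true(abs(lv[4] - median(lv)) > 5 * mad(lv))  # oracle agrees
  flags2 <- qualityScreen(man, sp2)
  expect_equal(unname(flags2[ring30$id[4]]), "outlier")
  expect_true(all(flags2[setdiff(ring30$id, ring30$id[4])] == "ok"))

  # alternating +-10% per-sample noise -> noisy
  sp3 <- spectra
  n <- length(values(sp3[[victim]]))
  sp3[[victim]]@values <- values(sp3[[victim]]) *
    (1 + 0.1 * rep_len(c(1, -1), n))
  flags3 <- qualityScreen(man, sp3)
  expect_equal(unname(flags3[ring30$id[4]]), "noisy")
})

test_that("quality screen is permutation-invariant within a ring", {
  fx <- quickSession(lambertian = FALSE, noiseSd = 0.005, seed = 3,
                     wl = seq(350, 1049, by = 1.5))
  man <- manifest(fx$session)
  spectra <- sessionSpectra(fx$session)
  flags <- qualityScreen(man, spectra)
  acq <- man@acquisitions
  # permute the 20-degree ring's acquisition rows
  ringRows <- which(acq$kind == "target_radiance" & acq$zenith == 20)
  perm <- sample(ringRows)
  acq2 <- acq
  acq2[ringRows, ] <- acq[perm, ]
  man2 <- SessionManifest(man@plotId, man@latitude, man@longitude,
                          man@utcOffset, acq2)
  flags2 <- qualityScreen(man2, spectra)
  expect_equal(flags2[names(flags)], flags)
})
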