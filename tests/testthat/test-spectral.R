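test_that("reflectance calibration is the panel-normalised ratio", {
  wl <- seq(380, 1100, length.out = 256)
  panel <- raw_scan(wl, rep(1000, 256), role = "panel")
  canopy <- raw_scan(wl, rep(500, 256), role = "canopy")
  spec <- calibrate_reflectance(canopy, panel, panel_reflectance = 0.99)
  expect_equal(unique(spec$reflectance), 0.495)

  self <- calibrate_reflectance(panel, panel, panel_reflectance = 0.99)
  expect_equal(unique(self$reflectance), 0.99)

  # mask is false outside the 450-820 nm usable range
  expect_false(any(spec$snr_mask[wl > 820 | wl < 450]))
  expect_true(all(spec$snr_mask[wl >= 450 & wl <= 820]))

  # calibrating an already-calibrated spectrum against a unit panel is identity
  unit <- raw_scan(wl, rep(1, 256), role = "panel")
  once <- raw_scan(wl, spec$reflectance, role = "canopy")
  twice <- calibrate_reflectance(once, unit, panel_reflectance = 1)
  expect_equal(twice$reflectance, spec$reflectance)

  bad <- raw_scan(wl, c(rep(1000, 100), 0, rep(1000, 155)), role = "panel")
  expect_error(calibrate_reflectance(canopy, bad),
               class = "ct_calibration_error")
  short <- raw_scan(wl[-1], rep(1000, 255), role = "panel")
  expect_error(calibrate_reflectance(canopy, short),
               class = "ct_calibration_error")
})

test_that("SNR-based masking removes low-signal wavelengths", {
  wl <- seq(380, 1100, length.out = 128)
  snr <- rep(100, 128); snr[60:70] <- 5
  panel <- raw_scan(wl, rep(1000, 128), role = "panel")
  canopy <- raw_scan(wl, rep(600, 128), role = "canopy")
  spec <- calibrate_reflectance(canopy, panel, snr = snr)
  expect_false(any(spec$snr_mask[60:70]))

  scans <- lapply(c(998, 1000, 1002), function(dn) {
    raw_scan(wl, rep(dn, 128))
  })
  est <- estimate_snr(scans)
  expect_equal(unique(round(est)), 500)  # mean 1000 / sd 2
})

test_that("Gaussian band sampling is exact on constant and linear spectra", {
  flat <- flat_spectrum(0.3)
  for (ctr in c(550, 670, 800)) {
    expect_equal(sample_band(flat, ctr, fwhm = 3), 0.3, tolerance = 1e-12)
  }
  lin <- flat_spectrum()
  a <- 0.05; b <- 4e-4
  lin$reflectance <- a + b * lin$wavelengths
  expect_equal(sample_band(lin, 670, fwhm = 3), a + b * 670,
               tolerance = 1e-6)
  expect_error(sample_band(flat, 900, fwhm = 3), class = "ct_domain_error")
})

test_that("indices match direct arithmetic on prescribed band values", {
  s <- spectrum_with_bands(c("550" = 0.10, "670" = 0.05, "681" = 0.10,
                             "709" = 0.20, "754" = 0.40, "800" = 0.50))
  expect_equal(ndvi(s), (0.5 - 0.05) / (0.5 + 0.05), tolerance = 1e-3)
  expect_equal(mtci(s), (0.40 - 0.20) / (0.20 - 0.10), tolerance = 0.02)
  # independent hand computation of the MCARI2 closed form
  r800 <- sample_band(s, 800); r670 <- sample_band(s, 670)
  r550 <- sample_band(s, 550)
  num <- 1.5 * (2.5 * (r800 - r670) - 1.3 * (r800 - r550))
  den <- sqrt((2 * r800 + 1)^2 - (6 * r800 - 5 * sqrt(r670))) - 0.5
  expect_equal(mcari2(s), num / den, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(mcari2(s), mcari2(s, literal = TRUE))))

  flat <- flat_spectrum(0.3)
  expect_equal(ndvi(flat), 0)
  expect_error(mtci(flat), class = "ct_domain_error")  # R709 == R681
})

test_that("NDVI and MTCI are scale-invariant, MCARI2 is not", {
  for (seed in 1:5) {
    sp <- gen_spectrum(runif(1, 0.2, 0.9), seed = seed, noise_sd = 0.02)
    s <- calibrate_reflectance(sp$canopy, sp$panel)
    s2 <- s
    k <- 1.7
    s2$reflectance <- k * s$reflectance
    expect_equal(ndvi(s2), ndvi(s), tolerance = 1e-9)
    expect_equal(mtci(s2), mtci(s), tolerance = 1e-9)
    expect_gt(abs(mcari2(s2) - mcari2(s)), 1e-3)
  }
})

test_that("repeat-scan averaging rejects MAD outliers", {
  wl <- seq(380, 1100, length.out = 64)
  good <- lapply(c(1000, 1004, 996, 1002), function(dn) raw_scan(wl, rep(dn, 64)))
  bad <- raw_scan(wl, rep(5000, 64))
  avg <- average_scans(c(good, list(bad)))
  expect_equal(unique(avg$counts), mean(c(1000, 1004, 996, 1002)))
})

test_that("plot-level default averages spectra before computing indices", {
  sp1 <- gen_spectrum(0.8, seed = 1)
  sp2 <- gen_spectrum(0.4, seed = 2)
  avg <- plot_reflectance(list(sp1$canopy, sp2$canopy), sp1$panel)
  s1 <- calibrate_reflectance(sp1$canopy, sp1$panel)
  s2 <- calibrate_reflectance(sp2$canopy, sp2$panel)
  expect_equal(avg$reflectance, (s1$reflectance + s2$reflectance) / 2)
  # index-of-average differs from average-of-indices (normalised ratios)
  per <- plot_reflectance(list(sp1$canopy, sp2$canopy), sp1$panel,
                          per_scan = TRUE)
  expect_false(isTRUE(all.equal(ndvi(avg), per$ndvi)))
})

test_that("spectra CSV reader skips metadata headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# instrument: vis-nir 256px", "wavelength_nm,value",
               "500,120", "600,150", "700,180"), path)
  scan <- read_scan(path)
  expect_equal(scan$wavelengths, c(500, 600, 700))
  expect_equal(scan$counts, c(120, 150, 180))
})
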