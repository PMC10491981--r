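test_that("buildSensingMatrix samples state transmissions at band centers", {
  axis <- SpectralAxis(450, 700, 250)
  phi <- buildSensingMatrix(defaultModulator(), generateStates(47), axis)
  expect_equal(dim(as.matrix(phi)), c(47L, 250L))
  expect_true(all(as.matrix(phi) >= 0 & as.matrix(phi) <= 0.5))
  # row i equals the state's transmission curve
  st <- generateStates(47)[[5]]
  expect_equal(as.matrix(phi)[5, ],
               stackTransmission(wavelengths(axis), defaultModulator(), st))
})

test_that("degenerate and duplicated states are caught", {
  # single-band axis tuned so the transmission is exactly zero: all-zero row
  axis1 <- SpectralAxis(499, 501, 1)
  stack <- ModulatorStack(list(flat_cell(25), flat_cell(25)))
  expect_error(buildSensingMatrix(stack, list(ModulationState(0.5)), axis1),
               "all-zero")
  # duplicated retardation scales flag rank deficiency via a message
  axis <- SpectralAxis(450, 700, 50)
  expect_message(
    buildSensingMatrix(defaultModulator(),
                       list(ModulationState(0.7, 0), ModulationState(0.7, 0.5)),
                       axis),
    "rank deficient")
})

test_that("calibration CSV round trip is bit exact and validated", {
  phi <- defaultSensingMatrix(SpectralAxis(450, 700, 40), m = 9)
  path <- tempfile(fileext = ".csv")
  writeTransmissionMap(phi, path)
  phi2 <- loadTransmissionMap(path)
  expect_identical(as.matrix(phi2), as.matrix(phi))
  expect_identical(stateTimes(phi2), stateTimes(phi))
  expect_equal(wavelengths(phi2), wavelengths(phi))

  # out-of-range entry is rejected naming the offending cell
  lines <- readLines(path)
  fields <- strsplit(lines[3], ",")[[1]]
  fields[4] <- "1.2"
  lines[3] <- paste(fields, collapse = ",")
  bad <- tempfile(fileext = ".csv")
  writeLines(lines, bad)
  expect_error(loadTransmissionMap(bad), "state row 2.*value 1.2")

  # non-uniform wavelength grid is rejected
  hdr <- strsplit(lines[1], ",")[[1]]
  hdr[3] <- "999"
  writeLines(c(paste(hdr, collapse = ","), lines[-1]), bad)
  expect_error(loadTransmissionMap(bad), "uniform|increasing")
})

test_that("simulateMeasurement computes g = Phi f (+ scaled noise)", {
  axis3 <- SpectralAxis(500, 560, 3)
  phi <- raw_sensing_matrix(rbind(c(1, 0, 1), c(0, 1, 0)), axis3)
  f <- Spectrum(c(2, 3, 4), axis3)
  expect_equal(intensities(simulateMeasurement(f, phi)), c(6, 3))

  # zero spectrum stays zero, identity sensing returns the spectrum
  expect_equal(intensities(simulateMeasurement(Spectrum(c(0, 0, 0), axis3), phi)),
               c(0, 0))
  eye <- raw_sensing_matrix(diag(3), axis3)
  expect_equal(intensities(simulateMeasurement(f, eye)), c(2, 3, 4))

  # noiseless linearity
  h <- Spectrum(c(1, 0, 5), axis3)
  lhs <- intensities(simulateMeasurement(Spectrum(2 * f@values + 3 * h@values,
                                                  axis3), phi))
  rhs <- 2 * intensities(simulateMeasurement(f, phi)) +
    3 * intensities(simulateMeasurement(h, phi))
  expect_equal(lhs, rhs)

  # noise is seeded, reproducible and scaled to the signal peak
  g1 <- simulateMeasurement(f, phi, noise_sigma = 0.1, seed = 42)
  g2 <- simulateMeasurement(f, phi, noise_sigma = 0.1, seed = 42)
  expect_identical(intensities(g1), intensities(g2))
  expect_equal(g1@noise_meta$sigma, 0.1 * 6)
  expect_error(simulateMeasurement(Spectrum(rep(1, 4), SpectralAxis(0, 4, 4)),
                                   phi), "axis mismatch")
})

test_that("acquireCube matches per-pixel simulateMeasurement", {
  axis <- SpectralAxis(450, 700, 250)
  phi <- defaultSensingMatrix(axis)
  set.seed(3)
  cube <- HyperspectralCube(array(runif(4 * 4 * 250), dim = c(4, 4, 250)),
                            axis)
  stack <- acquireCube(cube, phi)
  expect_equal(dim(stack@frames), c(4L, 4L, 47L))

  # constant-spectrum cube gives spatially constant frames
  const <- HyperspectralCube(
    array(rep(filterSpectrum(FilterSpec(550, 30), axis)@values,
              each = 4), dim = c(2, 2, 250)), axis)
  cstack <- acquireCube(const, phi)
  for (i in 1:3)
    expect_equal(max(cstack@frames[, , i]) - min(cstack@frames[, , i]), 0)

  # single-pixel cube reproduces simulateMeasurement exactly (same seed)
  f <- Spectrum(cube@data[1, 1, ], axis)
  one <- HyperspectralCube(array(f@values, dim = c(1, 1, 250)), axis)
  s1 <- acquireCube(one, phi, noise_sigma = 0.05, seed = 11)
  g1 <- simulateMeasurement(f, phi, noise_sigma = 0.05, seed = 11)
  expect_equal(as.numeric(s1@frames[1, 1, ]), intensities(g1))

  expect_error(acquireCube(const, defaultSensingMatrix(SpectralAxis(500, 700, 200))),
               "axis mismatch")
})

test_that("throughput captures the multiplex advantage", {
  # ideal single-band filter row: 1/250 = 0.4%
  axis <- SpectralAxis(450, 700, 250)
  row <- matrix(0, 1, 250)
  row[1, 100] <- 1
  ideal <- raw_sensing_matrix(row, axis)
  expect_equal(throughput(ideal)$mean, 1 / 250)

  # constant 0.25 row
  expect_equal(throughput(raw_sensing_matrix(matrix(0.25, 1, 250), axis))$mean,
               0.25)

  # simulated default modulator: mean in [0.20, 0.30], two orders of
  # magnitude above the ideal filter, compressive ratio >= 5
  phi <- defaultSensingMatrix(axis)
  tp <- throughput(phi)
  expect_gte(tp$mean, 0.20)
  expect_lte(tp$mean, 0.30)
  expect_gte(tp$mean / (1 / 250), 50)
  expect_gte(nBands(phi) / nStates(phi), 5)
  expect_length(tp$per_state, 47)
})
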