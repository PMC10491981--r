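test_that("psnr is scale free and matches the closed form", {
  ax <- SpectralAxis(500, 700, 100)
  ref <- filterSpectrum(FilterSpec(600, 20), ax)

  expect_equal(psnr(ref, ref), 300)                          # capped maximum
  expect_equal(psnr(ref, Spectrum(2 * ref@values, ax)), 300) # scale invariance

  # uniform error of 0.01 everywhere except at the (shared) peak band:
  # closed-form MSE oracle
  est_vals <- ref@values - 0.01
  est_vals[which.max(ref@values)] <- 1
  est <- new("Spectrum", values = est_vals, axis = ax)
  mse <- mean((ref@values / max(ref@values) - est_vals)^2)
  expect_equal(psnr(ref, est), 10 * log10(1 / mse), tolerance = 1e-12)
  expect_equal(psnr(ref, est), 40, tolerance = 0.1)

  expect_error(psnr(Spectrum(rep(0, 100), ax), ref), "zero")
})

test_that("psnr decreases as estimate noise grows", {
  ax <- SpectralAxis(500, 700, 100)
  ref <- filterSpectrum(FilterSpec(600, 30), ax)
  mean_psnr <- function(sig) {
    mean(vapply(1:20, function(s) {
      set.seed(s)
      est <- new("Spectrum", values = ref@values + rnorm(100, 0, sig),
                 axis = ax)
      psnr(ref, est)
    }, numeric(1)))
  }
  levels <- vapply(c(0.002, 0.01, 0.05, 0.2), mean_psnr, numeric(1))
  expect_true(all(diff(levels) < 0))
})

test_that("edge MTF matches the analytic oracles", {
  # ideal noiseless step: delta LSF, MTF identically 1
  step <- edgeTarget(64, 64, blur_sigma = 0)
  m0 <- mtfFromEdge(step)
  expect_true(all(abs(m0@values - 1) < 1e-6))
  expect_equal(m0@values[1], 1)
  expect_lte(max(m0@frequencies), 0.5)

  # Gaussian blur sigma = 1.5 px: MTF = exp(-2 pi^2 sigma^2 u^2)
  img <- edgeTarget(64, 64, blur_sigma = 1.5)
  m <- mtfFromEdge(img)
  sel <- m@frequencies <= 0.3
  analytic <- exp(-2 * pi^2 * 1.5^2 * m@frequencies[sel]^2)
  expect_lt(max(abs(m@values[sel] - analytic)), 0.02)

  # two disjoint ROIs on one edge agree
  ma <- mtfFromEdge(img, roi = c(1, 32, 1, 64))
  mb <- mtfFromEdge(img, roi = c(33, 64, 1, 64))
  expect_lt(compareMtf(ma, mb), 0.01)

  # horizontal orientation equals the transposed analysis
  mh <- mtfFromEdge(t(img), edge_orientation = "horizontal")
  expect_equal(mh@values, m@values, tolerance = 1e-12)

  # featureless noise: no detectable edge
  set.seed(1)
  flat <- matrix(rnorm(64 * 64, 0.5, 0.01), 64, 64)
  expect_error(mtfFromEdge(flat), "edge")
})

test_that("MTF estimate converges with averaging length under noise", {
  analytic_err <- function(rows, seed) {
    img <- edgeTarget(rows, 64, blur_sigma = 1.5, noise_sigma = 0.01,
                      seed = seed)
    m <- mtfFromEdge(img)
    sel <- m@frequencies <= 0.3
    max(abs(m@values[sel] - exp(-2 * pi^2 * 1.5^2 * m@frequencies[sel]^2)))
  }
  short <- mean(vapply(1:5, function(s) analytic_err(32, s), numeric(1)))
  long <- mean(vapply(1:5, function(s) analytic_err(512, s), numeric(1)))
  # quadrupling the averaging length twice should at least halve the error
  expect_lt(long, short / 2)
})

test_that("compareMtf returns the sup-norm difference", {
  f <- seq(0, 0.5, by = 0.05)
  a <- new("MTFCurve", frequencies = f, values = rep(1, length(f)))
  b <- new("MTFCurve", frequencies = f, values = c(1, rep(0.9, length(f) - 1)))
  expect_equal(compareMtf(a, a), 0)
  expect_equal(compareMtf(a, b), 0.1)

  # same blur, independently simulated native vs modulated views
  m1 <- mtfFromEdge(edgeTarget(64, 64, blur_sigma = 1.2, contrast = 1))
  m2 <- mtfFromEdge(edgeTarget(64, 64, blur_sigma = 1.2, contrast = 0.4))
  expect_lte(compareMtf(m1, m2), 0.02)
})

test_that("binToMultispectral averages contiguous equal-width groups", {
  ax <- SpectralAxis(450, 700, 250)
  ramp <- Spectrum(seq_len(250), ax)

  # identity when n_out = N, constant stays constant
  expect_equal(intensities(binToMultispectral(ramp, 250)), seq_len(250) + 0)
  expect_equal(intensities(binToMultispectral(Spectrum(rep(3, 250), ax), 8)),
               rep(3, 8))

  # hand-computed oracle on the ramp: mean of each contiguous index range
  out <- binToMultispectral(ramp, 8)
  expected <- numeric(8)
  for (b in 0:7) {
    members <- which(floor((seq_len(250) - 1) * 8 / 250) == b)
    expected[b + 1] <- sum(members) / length(members)
  }
  expect_equal(intensities(out), expected)
  expect_equal(nBands(out), 8L)

  # width-weighted integral is conserved
  widths <- as.numeric(table(floor((seq_len(250) - 1) * 8 / 250)))
  expect_equal(sum(intensities(out) * widths), sum(intensities(ramp)))

  # linearity
  set.seed(2)
  a <- Spectrum(runif(250), ax)
  b <- Spectrum(runif(250), ax)
  expect_equal(intensities(binToMultispectral(Spectrum(a@values + b@values, ax), 8)),
               intensities(binToMultispectral(a, 8)) +
                 intensities(binToMultispectral(b, 8)))

  expect_error(binToMultispectral(ramp, 300), "exceed")
})

test_that("class envelopes quantify two-class separability", {
  ax <- SpectralAxis(450, 700, 50)

  # identical class distributions: separability 0
  set.seed(7)
  X <- matrix(runif(50 * 8), 50, 8)
  same <- classEnvelopes(cbind(X, X), rep(c("normal", "cancer"), each = 8),
                         axis = ax)
  expect_equal(same$separability, 0)
  expect_equal(same$normal@mean_spectrum, same$cancer@mean_spectrum)

  # means 0 and 10 with unit-scale spread: fully disjoint envelopes
  A <- matrix(rep(c(-1, 1), each = 50), 50, 2)
  B <- 10 + A
  full <- classEnvelopes(cbind(A, B), rep(c("normal", "cancer"), each = 2),
                         axis = ax)
  expect_equal(full$separability, 1)

  # invariant under a common affine rescaling of all spectra
  aff <- classEnvelopes(cbind(A, B) * 3.7 + 2,
                        rep(c("normal", "cancer"), each = 2), axis = ax)
  expect_equal(aff$separability, full$separability)

  expect_error(classEnvelopes(A, rep("normal", 2), axis = ax), "cancer")
})

test_that("fine spectral sampling separates the tissue classes better than 8 bands", {
  ax <- SpectralAxis(450, 700, 250)
  cube <- tissueCube(tissuePhantomConfig(), ax, seed = 41)
  d <- dim(cubeData(cube))
  X <- t(matrix(cubeData(cube), nrow = d[1] * d[2]))
  labels <- as.character(cubeLabels(cube))
  full <- classEnvelopes(X, labels, axis = ax)
  X8 <- vapply(seq_len(ncol(X)), function(j)
    intensities(binToMultispectral(new("Spectrum", values = X[, j], axis = ax), 8)),
    numeric(8))
  coarse <- classEnvelopes(X8, labels, axis = SpectralAxis(450, 700, 8))
  expect_gt(full$separability, coarse$separability)
})
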