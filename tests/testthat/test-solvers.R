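test_that("OMP handles the elementary cases", {
  ax <- SpectralAxis(500, 700, 12)
  set.seed(4)
  phi <- raw_sensing_matrix(matrix(runif(8 * 12), 8, 12), ax)
  psi <- dctBasis(ax)
  A <- as.matrix(phi) %*% as.matrix(psi)

  # g equal to one effective column: support {j}, zero residual
  r <- ompSolve(A[, 7], phi, psi, SolverConfig("omp", sparsity_k = 1))
  expect_identical(r@coefficients@indices, 7L)
  expect_lt(r@objective_trace[length(r@objective_trace)], 1e-10)

  # k = 0: zero spectrum, residual equals ||g||
  g <- A[, 3] * 2
  r0 <- ompSolve(g, phi, psi, SolverConfig("omp", sparsity_k = 0))
  expect_equal(intensities(r0@spectrum), rep(0, 12))
  expect_equal(r0@objective_trace, sqrt(sum(g^2)))

  # k > M is rejected
  expect_error(ompSolve(g, phi, psi, SolverConfig("omp", sparsity_k = 9)),
               "exceed")

  # a zero column in Phi * Psi is rejected
  zphi <- raw_sensing_matrix(cbind(diag(2), matrix(0, 2, 10)), ax)
  eye <- identity_dictionary(ax)
  expect_error(ompSolve(c(1, 1), zphi, eye, SolverConfig("omp", sparsity_k = 1)),
               "zero column")
})

test_that("OMP equals exhaustive support search on guaranteed instances", {
  # noiseless 2-sparse instances with M = 6, N = P = 8 that satisfy the
  # exact recovery condition (the regime where the equality is a theorem)
  M <- 6; N <- 8; k <- 2
  ax <- SpectralAxis(500, 700, N)
  eye <- identity_dictionary(ax)
  used <- 0
  t <- 0
  while (used < 25) {
    t <- t + 1
    set.seed(t)
    A <- matrix(runif(M * N), M, N)
    S <- sort(sample(N, k))
    if (erc_value(A, S) >= 1) next
    used <- used + 1
    g <- drop(A[, S] %*% runif(k, 0.5, 2))
    phi <- raw_sensing_matrix(A, ax)
    r <- ompSolve(g, phi, eye, SolverConfig("omp", sparsity_k = k,
                                            norm_power = 1))
    expect_identical(sort(r@coefficients@indices), exhaustive_support(g, A, k))
    expect_identical(sort(r@coefficients@indices), as.integer(S))
  }
})

test_that("TwIST inverts trivial systems and shrinks fully at large lambda", {
  ax <- SpectralAxis(500, 700, 6)
  eye_phi <- raw_sensing_matrix(diag(6), ax)
  eye_psi <- identity_dictionary(ax)
  g <- c(0.9, 0.2, 0.7, 0.4, 1, 0.6)

  cfg0 <- SolverConfig("twist", reg_lambda = 0, lambda_mode = "absolute",
                       max_iterations = 5000, tolerance = 1e-14,
                       debias = FALSE)
  r <- twistSolve(g, eye_phi, eye_psi, cfg0)
  expect_equal(intensities(r@spectrum), g, tolerance = 1e-6)

  # lambda at the shrinkage threshold: zero solution
  rl <- twistSolve(g, eye_phi, eye_psi,
                   SolverConfig("twist", reg_lambda = 1, debias = FALSE))
  expect_equal(intensities(rl@spectrum), rep(0, 6))
})

test_that("TwIST matches the least-squares oracle as lambda -> 0", {
  ax <- SpectralAxis(500, 700, 8)
  set.seed(12)
  phi <- raw_sensing_matrix(matrix(runif(12 * 8), 12, 8), ax)   # M > P
  atoms <- matrix(rnorm(8 * 4), 8, 4)
  atoms <- sweep(atoms, 2, sqrt(colSums(atoms^2)), "/")
  dict <- new("DictionaryModel", atoms = atoms, axis = ax,
              training_meta = list(source = "random"))
  A <- as.matrix(phi) %*% atoms
  alpha_true <- c(1, -0.5, 2, 0.3)
  g <- drop(A %*% alpha_true) + 0.01 * rnorm(12)

  cfg <- SolverConfig("twist", reg_lambda = 1e-8, lambda_mode = "absolute",
                      max_iterations = 20000, tolerance = 1e-15,
                      norm_power = 0, debias = FALSE)
  r <- twistSolve(g, phi, dict, cfg)
  oracle <- drop(atoms %*% qr.solve(A, g))     # dense normal-equations fit
  expect_lt(sqrt(sum((intensities(r@spectrum) - oracle)^2)) /
              sqrt(sum(oracle^2)), 1e-4)

  # objective trace is non-increasing and ends at or below its start
  expect_true(all(diff(r@objective_trace) <= 1e-12))
  expect_lte(r@objective_trace[length(r@objective_trace)],
             r@objective_trace[1])
  expect_true(r@converged)
})

test_that("TwIST is scale equivariant (c g with lambda c gives c f)", {
  ax <- SpectralAxis(500, 700, 20)
  phi <- defaultSensingMatrix(ax, m = 10)
  psi <- dctBasis(ax)
  f <- filterSpectrum(FilterSpec(600, 30), ax)
  g <- drop(as.matrix(phi) %*% intensities(f))
  cfg1 <- SolverConfig("twist", reg_lambda = 1e-3, lambda_mode = "absolute",
                       debias = FALSE)
  cfgc <- SolverConfig("twist", reg_lambda = 1e-3 * 7, lambda_mode = "absolute",
                       debias = FALSE)
  r1 <- twistSolve(g, phi, psi, cfg1)
  rc <- twistSolve(7 * g, phi, psi, cfgc)
  rel <- sqrt(sum((intensities(rc@spectrum) - 7 * intensities(r1@spectrum))^2)) /
    sqrt(sum((7 * intensities(r1@spectrum))^2))
  expect_lt(rel, 1e-3)
})

test_that("noiseless k-sparse round trips succeed through an incoherent mask", {
  # binary-mask sensing (28 x 40) of spectra 2-sparse in the DCT basis
  ax <- SpectralAxis(500, 700, 40)
  set.seed(9)
  phiB <- raw_sensing_matrix(matrix(rbinom(28 * 40, 1, 0.5), 28, 40), ax)
  psi <- dctBasis(ax)
  ok <- 0
  trials <- 40
  for (t in seq_len(trials)) {
    set.seed(t)
    idx <- sample(40, 2)
    f <- synthesize(SparseCoefficients(as.integer(idx), runif(2, 0.5, 2), 40L),
                    psi)
    g <- drop(as.matrix(phiB) %*% intensities(f))
    r <- ompSolve(g, phiB, psi, SolverConfig("omp", sparsity_k = 2))
    rel <- sqrt(sum((intensities(r@spectrum) - intensities(f))^2)) /
      sqrt(sum(intensities(f)^2))
    if (rel <= 1e-3) ok <- ok + 1
  }
  expect_gte(ok / trials, 0.95)
})

test_that("reconstructCube solves pixels independently", {
  ax <- SpectralAxis(500, 700, 40)
  phi <- defaultSensingMatrix(ax, m = 20)
  corpus <- trainingCorpus(ax, n = 200, seed = 3)
  dict <- trainDictionary(corpus, axis = ax, iterations = 10, seed = 3)

  # 2 x 2 cube whose pixels are exact single atoms: OMP at the true
  # sparsity recovers every pixel at PSNR >= 40 dB
  atoms <- as.matrix(dict)
  picks <- c(5, 45, 62, 78)
  data <- array(0, dim = c(2, 2, 40))
  for (i in 1:4)
    data[(i - 1) %% 2 + 1, (i - 1) %/% 2 + 1, ] <- abs(atoms[, picks[i]])
  cube <- HyperspectralCube(data, ax)
  stack <- acquireCube(cube, phi)
  rec <- reconstructCube(stack, phi, dict, SolverConfig("omp", sparsity_k = 1))
  expect_equal(dim(cubeData(rec$cube)), c(2L, 2L, 40L))
  for (i in 1:2) for (j in 1:2) {
    truth <- new("Spectrum", values = data[i, j, ], axis = ax)
    est <- new("Spectrum", values = cubeData(rec$cube)[i, j, ], axis = ax)
    expect_gte(psnr(truth, est), 40)
  }

  # spatially constant stack gives a spatially constant reconstruction
  cstack <- acquireCube(HyperspectralCube(
    array(rep(abs(atoms[, 30]), each = 4), dim = c(2, 2, 40)), ax), phi)
  crec <- reconstructCube(cstack, phi, dict, SolverConfig("omp", sparsity_k = 2))
  for (b in c(1, 20, 40))
    expect_equal(max(cubeData(crec$cube)[, , b]) -
                   min(cubeData(crec$cube)[, , b]), 0)

  # frame/matrix mismatch is an error
  expect_error(reconstructCube(stack, defaultSensingMatrix(ax, m = 19),
                               dict), "frame count")
})

test_that("a 47-frame stack reconstructs to a 250-band cube", {
  ax <- SpectralAxis(450, 700, 250)
  phi <- defaultSensingMatrix(ax)
  psi <- dctBasis(ax)
  cube <- HyperspectralCube(
    array(filterSpectrum(FilterSpec(550, 40), ax)@values, dim = c(1, 2, 250)),
    ax)
  stack <- acquireCube(cube, phi)
  expect_equal(dim(stack@frames)[3], 47L)
  rec <- reconstructCube(stack, phi, psi, SolverConfig("omp", sparsity_k = 3))
  expect_equal(dim(cubeData(rec$cube)), c(1L, 2L, 250L))
  expect_gte(nBands(phi) / nStates(phi), 5)
})
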