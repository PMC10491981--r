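# Effective dictionary in measurement space with the solver's internal
# column weighting: selection operates on columns of A scaled by
# ||a_j||^-p; coefficients are rescaled back before synthesis so the
# physical row energies of Phi are untouched.
effective_dictionary <- function(phi, dict, norm_power) {
  if (!same_axis(phi@axis, dict@axis))
    stop_axis_mismatch("sensing matrix and dictionary differ")
  A <- phi@values %*% dict@atoms
  nrm <- sqrt(colSums(A^2))
  if (any(nrm == 0))
    stop("effective dictionary Phi * Psi has a zero column")
  w <- nrm^norm_power
  list(A = A, Aw = sweep(A, 2, w, "/"), weights = w)
}

as_sparse_coefficients <- function(x, p_total, tol = 0) {
  idx <- which(abs(x) > tol)
  SparseCoefficients(idx, x[idx], p_total)
}

build_result <- function(x, dict, trace, iters, converged) {
  co <- as_sparse_coefficients(x, ncol(dict@atoms))
  spec <- new("Spectrum", values = drop(dict@atoms %*% x), axis = dict@axis)
  new("ReconstructionResult", spectrum = spec, coefficients = co,
      objective_trace = trace, iterations_used = as.integer(iters),
      converged = converged)
}

#' Orthogonal matching pursuit recovery
#'
#' Greedy sparse recovery of `alpha` in `g = Phi Psi alpha`: at each step
#' the atom whose weighted column correlates most strongly with the
#' current residual joins the support, and the coefficients are refit by
#' least squares on the whole support. Stops after `sparsity_k` atoms or
#' when the relative residual falls below `residual_tol`.
#'
#' @param g a [MeasurementVector-class] (or numeric vector of length M).
#' @param phi a [SensingMatrix-class].
#' @param dict a [DictionaryModel-class] on the same axis.
#' @param config a [SolverConfig-class] with `solver = "omp"`.
#' @return a [ReconstructionResult-class]; the objective trace holds the
#'   residual norm after each step.
#' @examples
#' ax <- SpectralAxis(500, 700, 40)
#' phi <- defaultSensingMatrix(ax, m = 20)
#' psi <- dctBasis(ax)
#' f <- synthesize(SparseCoefficients(2L, 1.5, 40L), psi)
#' g <- drop(as.matrix(phi) %*% intensities(f))
#' r <- ompSolve(g, phi, psi, SolverConfig("omp", sparsity_k = 1))
#' @export
ompSolve <- function(g, phi, dict, config = SolverConfig("omp")) {
  if (config@solver != "omp") stop("config does not select the omp solver")
  gv <- if (is(g, "MeasurementVector")) g@values else as.numeric(g)
  if (length(gv) != nStates(phi))
    stop("measurement length does not match the sensing matrix")
  k <- config@sparsity_k
  if (k > nStates(phi))
    stop("sparsity_k may not exceed the number of measurements M")
  # greedy selection always uses fully normalised columns (classic OMP);
  # the least-squares refit operates on the raw physical columns
  ed <- effective_dictionary(phi, dict, 1)
  P <- ncol(ed$A)
  x <- numeric(P)
  g0 <- sqrt(sum(gv^2))
  resid <- gv
  trace <- g0
  supp <- integer(0)
  w <- numeric(0)
  if (k > 0 && g0 > 0) {
    for (step in seq_len(k)) {
      corr <- drop(crossprod(ed$Aw, resid))
      corr[supp] <- 0
      j <- which.max(abs(corr))
      if (abs(corr[j]) < 1e-14) break
      supp <- c(supp, j)
      w <- lstsq(ed$A[, supp, drop = FALSE], gv)
      resid <- gv - drop(ed$A[, supp, drop = FALSE] %*% w)
      trace <- c(trace, sqrt(sum(resid^2)))
      if (trace[length(trace)] <= config@residual_tol * g0) break
    }
    if (length(supp)) x[supp] <- w
  }
  build_result(x, dict, trace, length(trace) - 1, TRUE)
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' TwIST recovery (two-step iterative shrinkage/thresholding)
#'
#' Minimises `0.5 ||g - A alpha||^2 + lambda ||alpha||_1` over the
#' weighted effective dictionary `A = Phi Psi diag(||a_j||^-p)` with the
#' two-step IST recursion. The operator is rescaled by its spectral norm
#' so the shrinkage step is a contraction; the two-step parameters follow
#' the standard rule driven by an assumed smallest-to-largest eigenvalue
#' ratio of 1e-4 (severely ill-posed regime). A monotone safeguard falls
#' back to the plain IST step whenever the two-step update would increase
#' the objective, so the reported objective trace is non-increasing. When
#' `debias = TRUE` the support (coefficients above `debias_threshold`
#' relative to the largest) is refit by least squares.
#'
#' @inheritParams ompSolve
#' @param config a [SolverConfig-class] with `solver = "twist"`.
#' @return a [ReconstructionResult-class] with the per-iteration objective
#'   trace (computed before debiasing).
#' @export
twistSolve <- function(g, phi, dict, config = SolverConfig("twist")) {
  if (config@solver != "twist") stop("config does not select the twist solver")
  gv <- if (is(g, "MeasurementVector")) g@values else as.numeric(g)
  if (length(gv) != nStates(phi))
    stop("measurement length does not match the sensing matrix")
  ed <- effective_dictionary(phi, dict, config@norm_power)
  s <- svd(ed$Aw, nu = 0, nv = 0)$d[1]
  B <- ed$Aw / s
  y <- gv / s
  lam <- if (config@lambda_mode == "relative")
    config@reg_lambda * max(abs(crossprod(B, y)))
  else config@reg_lambda / s^2
  obj <- function(x) 0.5 * sum((y - B %*% x)^2) + lam * sum(abs(x))
  # two-step parameters from the assumed eigenvalue ratio
  xi1 <- 1e-4
  rho0 <- (1 - xi1) / (1 + xi1)
  alpha <- 2 / (1 + sqrt(1 - rho0^2))
  beta <- alpha * 2 / (1 + xi1)
  x1 <- soft_threshold(drop(crossprod(B, y)), lam)
  if (obj(x1) > obj(numeric(length(x1)))) x1 <- numeric(length(x1))
  x0 <- x1
  o1 <- obj(x1)
  trace <- o1
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(config@max_iterations)) {
    iters <- it
    grad <- drop(crossprod(B, y - B %*% x1))
    xg <- soft_threshold(x1 + grad, lam)
    xn <- (1 - alpha) * x0 + (alpha - beta) * x1 + beta * xg
    on <- obj(xn)
    if (on > o1) {          # monotone fallback: plain IST step
      xn <- xg
      on <- obj(xn)
    }
    if (on > o1) {          # cannot improve: keep the current iterate
      xn <- x1
      on <- o1
    }
    drel <- abs(o1 - on) / max(o1, .Machine$double.xmin)
    x0 <- x1
    x1 <- xn
    o1 <- on
    trace <- c(trace, on)
    if (drel < config@tolerance) {
      converged <- TRUE
      break
    }
  }
  x <- x1
  if (config@debias) {
    st <- which(abs(x) > config@debias_threshold * max(abs(x), 1e-300))
    if (length(st) && length(st) <= length(gv)) {
      w <- lstsq(ed$Aw[, st, drop = FALSE], gv)
      x <- numeric(length(x))
      x[st] <- w
    }
  }
  build_result(x / ed$weights, dict, trace, iters, converged)
}

#' Reconstruct a hyperspectral cube pixel by pixel
#'
#' Runs the configured solver on every pixel's measurement vector. Pixels
#' are independent, so the result does not depend on the visiting order.
#'
#' @param stack a [CompressedStack-class] of M frames.
#' @param phi the [SensingMatrix-class] used for the acquisition (frame
#'   count must equal M).
#' @param dict a [DictionaryModel-class].
#' @param config a [SolverConfig-class]; default OMP, mirroring the use of
#'   greedy recovery for tissue cubes.
#' @return a list with `cube` (a [HyperspectralCube-class] on the axis of
#'   `phi`, N bands) and `n_nonconverged` (pixel count whose solve did not
#'   converge).
#' @export
reconstructCube <- function(stack, phi, dict, config = SolverConfig("omp")) {
  d <- dim(stack@frames)
  if (d[3] != nStates(phi))
    stop("frame count does not match the sensing matrix row count")
  n <- nBands(phi)
  out <- array(0, dim = c(d[1], d[2], n))
  bad <- 0L
  solver <- if (config@solver == "twist") twistSolve else ompSolve
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      res <- solver(stack@frames[i, j, ], phi, dict, config)
      out[i, j, ] <- res@spectrum@values
      if (!res@converged) bad <- bad + 1L
    }
  }
  list(cube = new("HyperspectralCube", data = out, axis = phi@axis,
                  labels = NULL),
       n_nonconverged = bad)
}
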