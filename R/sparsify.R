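#' Orthonormal DCT-II basis as a sparsifying dictionary
#'
#' Smooth spectra compact most of their energy into the low-order cosine
#' atoms, which makes the DCT a reasonable analytic sparsifying operator
#' when no training data are available.
#'
#' @param axis a [SpectralAxis-class] with at least 2 bands.
#' @return a [DictionaryModel-class] with P = N orthonormal atoms.
#' @examples
#' psi <- dctBasis(SpectralAxis(500, 700, 8))
#' round(crossprod(as.matrix(psi)), 10)  # identity
#' @export
dctBasis <- function(axis) {
  n <- axis@n_bands
  if (n < 2) stop("axis must have at least 2 bands")
  i <- seq_len(n) - 1
  atoms <- vapply(i, function(k) {
    a <- sqrt(2 / n) * cos(pi * (2 * i + 1) * k / (2 * n))
    if (k == 0) a / sqrt(2) else a
  }, numeric(n))
  new("DictionaryModel", atoms = atoms, axis = axis,
      training_meta = list(source = "DCT-II basis"))
}

# Sparse-code a batch of signals against unit-norm atoms with a Gram-based
# orthogonal matching pursuit (one LS refit per added atom).
batch_omp_code <- function(D, X, k, tol = 1e-12) {
  P <- ncol(D)
  G <- crossprod(D)
  C0 <- crossprod(D, X)
  codes <- matrix(0, P, ncol(X))
  for (j in seq_len(ncol(X))) {
    c0 <- C0[, j]
    corr <- c0
    supp <- integer(0)
    w <- numeric(0)
    for (it in seq_len(k)) {
      i <- which.max(abs(corr))
      if (abs(corr[i]) < tol) break
      supp <- c(supp, i)
      w <- solve(G[supp, supp, drop = FALSE] +
                   diag(1e-12, length(supp)), c0[supp])
      corr <- c0 - drop(G[, supp, drop = FALSE] %*% w)
    }
    if (length(supp)) codes[supp, j] <- w
  }
  codes
}

#' Train a learned dictionary (K-SVD)
#'
#' Alternates OMP sparse coding of the training spectra with per-atom
#' rank-1 SVD updates (K-SVD). Atoms that no training spectrum uses are
#' replaced by the currently worst-represented sample. Two safeguards make
#' the training error provably non-increasing from iteration to iteration:
#' each signal keeps its previous code whenever re-coding would increase
#' its residual, and the SVD update never increases the residual of the
#' signals using the atom.
#'
#' The dictionary is initialised from the first `p_atoms` training
#' columns, so a corpus that leads with one exemplar of every distinct
#' prototype (see [trainingCorpus()]) starts — and with `sparsity = 1`
#' stays — in the prototype regime that per-pixel recovery through the
#' physically structured sensing matrix requires.
#'
#' @param training either an N x S numeric matrix of training spectra
#'   (columns are samples) or a list of [Spectrum-class] objects on one
#'   axis.
#' @param axis the [SpectralAxis-class]; required when `training` is a
#'   plain matrix.
#' @param p_atoms dictionary size P, default `2 * N`.
#' @param sparsity coding sparsity during training, default 1 (spherical
#'   k-means regime: atoms remain whole-spectrum prototypes).
#' @param iterations alternation count, default 30.
#' @param seed seed controlling the (only) stochastic step, dead-atom
#'   tie-breaking; training is deterministic given the corpus and seed.
#' @return a [DictionaryModel-class]; `training_meta$mse_trace` holds the
#'   per-iteration mean squared representation error.
#' @export
trainDictionary <- function(training, axis = NULL, p_atoms = NULL,
                            sparsity = 1, iterations = 30, seed = 1) {
  if (is.list(training)) {
    if (!length(training)) stop("empty training set")
    axis <- training[[1]]@axis
    for (s in training)
      if (!same_axis(s@axis, axis)) stop_axis_mismatch("training spectra differ")
    X <- vapply(training, intensities, numeric(axis@n_bands))
  } else {
    if (is.null(axis)) stop("axis is required for matrix input")
    X <- as.matrix(training)
    if (nrow(X) != axis@n_bands)
      stop_axis_mismatch("training matrix rows must equal axis n_bands")
  }
  n <- nrow(X)
  S <- ncol(X)
  if (is.null(p_atoms)) p_atoms <- 2L * n
  if (S < sparsity) stop("fewer training spectra than the coding sparsity")
  if (S < p_atoms)
    warning("fewer training spectra than atoms; dictionary will be redundant")
  nrmX <- pmax(sqrt(colSums(X^2)), 1e-12)
  Xn <- sweep(X, 2, nrmX, "/")
  D <- Xn[, rep_len(seq_len(S), p_atoms), drop = FALSE]
  mse <- numeric(iterations)
  prev <- NULL
  for (it in seq_len(iterations)) {
    codes <- batch_omp_code(D, Xn, sparsity)
    if (!is.null(prev)) {
      r_new <- colSums((Xn - D %*% codes)^2)
      r_old <- colSums((Xn - D %*% prev)^2)
      worse <- r_new > r_old
      codes[, worse] <- prev[, worse]
    }
    R <- Xn - D %*% codes
    for (p in seq_len(p_atoms)) {
      users <- which(codes[p, ] != 0)
      if (!length(users)) {
        err <- colSums(R^2)
        j <- which.max(err)
        cand <- Xn[, j]
        if (sum(cand^2) < 1e-20)
          cand <- with_seed(seed + p, stats::rnorm(n))
        D[, p] <- cand / sqrt(sum(cand^2))
        next
      }
      E <- R[, users, drop = FALSE] + outer(D[, p], codes[p, users])
      sv <- svd(E, nu = 1, nv = 1)
      D[, p] <- sv$u[, 1]
      codes[p, users] <- sv$d[1] * sv$v[, 1]
      R[, users] <- E - outer(D[, p], codes[p, users])
    }
    prev <- codes
    mse[it] <- mean(colSums(R^2))
  }
  new("DictionaryModel", atoms = D, axis = axis,
      training_meta = list(source = "K-SVD learned dictionary",
                           n_training = S, sparsity = sparsity,
                           iterations = iterations, seed = seed,
                           mse_trace = mse))
}

#' Synthesize a spectrum from sparse coefficients
#'
#' `f = Psi alpha`: the linear combination of the supported atoms.
#'
#' @param coeffs a [SparseCoefficients-class].
#' @param dict a [DictionaryModel-class] with `p_total` atoms.
#' @return a [Spectrum-class] (may contain negative values for mixed-sign
#'   atoms; no clipping is applied).
#' @export
synthesize <- function(coeffs, dict) {
  if (coeffs@p_total != ncol(dict@atoms))
    stop("coefficient p_total does not match the dictionary size")
  if (length(coeffs@indices) &&
      max(coeffs@indices) > ncol(dict@atoms))
    stop("atom index out of range")
  v <- numeric(nrow(dict@atoms))
  if (length(coeffs@indices))
    v <- drop(dict@atoms[, coeffs@indices, drop = FALSE] %*% coeffs@values)
  new("Spectrum", values = v, axis = dict@axis)
}

#' Analysis coefficients in an orthonormal basis
#'
#' `alpha = Psi' f`; defined for square orthonormal dictionaries (P = N),
#' where synthesize(analyze(f)) reconstructs f exactly.
#'
#' @param f a [Spectrum-class] on the dictionary axis.
#' @param dict an orthonormal [DictionaryModel-class] (e.g. [dctBasis()]).
#' @return a [SparseCoefficients-class] holding all N coefficients.
#' @export
analyze <- function(f, dict) {
  if (!same_axis(f@axis, dict@axis))
    stop_axis_mismatch("spectrum and dictionary differ")
  P <- ncol(dict@atoms)
  if (P != nrow(dict@atoms))
    stop("analyze() requires a square orthonormal dictionary")
  a <- drop(crossprod(dict@atoms, f@values))
  SparseCoefficients(seq_len(P), a, P)
}
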