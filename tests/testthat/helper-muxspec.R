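# Shared fixtures. Everything is generated in code; the only expensive
# object (the full-size learned dictionary used by the filter-PSNR
# experiments) is built lazily once per test run and cached.

# Constant-dispersion cell: dn = 0.2 at every wavelength, handy because
# retardations become exact rational multiples of pi.
flat_cell <- function(thickness_um, dn = 0.2)
  LiquidCrystalCell(thickness_um, c(dn, 0, 0))

# A tiny identity "dictionary" on an axis (atoms = delta spectra).
identity_dictionary <- function(axis)
  new("DictionaryModel", atoms = diag(nBands(axis)), axis = axis,
      training_meta = list(source = "identity"))

# Arbitrary valid sensing matrix from plain values.
raw_sensing_matrix <- function(values, axis)
  suppressWarnings(SensingMatrix(values, axis))

# Cached full-scale fixture for the filter reconstruction experiments:
# 200 bands over 500-700 nm, default 47-state modulator, dictionary
# trained on the default phantom corpus.
filter_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      axis <- SpectralAxis(500, 700, 200)
      phi <- defaultSensingMatrix(axis)
      corpus <- trainingCorpus(axis, n = 2000, seed = 7)
      dict <- trainDictionary(corpus, axis = axis, seed = 7)
      cache <<- list(axis = axis, phi = phi, dict = dict)
    }
    cache
  }
})

# Exact recovery condition (Tropp) of a support S for column-normalised A:
# OMP provably recovers S from any noiseless combination iff erc < 1.
erc_value <- function(A, S) {
  An <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  As <- An[, S, drop = FALSE]
  rest <- An[, -S, drop = FALSE]
  max(colSums(abs(solve(crossprod(As), crossprod(As, rest)))))
}

# Exhaustive best-support search at sparsity k (least-squares residual
# over every possible support) -- the brute-force oracle for OMP.
exhaustive_support <- function(g, A, k) {
  combs <- utils::combn(ncol(A), k)
  best <- NULL
  best_r <- Inf
  for (i in seq_len(ncol(combs))) {
    S <- combs[, i]
    r <- sum((g - qr.fitted(qr(A[, S, drop = FALSE]), g))^2)
    if (r < best_r - 1e-12) {
      best_r <- r
      best <- S
    }
  }
  sort(best)
}
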