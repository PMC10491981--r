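# Internal helpers shared across modules.

# Run code with a temporary RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards so seeded helpers do not perturb the
# global stream. seed = NULL draws from the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Minimum-norm least squares via SVD with relative rank tolerance; tolerant
# of exactly collinear columns (duplicate modulator states).
lstsq <- function(A, b, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  drop(s$v[, keep, drop = FALSE] %*%
         (crossprod(s$u[, keep, drop = FALSE], b) / s$d[keep]))
}

# Axes are equal when they describe the same grid.
same_axis <- function(a, b, tol = 1e-9) {
  a@n_bands == b@n_bands &&
    abs(a@start_nm - b@start_nm) < tol &&
    abs(a@stop_nm - b@stop_nm) < tol
}

stop_axis_mismatch <- function(what) {
  stop(sprintf("spectral axis mismatch: %s", what), call. = FALSE)
}
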