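#' Build the sensing matrix from modulator states
#'
#' Row i of the sensing matrix is the spectral transmission of the stack
#' in state i sampled at the band centers of the axis; the compressive
#' measurement model is then `g = Phi f` per pixel. Duplicated states
#' (identical retardation scales) produce identical rows; the resulting
#' rank deficiency is reported with a message rather than an error.
#'
#' @param stack a [ModulatorStack-class].
#' @param states list of [ModulationState-class], e.g. from
#'   [generateStates()].
#' @param axis a [SpectralAxis-class].
#' @return a [SensingMatrix-class] with one row per state.
#' @examples
#' phi <- buildSensingMatrix(defaultModulator(), generateStates(47),
#'                           SpectralAxis(450, 700, 250))
#' dim(as.matrix(phi))  # 47 x 250
#' @export
buildSensingMatrix <- function(stack, states, axis) {
  if (length(states) < 1) stop("at least one state is required")
  lam <- wavelengths(axis)
  vals <- t(vapply(states, function(st) stackTransmission(lam, stack, st),
                   numeric(length(lam))))
  if (any(rowSums(vals) < 1e-12))
    stop("degenerate modulator state produced an all-zero transmission row")
  scales <- vapply(states, function(st) st@retardation_scale, numeric(1))
  if (anyDuplicated(signif(scales, 12)))
    message("duplicated retardation scales: sensing matrix is rank deficient")
  times <- vapply(states, function(st) st@time_s, numeric(1))
  SensingMatrix(vals, axis, state_times = times)
}

#' Default sensing matrix of the simulated instrument
#'
#' Convenience wrapper: two-cell E7 modulator behind an ideal polarizer,
#' M states equally spaced over the 1 s relaxation window.
#'
#' @param axis a [SpectralAxis-class], default 450--700 nm with 250 bands.
#' @param m number of states, default 47.
#' @param stack a [ModulatorStack-class], default [defaultModulator()].
#' @param relaxation a [RelaxationModel-class].
#' @param window_s capture window in seconds, default 1.
#' @return a [SensingMatrix-class].
#' @export
defaultSensingMatrix <- function(axis = SpectralAxis(450, 700, 250), m = 47,
                                 stack = defaultModulator(),
                                 relaxation = RelaxationModel(),
                                 window_s = 1) {
  buildSensingMatrix(stack, generateStates(m, window_s, relaxation), axis)
}

#' Read a calibration transmission map
#'
#' Calibration CSV layout: a header line `wavelength_nm,<w1>,...,<wN>`
#' listing the N band-center wavelengths, then one line per modulator
#' state whose first field is the state's acquisition time (s) followed by
#' the N measured transmissions. The wavelength grid must be uniform and
#' all transmissions must lie in `[0, 1]`; offending cells are reported by
#' state row and wavelength column.
#'
#' @param path CSV file path.
#' @return a [SensingMatrix-class].
#' @seealso [writeTransmissionMap()] for the writer; a write/read round
#'   trip is bit exact.
#' @export
loadTransmissionMap <- function(path) {
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (colnames(raw)[1] != "wavelength_nm")
    stop("first header field must be 'wavelength_nm'")
  lam <- as.numeric(colnames(raw)[-1])
  if (any(is.na(lam))) stop("header wavelengths must be numeric")
  dl <- diff(lam)
  if (length(dl) && (any(dl <= 0) ||
                     max(abs(dl - dl[1])) > 1e-6 * abs(dl[1])))
    stop("wavelength grid must be strictly increasing and uniform")
  vals <- as.matrix(raw[, -1, drop = FALSE])
  bad <- which(!is.finite(vals) | vals < 0 | vals > 1, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("transmission outside [0, 1] at state row %d, wavelength %g nm (value %g)",
                 bad[1, 1], lam[bad[1, 2]], vals[bad[1, 1], bad[1, 2]]))
  spacing <- if (length(dl)) dl[1] else 1
  axis <- SpectralAxis(lam[1] - spacing / 2, lam[length(lam)] + spacing / 2,
                       length(lam))
  dimnames(vals) <- NULL
  SensingMatrix(vals, axis, state_times = as.numeric(raw[[1]]))
}

#' Write a sensing matrix as a calibration CSV
#'
#' Inverse of [loadTransmissionMap()]; values are written with 17
#' significant digits so the round trip reproduces doubles bit-exactly.
#'
#' @param phi a [SensingMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTransmissionMap <- function(phi, path) {
  lam <- wavelengths(phi)
  fmt <- function(x) sprintf("%.17g", x)
  header <- paste(c("wavelength_nm", fmt(lam)), collapse = ",")
  rows <- vapply(seq_len(nStates(phi)), function(i)
    paste(c(fmt(phi@state_times[i]), fmt(phi@values[i, ])), collapse = ","),
    character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Simulate one multiplexed measurement
#'
#' Computes `g = Phi f` and, when `noise_sigma > 0`, adds iid zero-mean
#' Gaussian noise with standard deviation `noise_sigma * max(Phi f)`
#' (noise scaled to the signal peak).
#'
#' @param f a [Spectrum-class] on the same axis as `phi`.
#' @param phi a [SensingMatrix-class].
#' @param noise_sigma relative noise level, default 0 (exact product).
#' @param seed integer seed for the noise draw; `NULL` uses the current
#'   RNG stream.
#' @return a [MeasurementVector-class] of length M.
#' @examples
#' ax <- SpectralAxis(500, 700, 200)
#' phi <- defaultSensingMatrix(ax)
#' f <- filterSpectrum(FilterSpec(600, 10), ax)
#' g <- simulateMeasurement(f, phi)
#' @export
simulateMeasurement <- function(f, phi, noise_sigma = 0, seed = NULL) {
  if (!same_axis(f@axis, phi@axis))
    stop_axis_mismatch("spectrum and sensing matrix differ")
  g <- drop(phi@values %*% f@values)
  meta <- list(model = "none")
  if (noise_sigma > 0) {
    sigma <- noise_sigma * max(g)
    g <- g + with_seed(seed, stats::rnorm(length(g), 0, sigma))
    meta <- list(model = "gaussian", sigma = sigma, relative = noise_sigma,
                 seed = seed)
  }
  new("MeasurementVector", values = g, noise_meta = meta)
}

#' Compressively acquire a hyperspectral cube
#'
#' Applies the sensing matrix to every pixel spectrum: frame i of the
#' output stack is the per-pixel dot product of sensing row i with the
#' cube. A single-pixel cube reproduces [simulateMeasurement()] exactly
#' (same seed): noise draws are consumed pixel by pixel in column-major
#' order, M values each, and each pixel's noise is scaled to that pixel's
#' signal peak.
#'
#' @param cube a [HyperspectralCube-class] on the same axis as `phi`.
#' @param phi a [SensingMatrix-class].
#' @param noise_sigma relative noise level, default 0.
#' @param seed integer seed, `NULL` for the current stream.
#' @return a [CompressedStack-class] of M frames.
#' @export
acquireCube <- function(cube, phi, noise_sigma = 0, seed = NULL) {
  if (!same_axis(cube@axis, phi@axis))
    stop_axis_mismatch("cube and sensing matrix differ")
  d <- dim(cube@data)
  npix <- d[1] * d[2]
  pix <- matrix(cube@data, nrow = npix)         # npix x N
  g <- pix %*% t(phi@values)                     # npix x M
  meta <- list(model = "none")
  if (noise_sigma > 0) {
    m <- nStates(phi)
    eps <- with_seed(seed, matrix(stats::rnorm(m * npix), nrow = m))
    peak <- apply(g, 1, max)
    g <- g + t(eps) * (noise_sigma * peak)
    meta <- list(model = "gaussian", relative = noise_sigma, seed = seed)
  }
  frames <- array(g, dim = c(d[1], d[2], nStates(phi)))
  new("CompressedStack", frames = frames, state_times = phi@state_times,
      matrix_id = sensingMatrixId(phi), noise_meta = meta)
}

# Stable identifier for provenance checks between stacks and matrices.
sensingMatrixId <- function(phi) {
  key <- paste(c(dim(phi@values), signif(phi@values[1, ], 8),
                 signif(phi@state_times, 8)), collapse = ",")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(key, tf)
  unname(substr(tools::md5sum(tf), 1, 12))
}

#' @describeIn throughput mean row transmission of each state and overall
#'   mean; equals area under the transmission curve normalised by the
#'   spectral span.
#' @examples
#' tp <- throughput(defaultSensingMatrix())
#' tp$mean  # ~0.25 for the default modulator
#' @export
setMethod("throughput", "SensingMatrix", function(phi) {
  per <- rowMeans(phi@values)
  list(per_state = per, mean = mean(per))
})
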