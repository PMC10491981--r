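#' Peak signal-to-noise ratio of a reconstructed spectrum
#'
#' Both spectra are normalised to unit maximum before comparison (the
#' metric is therefore invariant to overall scale), and
#' `PSNR = 10 log10(1 / MSE)` with the mean squared error taken over all
#' bands. Identical inputs would give +Inf; the value is capped at 300 dB
#' so results remain serialisable.
#'
#' @param reference ground-truth [Spectrum-class]; must not be identically
#'   zero.
#' @param estimate reconstructed [Spectrum-class] on the same axis.
#' @return PSNR in decibels.
#' @examples
#' ax <- SpectralAxis(500, 700, 200)
#' f <- filterSpectrum(FilterSpec(600, 10), ax)
#' psnr(f, f)  # 300 (capped)
#' @export
psnr <- function(reference, estimate) {
  if (!same_axis(reference@axis, estimate@axis))
    stop_axis_mismatch("reference and estimate differ")
  rmax <- max(abs(reference@values))
  if (rmax == 0) stop("reference spectrum is identically zero")
  emax <- max(abs(estimate@values))
  r <- reference@values / rmax
  e <- if (emax == 0) estimate@values else estimate@values / emax
  mse <- mean((r - e)^2)
  if (mse == 0) return(300)
  min(10 * log10(1 / mse), 300)
}

#' Estimate the MTF from a straight edge
#'
#' Classic edge-gradient method for an axis-aligned edge: the edge spread
#' function (ESF) is the profile across the edge averaged along it, the
#' line spread function (LSF) is the finite difference of the ESF
#' (centred at half-pixel positions, so an ideal step maps to a discrete
#' delta), the optical transfer function is the discrete Fourier transform
#' of the LSF, and the MTF is its modulus normalised to 1 at zero
#' frequency. Frequencies are reported up to Nyquist (0.5 cycles/pixel).
#'
#' @param image numeric matrix (grayscale image).
#' @param roi optional `c(row1, row2, col1, col2)` rectangle; default is
#'   the whole image. At least 16 pixels across the edge are required.
#' @param edge_orientation `"vertical"` (edge runs along rows, profile
#'   taken across columns) or `"horizontal"`.
#' @return an [MTFCurve-class].
#' @examples
#' img <- edgeTarget(64, 64, blur_sigma = 1.5)
#' m <- mtfFromEdge(img)
#' @export
mtfFromEdge <- function(image, roi = NULL, edge_orientation = c("vertical", "horizontal")) {
  edge_orientation <- match.arg(edge_orientation)
  if (!is.null(roi)) {
    image <- image[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  }
  if (edge_orientation == "horizontal") image <- t(image)
  if (ncol(image) < 16)
    stop("need at least 16 pixels across the edge")
  esf <- colMeans(image)
  lsf <- diff(esf)
  grad_peak <- max(abs(lsf))
  noise_floor <- stats::mad(lsf, center = 0)
  if (grad_peak < 6 * noise_floor || grad_peak == 0)
    stop("no detectable edge in the region of interest")
  otf <- abs(stats::fft(lsf))
  n <- length(lsf)
  freqs <- (seq_len(n) - 1) / n
  keep <- freqs <= 0.5 + 1e-12
  vals <- otf[keep] / otf[1]
  new("MTFCurve", frequencies = freqs[keep], values = vals)
}

#' Sup-norm difference between two MTF curves
#'
#' Curves are linearly interpolated onto the union of their frequency
#' grids restricted to the overlapping support, then the maximum absolute
#' difference is returned.
#'
#' @param curve_a,curve_b [MTFCurve-class] objects with overlapping
#'   frequency supports.
#' @return maximum absolute modulation difference.
#' @export
compareMtf <- function(curve_a, curve_b) {
  lo <- max(min(curve_a@frequencies), min(curve_b@frequencies))
  hi <- min(max(curve_a@frequencies), max(curve_b@frequencies))
  if (hi <= lo) stop("frequency supports do not overlap")
  grid <- sort(unique(c(curve_a@frequencies, curve_b@frequencies)))
  grid <- grid[grid >= lo & grid <= hi]
  va <- stats::approx(curve_a@frequencies, curve_a@values, grid)$y
  vb <- stats::approx(curve_b@frequencies, curve_b@values, grid)$y
  max(abs(va - vb))
}

# Contiguous equal-width band grouping: band i (0-based) of N maps to
# output band floor(i * n_out / N).
bin_indices <- function(n, n_out) floor((seq_len(n) - 1) * n_out / n)

#' Bin a spectrum to a coarse multispectral axis
#'
#' Emulates a multispectral imager with `n_out` contiguous equal-width
#' bands: each output band is the mean of the input bands it covers, so
#' the width-weighted integral of the signal is conserved.
#'
#' @param spectrum a [Spectrum-class] with N bands.
#' @param n_out desired number of output bands (<= N).
#' @return a [Spectrum-class] on the coarse axis.
#' @export
binToMultispectral <- function(spectrum, n_out) {
  n <- nBands(spectrum)
  if (n_out > n) stop("n_out may not exceed the number of input bands")
  idx <- bin_indices(n, n_out)
  v <- as.numeric(tapply(spectrum@values, idx, mean))
  axis <- SpectralAxis(spectrum@axis@start_nm, spectrum@axis@stop_nm, n_out)
  new("Spectrum", values = v, axis = axis)
}

#' Class envelopes and spectral separability
#'
#' Computes the per-band mean and standard deviation envelope of each
#' class and the separability fraction: the share of bands where the
#' `mean +/- sd` intervals of the two classes do not overlap. This is the
#' quantitative analogue of visually disjoint shaded envelopes in a
#' two-class spectral plot.
#'
#' @param spectra list of [Spectrum-class] objects on one axis, or an
#'   N x S matrix (columns are samples).
#' @param labels character vector with entries `"normal"` or `"cancer"`,
#'   one per sample; at least 2 samples per class.
#' @param axis required when `spectra` is a matrix.
#' @return list with elements `normal` and `cancer`
#'   ([ClassEnvelope-class]) and `separability` (fraction in `[0, 1]`).
#' @export
classEnvelopes <- function(spectra, labels, axis = NULL) {
  if (is.list(spectra)) {
    axis <- spectra[[1]]@axis
    X <- vapply(spectra, intensities, numeric(axis@n_bands))
  } else {
    if (is.null(axis)) stop("axis is required for matrix input")
    X <- as.matrix(spectra)
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(X))
    stop("one label per spectrum is required")
  for (cl in c("normal", "cancer"))
    if (sum(labels == cl) < 2)
      stop(sprintf("class '%s' needs at least 2 samples", cl))
  env <- lapply(c(normal = "normal", cancer = "cancer"), function(cl) {
    sub <- X[, labels == cl, drop = FALSE]
    new("ClassEnvelope",
        mean_spectrum = rowMeans(sub),
        sd_spectrum = apply(sub, 1, stats::sd),
        n_samples = ncol(sub), axis = axis)
  })
  a <- env$normal
  b <- env$cancer
  disjoint <- abs(a@mean_spectrum - b@mean_spectrum) >
    (a@sd_spectrum + b@sd_spectrum)
  c(env, list(separability = mean(disjoint)))
}
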