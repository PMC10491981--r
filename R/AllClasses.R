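#' Uniform wavelength grid
#'
#' A spectral axis splits `[start_nm, stop_nm)` into `n_bands` contiguous
#' bands of equal width; band centers sit at the midpoints. With the
#' default instrument configuration (450--700 nm, 250 bands) each band is
#' 1 nm wide, so band indices read directly as nanometres.
#'
#' @slot start_nm lower edge of the first band (nm).
#' @slot stop_nm upper edge of the last band (nm).
#' @slot n_bands number of bands N.
#' @export
setClass("SpectralAxis",
  representation(start_nm = "numeric", stop_nm = "numeric", n_bands = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@start_nm) != 1 || length(object@stop_nm) != 1)
      msg <- c(msg, "start_nm and stop_nm must be scalars")
    else if (!is.finite(object@start_nm) || !is.finite(object@stop_nm) ||
             object@stop_nm <= object@start_nm)
      msg <- c(msg, "stop_nm must exceed start_nm")
    if (length(object@n_bands) != 1 || is.na(object@n_bands) || object@n_bands < 1L)
      msg <- c(msg, "n_bands must be a positive integer")
    if (length(msg)) msg else TRUE
  })

#' Construct a SpectralAxis
#'
#' @param start_nm,stop_nm wavelength range in nm (half-open interval).
#' @param n_bands number of equal-width bands.
#' @return a [SpectralAxis-class] object.
#' @examples
#' ax <- SpectralAxis(450, 700, 250)
#' bandSpacing(ax)  # 1 nm
#' @export
SpectralAxis <- function(start_nm, stop_nm, n_bands) {
  new("SpectralAxis", start_nm = as.numeric(start_nm),
      stop_nm = as.numeric(stop_nm), n_bands = as.integer(n_bands))
}

#' A nematic liquid-crystal cell
#'
#' Holds the cell thickness and a three-term Cauchy model of the
#' birefringence dispersion, `dn(lambda) = A + B/lambda^2 + C/lambda^4`
#' with lambda in nm.
#'
#' @slot thickness_um cell gap in micrometres.
#' @slot cauchy_coeffs named numeric vector `c(A, B, C)`; B in nm^2, C in nm^4.
#' @export
setClass("LiquidCrystalCell",
  representation(thickness_um = "numeric", cauchy_coeffs = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@thickness_um) != 1 || !is.finite(object@thickness_um) ||
        object@thickness_um <= 0)
      msg <- c(msg, "thickness_um must be a positive scalar")
    if (length(object@cauchy_coeffs) != 3)
      msg <- c(msg, "cauchy_coeffs must have three elements (A, B, C)")
    else {
      lam <- seq(400, 750, by = 1)
      dn <- object@cauchy_coeffs[1] + object@cauchy_coeffs[2] / lam^2 +
        object@cauchy_coeffs[3] / lam^4
      if (any(!is.finite(dn)) || any(dn <= 0) || any(dn >= 0.4))
        msg <- c(msg, "birefringence must lie in (0, 0.4) over 400-750 nm")
    }
    if (length(msg)) msg else TRUE
  })

#' Cauchy dispersion coefficients for the E7 nematic mixture
#'
#' Three-term Cauchy coefficients fitted exactly through room-temperature
#' E7 birefringence anchors dn(450 nm) = 0.250, dn(589 nm) = 0.2255 and
#' dn(700 nm) = 0.216, values consistent with published measurements of
#' the mixture. Wavelengths in nm.
#'
#' @return named numeric vector `c(A, B, C)`.
#' @export
e7CauchyCoefficients <- function() {
  c(A = 1.942461833e-01, B = 1.021508327e+04, C = 2.177005834e+08)
}

#' Construct a LiquidCrystalCell
#'
#' @param thickness_um cell gap in micrometres (> 0).
#' @param cauchy_coeffs numeric `c(A, B, C)` dispersion coefficients;
#'   defaults to the E7 fit of [e7CauchyCoefficients()].
#' @return a [LiquidCrystalCell-class].
#' @examples
#' cell <- LiquidCrystalCell(50)
#' birefringence(589, cell)  # ~0.2255
#' @export
LiquidCrystalCell <- function(thickness_um, cauchy_coeffs = e7CauchyCoefficients()) {
  cc <- as.numeric(cauchy_coeffs)
  names(cc) <- c("A", "B", "C")
  new("LiquidCrystalCell", thickness_um = as.numeric(thickness_um),
      cauchy_coeffs = cc)
}

#' Two-cell spectral modulator between crossed polarizers
#'
#' @slot cells list of exactly two [LiquidCrystalCell-class] objects
#'   (anti-parallel aligned pair).
#' @slot polarizer_factor fraction of unpolarized input transmitted by the
#'   entrance polarizer; at most 0.5 for an ideal polarizer on lamp light.
#' @export
setClass("ModulatorStack",
  representation(cells = "list", polarizer_factor = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@cells) != 2 ||
        !all(vapply(object@cells, is, logical(1), "LiquidCrystalCell")))
      msg <- c(msg, "cells must be a list of exactly two LiquidCrystalCell objects")
    pf <- object@polarizer_factor
    if (length(pf) != 1 || !is.finite(pf) || pf <= 0 || pf > 1)
      msg <- c(msg, "polarizer_factor must be in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Construct a ModulatorStack
#'
#' @param cells list of two [LiquidCrystalCell-class] objects.
#' @param polarizer_factor entrance-polarizer transmission for unpolarized
#'   light, default 0.5 (ideal polarizer).
#' @return a [ModulatorStack-class].
#' @export
ModulatorStack <- function(cells, polarizer_factor = 0.5) {
  new("ModulatorStack", cells = cells,
      polarizer_factor = as.numeric(polarizer_factor))
}

#' Default modulator: 50 um + 25 um E7 cells behind an ideal polarizer
#'
#' The instrument's spectral encoder: two anti-parallel aligned E7 cells
#' of 50 and 25 micrometres between crossed polarizers, illuminated with
#' unpolarized lamp light (polarizer factor 0.5).
#'
#' @param polarizer_factor see [ModulatorStack()].
#' @return a [ModulatorStack-class].
#' @export
defaultModulator <- function(polarizer_factor = 0.5) {
  ModulatorStack(list(LiquidCrystalCell(50), LiquidCrystalCell(25)),
                 polarizer_factor = polarizer_factor)
}

#' One drive state of the modulator
#'
#' The tilt-angle profile induced by the drive voltage is collapsed into a
#' single effective retardation scale shared by both cells: scale 1 means
#' fully relaxed molecules (maximum retardation), small scales correspond
#' to high drive voltage.
#'
#' @slot retardation_scale effective retardation fraction in (0, 1].
#' @slot time_s acquisition time within the switch-off decay window (s).
#' @export
setClass("ModulationState",
  representation(retardation_scale = "numeric", time_s = "numeric"),
  validity = function(object) {
    msg <- character(0)
    s <- object@retardation_scale
    if (length(s) != 1 || !is.finite(s) || s <= 0 || s > 1)
      msg <- c(msg, "retardation_scale must be in (0, 1]")
    if (length(object@time_s) != 1 || !is.finite(object@time_s) || object@time_s < 0)
      msg <- c(msg, "time_s must be a nonnegative scalar")
    if (length(msg)) msg else TRUE
  })

#' Construct a ModulationState
#'
#' @param retardation_scale effective retardation fraction in (0, 1].
#' @param time_s acquisition time in seconds (>= 0).
#' @return a [ModulationState-class].
#' @export
ModulationState <- function(retardation_scale, time_s = 0) {
  new("ModulationState", retardation_scale = as.numeric(retardation_scale),
      time_s = as.numeric(time_s))
}

#' Switch-off relaxation dynamics of the modulator
#'
#' After the drive voltage is removed the molecules relax towards the
#' planar state; the effective retardation scale recovers as
#' `s(t) = 1 - (1 - scale_on) * exp(-t / tau_s)`.
#'
#' @slot tau_s relaxation time constant in seconds.
#' @slot scale_on retardation scale at voltage-on (t = 0), in (0, 1).
#' @export
setClass("RelaxationModel",
  representation(tau_s = "numeric", scale_on = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@tau_s) != 1 || !is.finite(object@tau_s) || object@tau_s <= 0)
      msg <- c(msg, "tau_s must be a positive scalar")
    so <- object@scale_on
    if (length(so) != 1 || !is.finite(so) || so <= 0 || so >= 1)
      msg <- c(msg, "scale_on must be in (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Construct a RelaxationModel
#'
#' Defaults qualitatively reproduce the measured switch-off behaviour of
#' the two-cell encoder: most of the modulation change happens early in
#' the one-second capture window while full relaxation takes longer.
#'
#' @param tau_s decay time constant in seconds, default 0.45.
#' @param scale_on retardation scale at maximum drive voltage, default 0.25.
#' @return a [RelaxationModel-class].
#' @export
RelaxationModel <- function(tau_s = 0.45, scale_on = 0.25) {
  new("RelaxationModel", tau_s = as.numeric(tau_s), scale_on = as.numeric(scale_on))
}

#' Single spectrum on a wavelength grid
#'
#' @slot values per-band intensities (finite).
#' @slot axis the [SpectralAxis-class] the values live on.
#' @export
setClass("Spectrum",
  representation(values = "numeric", axis = "SpectralAxis"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@values) != object@axis@n_bands)
      msg <- c(msg, sprintf("values length (%d) must equal n_bands (%d)",
                            length(object@values), object@axis@n_bands))
    if (any(!is.finite(object@values)))
      msg <- c(msg, "values must be finite")
    if (length(msg)) msg else TRUE
  })

#' Construct a Spectrum
#'
#' Physical input spectra are nonnegative; reconstructed spectra produced
#' by the solvers may carry small negative excursions and are built
#' internally without this check.
#'
#' @param values numeric vector of per-band intensities (nonnegative).
#' @param axis a [SpectralAxis-class].
#' @return a [Spectrum-class].
#' @export
Spectrum <- function(values, axis) {
  if (any(values < 0, na.rm = TRUE))
    stop("Spectrum values must be nonnegative")
  new("Spectrum", values = as.numeric(values), axis = axis)
}

#' Sensing matrix of the compressive spectral imager
#'
#' Rows are the spectral transmission curves of the M modulation states
#' sampled at the band centers of the axis; the measurement model is
#' `g = Phi f` per pixel. Compressive operation means M < N.
#'
#' @slot values M x N matrix with entries in `[0, 1]`.
#' @slot axis wavelength grid of the columns.
#' @slot state_times acquisition time of each state (s).
#' @export
setClass("SensingMatrix",
  representation(values = "matrix", axis = "SpectralAxis", state_times = "numeric"),
  validity = function(object) {
    msg <- character(0)
    v <- object@values
    if (ncol(v) != object@axis@n_bands)
      msg <- c(msg, "number of columns must equal axis n_bands")
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1 + 1e-9))
      msg <- c(msg, "entries must be finite and in [0, 1]")
    if (nrow(v) >= 1 && any(rowSums(abs(v)) == 0))
      msg <- c(msg, "all-zero rows are not allowed (degenerate modulator state)")
    if (length(object@state_times) != nrow(v))
      msg <- c(msg, "state_times length must equal the number of rows")
    if (length(msg)) msg else TRUE
  })

#' Construct a SensingMatrix
#'
#' @param values M x N nonnegative matrix of per-state transmissions.
#' @param axis a [SpectralAxis-class] matching the columns.
#' @param state_times acquisition times (s), one per row; defaults to
#'   zero-based equal indexing.
#' @return a [SensingMatrix-class]. A warning is raised when M >= N
#'   (non-compressive configuration).
#' @export
SensingMatrix <- function(values, axis, state_times = NULL) {
  values <- as.matrix(values)
  if (is.null(state_times)) state_times <- seq_len(nrow(values)) - 1
  obj <- new("SensingMatrix", values = values, axis = axis,
             state_times = as.numeric(state_times))
  if (nrow(values) >= axis@n_bands)
    warning("M >= N: non-compressive configuration")
  obj
}

#' Multiplexed measurement vector of one pixel
#'
#' @slot values M measured intensities.
#' @slot noise_meta list recording the noise model (`model`, `sigma`, `seed`).
#' @export
setClass("MeasurementVector",
  representation(values = "numeric", noise_meta = "list"),
  validity = function(object) {
    if (any(!is.finite(object@values))) "values must be finite" else TRUE
  })

#' Stack of M spectrally encoded camera frames
#'
#' @slot frames array `rows x cols x M`.
#' @slot state_times acquisition time of each frame (s).
#' @slot matrix_id identifier (hash) of the sensing matrix used.
#' @slot noise_meta list recording the noise model.
#' @export
setClass("CompressedStack",
  representation(frames = "array", state_times = "numeric",
                 matrix_id = "character", noise_meta = "list"),
  validity = function(object) {
    msg <- character(0)
    if (length(dim(object@frames)) != 3)
      msg <- c(msg, "frames must be a rows x cols x M array")
    else if (length(object@state_times) != dim(object@frames)[3])
      msg <- c(msg, "state_times length must equal the frame count")
    if (any(!is.finite(object@frames)))
      msg <- c(msg, "frames must be finite")
    if (length(msg)) msg else TRUE
  })

#' Hyperspectral datacube
#'
#' @slot data array `rows x cols x N` of per-pixel spectra.
#' @slot axis wavelength grid of the third dimension.
#' @slot labels optional character matrix (`rows x cols`) of pixel classes.
#' @export
setClass("HyperspectralCube",
  representation(data = "array", axis = "SpectralAxis", labels = "ANY"),
  prototype(labels = NULL),
  validity = function(object) {
    msg <- character(0)
    d <- dim(object@data)
    if (length(d) != 3)
      msg <- c(msg, "data must be a rows x cols x bands array")
    else {
      if (d[3] != object@axis@n_bands)
        msg <- c(msg, "third dimension must equal axis n_bands")
      if (!is.null(object@labels) &&
          (!is.matrix(object@labels) || !identical(dim(object@labels), d[1:2])))
        msg <- c(msg, "labels must be NULL or a rows x cols matrix")
    }
    if (any(!is.finite(object@data)))
      msg <- c(msg, "data must be finite")
    if (length(msg)) msg else TRUE
  })

#' Construct a HyperspectralCube
#'
#' @param data numeric array `rows x cols x N`.
#' @param axis a [SpectralAxis-class].
#' @param labels optional `rows x cols` matrix of class labels.
#' @return a [HyperspectralCube-class].
#' @export
HyperspectralCube <- function(data, axis, labels = NULL) {
  new("HyperspectralCube", data = data, axis = axis, labels = labels)
}

#' Sparsifying dictionary
#'
#' Columns ("atoms") are unit-norm spectra; a pixel spectrum is modelled
#' as a sparse combination `f = Psi alpha`. Analytic bases have P = N
#' orthonormal atoms; learned dictionaries are overcomplete (P >= N).
#'
#' @slot atoms N x P matrix with unit-norm columns.
#' @slot axis wavelength grid of the rows.
#' @slot training_meta list describing provenance (source, seed, iterations,
#'   per-iteration training error).
#' @export
setClass("DictionaryModel",
  representation(atoms = "matrix", axis = "SpectralAxis", training_meta = "list"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@atoms) != object@axis@n_bands)
      msg <- c(msg, "atom length must equal axis n_bands")
    nrm <- sqrt(colSums(object@atoms^2))
    if (any(abs(nrm - 1) > 1e-8))
      msg <- c(msg, "all atoms must have unit Euclidean norm (+/- 1e-8)")
    if (length(msg)) msg else TRUE
  })

#' Sparse coefficient vector
#'
#' @slot indices support set (1-based atom indices, distinct).
#' @slot values coefficients, one per index.
#' @slot p_total size of the dictionary the indices refer to.
#' @export
setClass("SparseCoefficients",
  representation(indices = "integer", values = "numeric", p_total = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@indices) != length(object@values))
      msg <- c(msg, "indices and values must have equal length")
    if (anyDuplicated(object@indices))
      msg <- c(msg, "indices must be distinct")
    if (length(object@indices) &&
        (min(object@indices) < 1L || max(object@indices) > object@p_total))
      msg <- c(msg, "indices must lie in [1, p_total]")
    if (length(msg)) msg else TRUE
  })

#' Construct SparseCoefficients
#'
#' @param indices integer support set (1-based).
#' @param values coefficients.
#' @param p_total dictionary size.
#' @return a [SparseCoefficients-class].
#' @export
SparseCoefficients <- function(indices, values, p_total) {
  new("SparseCoefficients", indices = as.integer(indices),
      values = as.numeric(values), p_total = as.integer(p_total))
}

#' Solver configuration for spectral recovery
#'
#' @slot solver `"twist"` or `"omp"`.
#' @slot reg_lambda l1 regularisation weight for TwIST. With
#'   `lambda_mode = "relative"` (default) the effective weight is
#'   `reg_lambda * max |A' g|` so one value works across signal scales.
#' @slot lambda_mode `"relative"` or `"absolute"`.
#' @slot sparsity_k maximum OMP support size.
#' @slot residual_tol OMP stop: relative residual norm below this.
#' @slot max_iterations iteration cap (TwIST).
#' @slot tolerance relative objective-change stopping tolerance (TwIST).
#' @slot norm_power internal column weighting exponent p: atom selection is
#'   performed on columns scaled by `||a_j||^-p`. 1 is full normalisation,
#'   0 leaves raw physical column energies.
#' @slot debias logical; refit the selected support by least squares.
#' @slot debias_threshold support selection threshold for debiasing,
#'   relative to the largest coefficient magnitude.
#' @export
setClass("SolverConfig",
  representation(solver = "character", reg_lambda = "numeric",
                 lambda_mode = "character", sparsity_k = "integer",
                 residual_tol = "numeric", max_iterations = "integer",
                 tolerance = "numeric", norm_power = "numeric",
                 debias = "logical", debias_threshold = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@solver) != 1 || !object@solver %in% c("twist", "omp"))
      msg <- c(msg, "solver must be exactly one of 'twist' or 'omp'")
    if (object@reg_lambda < 0) msg <- c(msg, "reg_lambda must be nonnegative")
    if (!object@lambda_mode %in% c("relative", "absolute"))
      msg <- c(msg, "lambda_mode must be 'relative' or 'absolute'")
    if (object@max_iterations < 1L) msg <- c(msg, "max_iterations must be positive")
    if (object@sparsity_k < 0L) msg <- c(msg, "sparsity_k must be nonnegative")
    if (object@norm_power < 0 || object@norm_power > 1)
      msg <- c(msg, "norm_power must be in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Construct a SolverConfig
#'
#' Defaults are the package's tuned settings: TwIST with relative lambda
#' 0.01, column weighting exponent 0.75 and least-squares debiasing; OMP
#' with support size 3.
#'
#' @param solver `"twist"` or `"omp"`.
#' @param reg_lambda regularisation weight (TwIST), see [SolverConfig-class].
#' @param lambda_mode `"relative"` (default) or `"absolute"`.
#' @param sparsity_k OMP support size, default 3.
#' @param residual_tol OMP relative residual stop, default 1e-6.
#' @param max_iterations TwIST iteration cap, default 2000.
#' @param tolerance TwIST relative objective-change stop, default 1e-9.
#' @param norm_power column weighting exponent in `[0, 1]`, default 0.75.
#' @param debias least-squares refit on the selected support, default TRUE.
#' @param debias_threshold relative support threshold, default 0.05.
#' @return a [SolverConfig-class].
#' @export
SolverConfig <- function(solver = c("twist", "omp"), reg_lambda = 0.01,
                         lambda_mode = "relative", sparsity_k = 3L,
                         residual_tol = 1e-6, max_iterations = 2000L,
                         tolerance = 1e-9, norm_power = 0.75,
                         debias = TRUE, debias_threshold = 0.05) {
  solver <- match.arg(solver)
  new("SolverConfig", solver = solver, reg_lambda = as.numeric(reg_lambda),
      lambda_mode = lambda_mode, sparsity_k = as.integer(sparsity_k),
      residual_tol = as.numeric(residual_tol),
      max_iterations = as.integer(max_iterations),
      tolerance = as.numeric(tolerance), norm_power = as.numeric(norm_power),
      debias = isTRUE(debias), debias_threshold = as.numeric(debias_threshold))
}

#' Result of one spectral recovery
#'
#' @slot spectrum recovered [Spectrum-class] (`Psi alpha`); may contain
#'   small negative values, which are clipped only at export.
#' @slot coefficients the sparse coefficients alpha.
#' @slot objective_trace per-iteration objective values (TwIST) or residual
#'   norms (OMP).
#' @slot iterations_used iterations actually run.
#' @slot converged TRUE when the stopping tolerance was reached before the
#'   iteration cap and the trace did not diverge.
#' @export
setClass("ReconstructionResult",
  representation(spectrum = "Spectrum", coefficients = "SparseCoefficients",
                 objective_trace = "numeric", iterations_used = "integer",
                 converged = "logical"))

#' Modulation transfer function estimate
#'
#' @slot frequencies spatial frequencies in cycles/pixel, up to Nyquist (0.5).
#' @slot values modulation normalised to 1 at zero frequency.
#' @export
setClass("MTFCurve",
  representation(frequencies = "numeric", values = "numeric"),
  validity = function(object) {
    msg <- character(0)
    f <- object@frequencies
    if (length(f) != length(object@values))
      msg <- c(msg, "frequencies and values must have equal length")
    if (length(f) && (f[1] != 0 || any(diff(f) <= 0)))
      msg <- c(msg, "frequencies must start at 0 and increase strictly")
    if (length(object@values) && abs(object@values[1] - 1) > 1e-12)
      msg <- c(msg, "value at zero frequency must be 1")
    if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
    if (length(msg)) msg else TRUE
  })

#' Per-class mean +/- sd spectral envelope
#'
#' @slot mean_spectrum per-band class mean.
#' @slot sd_spectrum per-band class standard deviation.
#' @slot n_samples number of pixels in the class.
#' @slot axis wavelength grid.
#' @export
setClass("ClassEnvelope",
  representation(mean_spectrum = "numeric", sd_spectrum = "numeric",
                 n_samples = "integer", axis = "SpectralAxis"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@mean_spectrum) != object@axis@n_bands ||
        length(object@sd_spectrum) != object@axis@n_bands)
      msg <- c(msg, "envelope lengths must match the axis")
    if (any(object@sd_spectrum < 0)) msg <- c(msg, "sd must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' Bandpass filter specification
#'
#' @slot center_nm central wavelength (nm).
#' @slot fwhm_nm full width at half maximum (nm).
#' @slot peak_transmission peak transmission in (0, 1].
#' @export
setClass("FilterSpec",
  representation(center_nm = "numeric", fwhm_nm = "numeric",
                 peak_transmission = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (object@fwhm_nm <= 0) msg <- c(msg, "fwhm_nm must be positive")
    if (object@peak_transmission <= 0 || object@peak_transmission > 1)
      msg <- c(msg, "peak_transmission must be in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Construct a FilterSpec
#'
#' @param center_nm central wavelength in nm.
#' @param fwhm_nm full width at half maximum in nm.
#' @param peak_transmission peak transmission, default 1.
#' @return a [FilterSpec-class].
#' @export
FilterSpec <- function(center_nm, fwhm_nm, peak_transmission = 1) {
  new("FilterSpec", center_nm = as.numeric(center_nm),
      fwhm_nm = as.numeric(fwhm_nm),
      peak_transmission = as.numeric(peak_transmission))
}

## ---- accessors and show methods ------------------------------------------

#' @describeIn wavelengths band centers of the axis itself
#' @export
setMethod("wavelengths", "SpectralAxis", function(x) {
  x@start_nm + (seq_len(x@n_bands) - 0.5) / x@n_bands * (x@stop_nm - x@start_nm)
})

#' @describeIn wavelengths axis of a spectrum
#' @export
setMethod("wavelengths", "Spectrum", function(x) wavelengths(x@axis))

#' @describeIn wavelengths axis of a sensing matrix
#' @export
setMethod("wavelengths", "SensingMatrix", function(x) wavelengths(x@axis))

#' @describeIn wavelengths axis of a cube
#' @export
setMethod("wavelengths", "HyperspectralCube", function(x) wavelengths(x@axis))

#' @describeIn wavelengths axis of a dictionary
#' @export
setMethod("wavelengths", "DictionaryModel", function(x) wavelengths(x@axis))

#' @describeIn nBands band count of the axis
#' @export
setMethod("nBands", "SpectralAxis", function(x) x@n_bands)

#' @describeIn nBands band count of a spectrum
#' @export
setMethod("nBands", "Spectrum", function(x) x@axis@n_bands)

#' @describeIn nBands band count of a sensing matrix
#' @export
setMethod("nBands", "SensingMatrix", function(x) x@axis@n_bands)

#' @describeIn nBands band count of a cube
#' @export
setMethod("nBands", "HyperspectralCube", function(x) x@axis@n_bands)

#' @describeIn nBands band count of a dictionary
#' @export
setMethod("nBands", "DictionaryModel", function(x) x@axis@n_bands)

#' @describeIn bandSpacing width of one band of the axis
#' @export
setMethod("bandSpacing", "SpectralAxis", function(x)
  (x@stop_nm - x@start_nm) / x@n_bands)

#' @describeIn bandSpacing band width of a spectrum's axis
#' @export
setMethod("bandSpacing", "Spectrum", function(x) bandSpacing(x@axis))

#' @describeIn bandSpacing band width of a sensing matrix's axis
#' @export
setMethod("bandSpacing", "SensingMatrix", function(x) bandSpacing(x@axis))

#' @describeIn nStates rows of the sensing matrix
#' @export
setMethod("nStates", "SensingMatrix", function(x) nrow(x@values))

#' @describeIn nStates frames in a compressed stack
#' @export
setMethod("nStates", "CompressedStack", function(x) dim(x@frames)[3])

#' @describeIn stateTimes of a sensing matrix
#' @export
setMethod("stateTimes", "SensingMatrix", function(x) x@state_times)

#' @describeIn stateTimes of a compressed stack
#' @export
setMethod("stateTimes", "CompressedStack", function(x) x@state_times)

#' @describeIn intensities values of a spectrum
#' @export
setMethod("intensities", "Spectrum", function(x) x@values)

#' @describeIn intensities values of a measurement vector
#' @export
setMethod("intensities", "MeasurementVector", function(x) x@values)

#' @describeIn cubeData the raw array
#' @export
setMethod("cubeData", "HyperspectralCube", function(x) x@data)

#' @describeIn cubeLabels label matrix or NULL
#' @export
setMethod("cubeLabels", "HyperspectralCube", function(x) x@labels)

#' @describeIn nAtoms atom count
#' @export
setMethod("nAtoms", "DictionaryModel", function(x) ncol(x@atoms))

#' Coerce a SensingMatrix to its numeric matrix
#' @param x a `SensingMatrix`.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "SensingMatrix", function(x, ...) x@values)

#' Coerce a DictionaryModel to its atom matrix
#' @param x a `DictionaryModel`.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "DictionaryModel", function(x, ...) x@atoms)

setMethod("show", "SpectralAxis", function(object) {
  cat(sprintf("SpectralAxis: %d bands over [%g, %g) nm (%.3g nm/band)\n",
              object@n_bands, object@start_nm, object@stop_nm,
              bandSpacing(object)))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d bands over [%g, %g) nm, range [%.4g, %.4g]\n",
              object@axis@n_bands, object@axis@start_nm, object@axis@stop_nm,
              min(object@values), max(object@values)))
})

setMethod("show", "SensingMatrix", function(object) {
  tp <- throughput(object)
  cat(sprintf(paste0("SensingMatrix: %d states x %d bands over [%g, %g) nm\n",
                     "  compression N/M = %.2f, mean throughput = %.1f%%\n"),
              nrow(object@values), ncol(object@values),
              object@axis@start_nm, object@axis@stop_nm,
              ncol(object@values) / nrow(object@values), 100 * tp$mean))
})

setMethod("show", "HyperspectralCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("HyperspectralCube: %d x %d pixels, %d bands over [%g, %g) nm%s\n",
              d[1], d[2], d[3], object@axis@start_nm, object@axis@stop_nm,
              if (is.null(object@labels)) "" else ", labeled"))
})

setMethod("show", "DictionaryModel", function(object) {
  cat(sprintf("DictionaryModel: %d atoms x %d bands (%s)\n",
              ncol(object@atoms), nrow(object@atoms),
              if (is.null(object@training_meta$source)) "unspecified source"
              else object@training_meta$source))
})

setMethod("show", "CompressedStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("CompressedStack: %d frames of %d x %d pixels\n", d[3], d[1], d[2]))
})

setMethod("show", "ReconstructionResult", function(object) {
  cat(sprintf("ReconstructionResult: %d iterations, %sconverged, |support| = %d\n",
              object@iterations_used, if (object@converged) "" else "NOT ",
              length(object@coefficients@indices)))
})

setMethod("show", "MTFCurve", function(object) {
  cat(sprintf("MTFCurve: %d frequencies up to %.3g cyc/px\n",
              length(object@frequencies), max(object@frequencies)))
})

setMethod("show", "ClassEnvelope", function(object) {
  cat(sprintf("ClassEnvelope: n = %d, %d bands\n", object@n_samples,
              object@axis@n_bands))
})
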