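#' Band-center wavelengths
#'
#' Returns the wavelengths (nm) at the centers of the spectral bands of an
#' object carrying a [SpectralAxis-class].
#'
#' @param x a `SpectralAxis`, `Spectrum`, `SensingMatrix`,
#'   `HyperspectralCube` or `DictionaryModel`.
#' @return numeric vector of band-center wavelengths in nm.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Number of spectral bands
#'
#' @param x an object carrying a [SpectralAxis-class].
#' @return integer band count N.
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' Width of one spectral band
#'
#' @param x an object carrying a [SpectralAxis-class].
#' @return band width in nm, `(stop - start) / n_bands`.
#' @export
setGeneric("bandSpacing", function(x) standardGeneric("bandSpacing"))

#' Number of modulation states / measurement frames
#'
#' @param x a `SensingMatrix` or `CompressedStack`.
#' @return integer count M.
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' Acquisition times of the modulation states
#'
#' @param x a `SensingMatrix` or `CompressedStack`.
#' @return numeric vector of state times in seconds.
#' @export
setGeneric("stateTimes", function(x) standardGeneric("stateTimes"))

#' Intensity values of a spectral or measurement vector
#'
#' @param x a `Spectrum` or `MeasurementVector`.
#' @return numeric vector of intensities.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Data array of a hyperspectral cube
#'
#' @param x a `HyperspectralCube`.
#' @return numeric array `rows x cols x bands`.
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' Per-pixel class labels of a hyperspectral cube
#'
#' @param x a `HyperspectralCube`.
#' @return character matrix of labels, or `NULL` when the cube is unlabeled.
#' @export
setGeneric("cubeLabels", function(x) standardGeneric("cubeLabels"))

#' Number of dictionary atoms
#'
#' @param x a `DictionaryModel`.
#' @return integer atom count P.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Optical throughput of a sensing matrix
#'
#' Per-exposure throughput is the mean transmission over the spectral
#' span (area under the state's transmission curve normalised by the
#' span), the multiplex-advantage figure of merit of the instrument.
#'
#' @param phi a [SensingMatrix-class].
#' @return a list with `per_state` (numeric, one value per row of the
#'   matrix) and `mean` (their average).
#' @export
setGeneric("throughput", function(phi) standardGeneric("throughput"))
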