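#' Birefringence of a liquid-crystal cell
#'
#' Evaluates the cell's Cauchy dispersion
#' `dn(lambda) = A + B/lambda^2 + C/lambda^4` (lambda in nm). With
#' positive B and C the birefringence decreases monotonically with
#' wavelength, as measured for nematic mixtures in the visible.
#'
#' @param lambda_nm wavelength(s) in nm; must lie in the supported
#'   400--750 nm range.
#' @param cell a [LiquidCrystalCell-class].
#' @return birefringence value(s), dimensionless.
#' @examples
#' birefringence(589, LiquidCrystalCell(50))  # ~0.2255 for E7
#' @export
birefringence <- function(lambda_nm, cell) {
  if (any(lambda_nm < 400 | lambda_nm > 750))
    stop("wavelength outside the supported 400-750 nm range")
  cc <- cell@cauchy_coeffs
  unname(cc[1] + cc[2] / lambda_nm^2 + cc[3] / lambda_nm^4)
}

#' Retardation of one cell at an effective drive scale
#'
#' Optical phase delay `Gamma = 2 pi dn(lambda) * scale * d / lambda`,
#' linear in both the cell gap d and the effective retardation scale.
#' The scale collapses the voltage-dependent tilt-angle profile of the
#' molecules into one scalar in (0, 1].
#'
#' @param lambda_nm wavelength(s) in nm.
#' @param cell a [LiquidCrystalCell-class].
#' @param scale effective retardation fraction in (0, 1].
#' @return retardation in radians.
#' @export
retardation <- function(lambda_nm, cell, scale = 1) {
  if (any(scale <= 0))
    stop("retardation scale must be positive")
  2 * pi * birefringence(lambda_nm, cell) * scale *
    (cell@thickness_um * 1000) / lambda_nm
}

#' Spectral transmission of the modulator stack in one state
#'
#' For the two-cell stack oriented at 45 degrees between crossed
#' polarizers the transmitted fraction is
#' `T = polarizer_factor * sin^2(Gamma_total / 2)` where `Gamma_total`
#' is the sum of the two cells' retardations; both cells share the
#' state's retardation scale. Larger scales put more interference
#' fringes across a fixed spectral window.
#'
#' @param lambda_nm wavelength(s) in nm.
#' @param stack a [ModulatorStack-class].
#' @param state a [ModulationState-class].
#' @return transmission fraction(s) in `[0, polarizer_factor]`.
#' @examples
#' st <- defaultModulator()
#' stackTransmission(550, st, ModulationState(1))
#' @export
stackTransmission <- function(lambda_nm, stack, state) {
  gamma_total <- retardation(lambda_nm, stack@cells[[1]], state@retardation_scale) +
    retardation(lambda_nm, stack@cells[[2]], state@retardation_scale)
  stack@polarizer_factor * sin(gamma_total / 2)^2
}

#' Relaxation of the retardation scale after switch-off
#'
#' Single-exponential approach to the relaxed state:
#' `s(t) = 1 - (1 - scale_on) * exp(-t / tau)`, strictly increasing from
#' `scale_on` at t = 0 towards 1.
#'
#' @param t_s time(s) since switch-off in seconds (>= 0).
#' @param model a [RelaxationModel-class].
#' @return retardation scale(s) in `[scale_on, 1)`.
#' @export
relaxationScale <- function(t_s, model) {
  if (any(t_s < 0)) stop("time must be nonnegative")
  1 - (1 - model@scale_on) * exp(-t_s / model@tau_s)
}

#' Generate modulation states over the capture window
#'
#' Samples the switch-off decay at `m` equally spaced times spanning
#' `[0, window_s]` and assigns each time its relaxation scale. Because the
#' relaxation is strictly monotone the scales are all distinct; a warning
#' is raised when neighbouring scales come closer than ~1e-6 (states no
#' longer usefully distinguishable for the given tau).
#'
#' @param m number of states (>= 1).
#' @param window_s capture window length in seconds, default 1.
#' @param model a [RelaxationModel-class].
#' @return list of [ModulationState-class], ordered in time.
#' @examples
#' st <- generateStates(47, 1, RelaxationModel())
#' length(st)  # 47
#' @export
generateStates <- function(m, window_s = 1, model = RelaxationModel()) {
  if (m < 1) stop("m must be at least 1")
  if (window_s <= 0) stop("window_s must be positive")
  times <- if (m == 1) 0 else seq(0, window_s, length.out = m)
  scales <- relaxationScale(times, model)
  if (m > 1 && min(diff(scales)) < 1e-6)
    warning("states nearly indistinguishable at this m / tau combination")
  mapply(function(s, t) ModulationState(s, t), scales, times,
         SIMPLIFY = FALSE)
}

#' Response-time gain of splitting a thick cell
#'
#' Nematic relaxation time grows quadratically with the cell gap
#' (tau proportional to d^2). Replacing a single thick cell by a pair of
#' thinner cells with the same total retardation leaves the response
#' limited by the thickest member of the pair, giving a speed-up of
#' `d_single^2 / max(d_pair)^2`.
#'
#' @param single_um thickness of the single-cell design in micrometres.
#' @param pair_um thicknesses of the replacement pair, default `c(50, 25)`.
#' @return the factor by which the limiting response time shrinks.
#' @examples
#' responseTimeRatio(75)  # 2.25
#' @export
responseTimeRatio <- function(single_um, pair_um = c(50, 25)) {
  if (single_um <= 0 || any(pair_um <= 0))
    stop("thicknesses must be positive")
  (single_um / max(pair_um))^2
}
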