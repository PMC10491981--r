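gaussian_profile <- function(lambda, center, sigma) {
  exp(-(lambda - center)^2 / (2 * sigma^2))
}

#' Gaussian bandpass filter spectrum
#'
#' Ideal bandpass filter transmission with a Gaussian profile:
#' `sigma = fwhm / (2 sqrt(2 ln 2))`, peak at the filter's central
#' wavelength.
#'
#' @param spec a [FilterSpec-class].
#' @param axis a [SpectralAxis-class]; the filter center must lie inside
#'   the axis range.
#' @return a [Spectrum-class].
#' @examples
#' f <- filterSpectrum(FilterSpec(632.8, 1), SpectralAxis(500, 700, 200))
#' @export
filterSpectrum <- function(spec, axis) {
  if (spec@center_nm < axis@start_nm || spec@center_nm >= axis@stop_nm)
    stop("filter center lies outside the spectral axis")
  sigma <- spec@fwhm_nm / (2 * sqrt(2 * log(2)))
  lam <- wavelengths(axis)
  Spectrum(spec@peak_transmission * gaussian_profile(lam, spec@center_nm, sigma),
           axis)
}

#' Configuration of the two-class H&E-like tissue phantom
#'
#' The phantom emulates transmission microscopy of an H&E-stained section
#' with a Beer--Lambert model: each pixel's transmission is
#' `illuminant * 10^-(c_h A_h(lambda) + c_e A_e(lambda))` plus additive
#' detection noise, with per-pixel stain concentrations drawn from
#' class-specific distributions. The hematoxylin-like absorbance is a
#' broad Gaussian band (590 nm, sd 85 nm) and the eosin-like absorbance a
#' narrower one (525 nm, sd 15 nm); these are synthetic stand-ins, not
#' measured stain spectra. The cancer class has a higher nuclear-stain and
#' lower cytoplasmic-stain concentration than the normal class — a
#' concentration-ratio shift, not a new chromophore — which separates the
#' class mean spectra with opposite signs on either side of a crossover
#' wavelength.
#'
#' @param n_pixels_per_class pixels per class, default 20.
#' @param noise_sigma additive Gaussian noise sd relative to the unit
#'   illuminant, default 0.002.
#' @param normal,cancer per-class concentration parameters: lists with
#'   `mean_h`, `mean_e`, `sd_h`, `sd_e`.
#' @param stains absorbance band parameters: list of two lists
#'   (`hematoxylin`, `eosin`) with `center`, `sigma`, `amplitude`.
#' @param illuminant scalar illuminant intensity, default 1 (flat lamp
#'   spectrum).
#' @return a list config accepted by [tissueCube()].
#' @export
tissuePhantomConfig <- function(n_pixels_per_class = 20, noise_sigma = 0.002,
                                normal = list(mean_h = 0.60, mean_e = 0.60,
                                              sd_h = 0.04, sd_e = 0.04),
                                cancer = list(mean_h = 0.95, mean_e = 0.34,
                                              sd_h = 0.04, sd_e = 0.04),
                                stains = list(
                                  hematoxylin = list(center = 590, sigma = 85,
                                                     amplitude = 1),
                                  eosin = list(center = 525, sigma = 15,
                                               amplitude = 1)),
                                illuminant = 1) {
  stopifnot(n_pixels_per_class >= 1, noise_sigma >= 0, illuminant > 0,
            all(unlist(normal) >= 0), all(unlist(cancer) >= 0),
            stains$hematoxylin$amplitude >= 0, stains$eosin$amplitude >= 0)
  list(n_pixels_per_class = n_pixels_per_class, noise_sigma = noise_sigma,
       normal = normal, cancer = cancer, stains = stains,
       illuminant = illuminant)
}

# Absorbance curves of the two stains on a wavelength grid.
stain_absorbances <- function(stains, lam) {
  list(h = stains$hematoxylin$amplitude *
         gaussian_profile(lam, stains$hematoxylin$center, stains$hematoxylin$sigma),
       e = stains$eosin$amplitude *
         gaussian_profile(lam, stains$eosin$center, stains$eosin$sigma))
}

#' Two-class labeled tissue phantom cube
#'
#' Generates a labeled hyperspectral cube with
#' `2 * n_pixels_per_class` pixels laid out in two rows (row 1 normal,
#' row 2 cancer). A pure function of `(config, seed)`: identical calls
#' give identical cubes.
#'
#' @param config from [tissuePhantomConfig()].
#' @param axis a [SpectralAxis-class].
#' @param seed integer seed, default 1.
#' @return a labeled [HyperspectralCube-class].
#' @examples
#' cube <- tissueCube(tissuePhantomConfig(), SpectralAxis(450, 700, 250))
#' table(cubeLabels(cube))
#' @export
tissueCube <- function(config, axis, seed = 1) {
  lam <- wavelengths(axis)
  ab <- stain_absorbances(config$stains, lam)
  npc <- config$n_pixels_per_class
  n <- axis@n_bands
  with_seed(seed, {
    data <- array(0, dim = c(2, npc, n))
    for (ci in 1:2) {
      cls <- if (ci == 1) config$normal else config$cancer
      for (j in seq_len(npc)) {
        ch <- max(stats::rnorm(1, cls$mean_h, cls$sd_h), 0)
        ce <- max(stats::rnorm(1, cls$mean_e, cls$sd_e), 0)
        spec <- config$illuminant * 10^-(ch * ab$h + ce * ab$e)
        if (config$noise_sigma > 0)
          spec <- spec + stats::rnorm(n, 0, config$noise_sigma)
        data[ci, j, ] <- pmin(pmax(spec, 0), config$illuminant)
      }
    }
    labels <- matrix(rep(c("normal", "cancer"), npc), nrow = 2)
    new("HyperspectralCube", data = data, axis = axis, labels = labels)
  })
}

#' Synthetic straight-edge resolution target
#'
#' Vertical step edge at mid-width (low level on the left, high on the
#' right), optionally blurred with a sampled Gaussian kernel and
#' corrupted with additive Gaussian noise. A pure function of its
#' arguments and the seed.
#'
#' @param height,width image size in pixels (>= 32 each).
#' @param blur_sigma Gaussian blur sd in pixels, 0 for a perfect step.
#' @param contrast step height, default 1.
#' @param noise_sigma additive noise sd, default 0.
#' @param seed integer seed for the noise, default 1.
#' @param low background level, default 0.1.
#' @return numeric `height x width` matrix.
#' @export
edgeTarget <- function(height = 64, width = 64, blur_sigma = 0, contrast = 1,
                       noise_sigma = 0, seed = 1, low = 0.1) {
  if (height < 32 || width < 32) stop("target must be at least 32 x 32")
  img <- matrix(low, height, width)
  img[, (width %/% 2 + 1):width] <- low + contrast
  if (blur_sigma > 0) {
    r <- ceiling(4 * blur_sigma)
    kern <- gaussian_profile((-r):r, 0, blur_sigma)
    kern <- kern / sum(kern)
    pad <- cbind(matrix(img[, 1], height, r), img,
                 matrix(img[, width], height, r))
    img <- t(apply(pad, 1, function(row)
      as.numeric(stats::filter(row, kern, sides = 2))))[, (r + 1):(r + width)]
  }
  if (noise_sigma > 0)
    img <- img + with_seed(seed, matrix(stats::rnorm(height * width, 0,
                                                     noise_sigma),
                                        height, width))
  img
}

#' Training corpus of phantom spectra for dictionary learning
#'
#' Builds the default corpus the learned dictionary is trained on:
#' \itemize{
#'   \item a narrowband calibration sweep — one Gaussian line of FWHM equal
#'     to one band spacing at every band center (the narrowband-filter
#'     family);
#'   \item a broadband sweep — FWHM of ten band spacings at every second
#'     band center (the broadband-filter family);
#'   \item random H&E-like tissue transmission spectra drawn from the
#'     tissue phantom's concentration distributions (both classes).
#' }
#' The corpus leads with exactly one exemplar of every distinct prototype,
#' then repeats the sweeps and fills up with random tissue spectra; this
#' ordering lets [trainDictionary()] initialise every prototype as an
#' atom. Deterministic given the seed.
#'
#' @param axis a [SpectralAxis-class].
#' @param n corpus size, default 2000.
#' @param seed integer seed for the tissue draws, default 1.
#' @param tissue_config tissue concentration config, default
#'   [tissuePhantomConfig()].
#' @return N x n numeric matrix of spectra (columns are samples).
#' @export
trainingCorpus <- function(axis, n = 2000, seed = 1,
                           tissue_config = tissuePhantomConfig()) {
  lam <- wavelengths(axis)
  nb <- axis@n_bands
  dl <- bandSpacing(axis)
  s_narrow <- dl / (2 * sqrt(2 * log(2)))
  s_broad <- 10 * dl / (2 * sqrt(2 * log(2)))
  ab <- stain_absorbances(tissue_config$stains, lam)
  with_seed(seed, {
    tis <- function() {
      cls <- if (stats::runif(1) < 0.5) tissue_config$normal else tissue_config$cancer
      ch <- max(stats::rnorm(1, cls$mean_h, cls$sd_h), 0)
      ce <- max(stats::rnorm(1, cls$mean_e, cls$sd_e), 0)
      10^-(ch * ab$h + ce * ab$e)
    }
    narrow <- vapply(lam, function(c0) gaussian_profile(lam, c0, s_narrow),
                     numeric(nb))
    broad <- vapply(lam[seq(1, nb, by = 2)],
                    function(c0) gaussian_profile(lam, c0, s_broad),
                    numeric(nb))
    n_proto_tis <- max(2, nb %/% 2)
    proto_tis <- vapply(seq_len(n_proto_tis), function(i) tis(), numeric(nb))
    proto <- cbind(narrow, broad, proto_tis)
    np <- ncol(proto)
    if (n < 2 * np)
      stop(sprintf("corpus size n must be at least %d for this axis", 2 * np))
    extra <- n - 2 * np
    X <- cbind(proto, proto,
               if (extra > 0)
                 vapply(seq_len(extra), function(i) tis(), numeric(nb)))
    X
  })
}
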