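---
title: "Multiplexed hyperspectral microscopy: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplexed hyperspectral microscopy: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muxspec)
```

This vignette is the package's account of the science it implements: the
physical forward model and its assumptions, the sparse-recovery machinery,
what every tunable parameter means and why its default was chosen, what the
phantom generators do and do not emulate, and the numerical decisions that
matter when reproducing results.

## 1. The physical forward model

A nematic liquid-crystal (LC) cell of gap $d$ placed at 45° between crossed
polarizers delays one polarization component by the retardation
$\Gamma(\lambda) = 2\pi\,\Delta n(\lambda)\, s\, d / \lambda$, and the stack
of two anti-parallel cells transmits

$$T(\lambda) = p \cdot \sin^2\!\big(\tfrac{1}{2}(\Gamma_1 + \Gamma_2)\big),$$

where $p$ is the fraction of the (unpolarized) lamp light passed by the
entrance polarizer. The transmission is a fringe pattern in $\lambda$; the
fringe count scales with the optical path difference
$\sum_i \Delta n\, d_i\, s$.

**Birefringence dispersion.** The E7 mixture's $\Delta n(\lambda)$ is
modelled by a three-term Cauchy law
$\Delta n = A + B/\lambda^2 + C/\lambda^4$. The default coefficients
(`e7CauchyCoefficients()`) are solved exactly through three
room-temperature anchors consistent with published E7 measurements:
$\Delta n(450) = 0.250$, $\Delta n(589) = 0.2255$, $\Delta n(700) = 0.216$.
The coefficients live in the configuration, not in the logic, so another
material is a config edit. At full relaxation the default 50 µm + 25 µm
pair has an optical path difference of ≈ 17.3 µm at 550 nm, which puts
≈ 17 fringes across 450–700 nm.

**Drive state.** The voltage-dependent tilt-angle profile of the molecules
is collapsed into a single *retardation scale* $s \in (0, 1]$ shared by
both cells (they are driven together). This is deliberate: the
reconstruction never needs the absolute voltage, only the calibrated
transmission rows, so a scalar effective scale is the minimal faithful
state description. Viewing-angle compensation, rise dynamics and
temperature dependence are out of scope.

**Relaxation sampling.** After switch-off the scale recovers as
$s(t) = 1 - (1 - s_{\mathrm{on}})\,e^{-t/\tau}$ — a single-exponential
approximation of the nematic director relaxation. Defaults
$\tau = 0.45$ s and $s_{\mathrm{on}} = 0.25$ reproduce the qualitative
behaviour of the measured device: most of the modulation change falls in
the first second, so `generateStates(m = 47, window_s = 1)` samples the
window at equal intervals and obtains 47 distinct states. Because
relaxation time grows as $d^2$, replacing one 75 µm cell with the
50 + 25 µm pair cuts the limiting response time by
$75^2/50^2 = 2.25\times$ (`responseTimeRatio()`).

**Sensing matrix.** Row $i$ of $\Phi$ is state $i$'s transmission sampled
at the band centers of a uniform wavelength grid. The default instrument
uses 250 bands on $[450, 700)$ nm (1 nm bands, so band arithmetic is
exact) and $M = 47$ states: compression $N/M \approx 5.3$. The mean of a
row is that exposure's optical throughput; over the default states it
averages 25%, versus $1/250 = 0.4\%$ for an ideal single-band filter —
the multiplex (Fellgett) advantage.

An important *structural* property, verified numerically: although $\Phi$
has 47 rows, its singular values decay sharply (the sin² fringe family is
nearly band-limited in the $\Delta n\, d\, s$ coordinate), leaving an
effective numerical rank of roughly 30. Recovery therefore leans heavily
on the sparsity prior — this drives several design choices below.

## 2. Sparsifying operators

`dctBasis()` provides the orthonormal DCT-II basis (adequate for smooth
spectra). `trainDictionary()` learns an overcomplete dictionary by K-SVD:
batch OMP sparse coding against the current atoms, then per-atom rank-1
SVD updates; dead atoms are replaced by the worst-represented training
sample. Two safeguards make the training error *provably* non-increasing
(each signal keeps its previous code when re-coding would worsen it, and
the SVD update is optimal for the signals using the atom), which the test
suite asserts.

**Training corpus** (`trainingCorpus()`): a deterministic narrowband sweep
(one Gaussian line of FWHM = 1 band spacing at every band center), a
deterministic broadband sweep (FWHM = 10 spacings at every second
center), and random H&E-like tissue spectra. The sweeps emulate
calibration with the two bandpass-filter families the evaluation uses
(1 nm and 10 nm FWHM); the tissue spectra cover the imaging use case. The
corpus leads with one exemplar of every distinct prototype and the
dictionary is initialised from the first $P$ columns, so every prototype
starts as an atom.

**Why coding sparsity 1.** The default training sparsity is 1 — the
spherical k-means regime of K-SVD — rather than a larger value. With the
rank-limited physical $\Phi$, per-pixel recovery succeeds only when the
dictionary contains whole-spectrum *prototypes* whose images under $\Phi$
are distinguishable; at coding sparsity ≥ 2 the atom updates let atoms
drift into residual-correction directions, and measured filter PSNR
collapses from ≈ 62 dB to 15–25 dB. At sparsity 1 the deterministic sweep
atoms are exact fixed points of the alternation, which also makes the
filter experiments reproducible across corpus seeds. Defaults: 2000
training spectra, $P = 2N$ atoms, 30 iterations.

## 3. Solvers

**OMP** (`ompSolve()`): greedy support growth on the effective dictionary
$A = \Phi\Psi$ with fully normalised columns for selection (classic OMP),
least-squares refit on the raw columns at every step, stopping at
`sparsity_k` atoms or at a relative residual below `residual_tol`. Under
the exact recovery condition (ERC < 1) OMP provably finds the true
support of noiseless sparse signals; the tests verify 100% agreement with
exhaustive support search on ERC-satisfying random instances (random
all-positive matrices routinely violate the ERC, so the guarantee regime
is the meaningful comparison set).

**TwIST** (`twistSolve()`): the two-step iterative shrinkage/thresholding
recursion for $\tfrac12\|g - A\alpha\|^2 + \lambda\|\alpha\|_1$, with the
operator rescaled by its spectral norm and the two-step parameters set
from an assumed smallest-to-largest eigenvalue ratio of $10^{-4}$
(severely ill-posed regime; config-overridable). A monotone safeguard
falls back to a plain IST step whenever the two-step update would raise
the objective, so the objective trace is non-increasing by construction.

Three tuned defaults matter (none are reported by the measurements the
simulator reproduces, so they are package choices, recorded here and in
`SolverConfig()`):

* **Column weighting `norm_power = 0.75`.** Atom selection inside TwIST
  operates on columns scaled by $\|a_j\|^{-p}$. Raw physical columns
  ($p = 0$) favour high-energy broad atoms and fail on narrowband spectra
  (≈ 15 dB); full normalisation ($p = 1$) lets line atoms crowd out broad
  ones and fails on broadband spectra (≈ 25 dB). $p = 0.75$ sits on a
  plateau ($p \in [0.6, 0.9]$, $\lambda_{\mathrm{rel}} \in [5·10^{-3},
  2·10^{-2}]$) where all three reference filters reconstruct at ≈ 62 dB.
* **Relative regularisation `reg_lambda = 0.01`** (of
  $\max|A^\top g|$), making one default work across signal scales;
  `lambda_mode = "absolute"` is available and is what the
  scale-equivariance property uses.
* **Debiasing on.** The ℓ1 estimate is refit by least squares on the
  support above 5% of the largest coefficient. With coherent columns the
  raw ℓ1 solution spreads energy over neighbouring atoms; the refit
  removes that bias.

The default stopping rule is effectively the iteration cap
(`max_iterations = 2000`; the relative-change tolerance $10^{-9}$ is
rarely reached on the ill-posed filter problems). This is intentional:
the ℓ1 objective keeps creeping for thousands of iterations while the
*debiased support* stabilises early, and very long runs slowly trade
spectral fidelity for objective decrease (62 dB at 2000 iterations,
≈ 49 dB at 6000 — both far above the acceptance floor, but the cap is
part of the tuned default). The `converged` flag honestly reports
cap-limited stops.

`reconstructCube()` applies the configured solver per pixel; pixels are
independent, so results do not depend on visiting order. The default cube
solver is OMP (fast, bounded support) while filter spectra default to
TwIST, mirroring how the two experiments are usually run.

## 4. Phantoms: what they emulate, what they do not

* `filterSpectrum()` — Gaussian bandpass profiles
  ($\sigma = \mathrm{FWHM}/2.355$). Real interference filters have flatter
  tops and side lobes; the Gaussian stand-in matches center/width specs
  only.
* `edgeTarget()` — a straight, axis-aligned step edge with optional
  Gaussian blur and noise, standing in for a resolution test target. The
  estimator (`mtfFromEdge()`) assumes the axis-aligned geometry; no
  slanted-edge super-resolution is attempted, so sub-pixel phase effects
  are not modelled.
* `tissueCube()` — Beer–Lambert transmission
  $I \cdot 10^{-(c_h A_h + c_e A_e)}$ with per-pixel stain concentrations
  drawn per class and additive detection noise. The absorbance shapes are
  synthetic stand-ins (broad hematoxylin-like band at 590 nm, sd 85 nm;
  narrower eosin-like band at 525 nm, sd 15 nm), *not* measured stain
  spectra. The cancer class differs only by a concentration-ratio shift
  (more nuclear stain, less cytoplasmic stain: 0.95/0.34 vs 0.60/0.60,
  sd 0.04, noise sd 0.002, 20 pixels per class, flat unit illuminant).
  The opposite-sign transmission differences cross zero near 545 nm and
  around the eosin band, so the class envelopes separate at fine spectral
  sampling but largely cancel inside the coarse band that straddles the
  eosin feature — which is exactly the fine-vs-8-band contrast the
  evaluation quantifies. The cancer eosin mean (0.34) was calibrated once
  so that this cancellation sits well inside the envelope overlap across
  generator seeds, then frozen. No tissue morphology, scattering or
  wavelength-dependent illumination is modelled, so passing tests say the
  *pipeline* reproduces the contrast mechanism, not that real biopsies
  would show these exact spectra.

All generators are pure functions of (config, seed).

## 5. Evaluation conventions

* **PSNR** normalises both spectra to unit maximum and reports
  $10\log_{10}(1/\mathrm{MSE})$, capped at 300 dB. The reference amplitude
  convention makes the metric scale-free; a different peak convention
  shifts all values equally.
* **MTF**: the edge spread function is the across-edge profile averaged
  along the edge; the line spread function is its first difference
  (centred at half-pixel positions — so an ideal step maps to a discrete
  delta and yields MTF ≡ 1 exactly, and a Gaussian blur of $\sigma = 1.5$
  px matches $\exp(-2\pi^2\sigma^2 u^2)$ to better than $10^{-4}$; a
  two-sample centred difference would bias the estimate by up to 0.05 at
  $u = 0.15$ cyc/px). Frequencies are reported to Nyquist.
* **Band binning** (`binToMultispectral()`) averages contiguous
  equal-width groups (group of band $i$ is $\lfloor i\,n_{\mathrm{out}}/N
  \rfloor$), conserving the width-weighted integral. 250 → 8 bands gives
  groups of 31–32 bands.
* **Separability** is the fraction of bands where the two classes'
  mean ± sd intervals are disjoint — the quantitative version of
  "the shaded envelopes do not overlap".

## 6. Numerical details and degenerate inputs

* Rank-deficient systems are handled by SVD-based minimum-norm least
  squares with a relative singular-value cutoff of $10^{-10}$ (duplicate
  modulator states or collinear supports do not crash the refits).
* `buildSensingMatrix()` rejects all-zero transmission rows (a modulator
  state that blocks everything) and flags duplicated retardation scales
  with a message; `SensingMatrix()` warns when $M \ge N$.
* Calibration CSVs, dictionaries and ENVI wavelength blocks are written
  with 17 significant digits so write→read round trips are bit exact;
  cube payloads are float32 (exact for float32-valued data).
* Reconstructed spectra may carry small negative excursions; nothing
  clips them except file export, which logs the clip.
* Seeded helpers save and restore the caller's RNG state, so seeded calls
  do not perturb the session stream.

## 7. Problem sizes used by the test suite

The suite runs the full-size filter experiments (200 bands, 47 states,
2000-spectrum corpus, 400 atoms, 30 K-SVD iterations) once and caches the
dictionary; unit tests elsewhere use 8–60 band axes, which exercise the
same code paths at interactive speed. The whole suite completes in well
under a minute on a single core; `scripts/acceptance.R` likewise.

## 8. Known limitations

* The scalar retardation scale ignores the spatial tilt-angle profile and
  viewing-angle dependence; a measured transmission map can be loaded via
  `loadTransmissionMap()` when physical fidelity matters.
* Noise is additive Gaussian scaled to the signal peak; photon shot
  noise, detector quantisation and fixed-pattern noise are out of scope.
* Filters far from the two trained families (e.g. 3 nm or 20 nm FWHM)
  reconstruct noticeably worse than the 1 nm / 10 nm families — the
  learned dictionary is a prototype dictionary, and the rank-limited
  modulator cannot compensate for missing prototypes.
* The 8-band "multispectral imager" emulation is plain contiguous
  averaging; real multispectral filter shapes are not modelled.
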