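---
title: "Methods: modelling and analysing transient mid-infrared nanoscopy of photoswitchable vesicles"
author: "nanoswitch developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transient mid-infrared nanoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoswitch)
```

# The measurement this package models

In membrane-based liquid s-SNOM, a metallized AFM tip taps at frequency
$\Omega$ on a ~10 nm SiN membrane; lipid vesicles adhere to the membrane's
underside in D$_2$O. A mid-infrared beam focused on the tip creates a
confined near field that probes ~100 nm into the liquid. The backscattered
field is demodulated at harmonics $n\Omega$ (here $n=2$) to suppress
far-field background, giving an amplitude $s_2$ and phase $\varphi_2$ per
pixel or time point. Azobenzene photolipids in the vesicle membrane
isomerize under 365 nm (trans to cis) and 465 nm (cis to trans)
illumination, changing the local dielectric function and the vesicle shape;
both responses are what the analysis quantifies.

The package implements four analysis blocks plus a synthetic-data
generator: a forward model of near-field contrast, vesicle image
segmentation and shape statistics, sigmoidal switching-kinetics fitting
with detection statistics, and nano-FTIR spectral processing.

# Forward model

## Multilayer reflection

The sample below the tip is a stack of planar media with complex
permittivities. Its quasi-static, momentum-resolved reflection coefficient
is built by downward recursion (transfer-matrix form): for an interface
with $\epsilon_j$ above and $\epsilon_{j+1}$ below, over a lower composite
$\beta_{below}$ across thickness $d_{j+1}$,

$$\beta_j(q) = \frac{r_j + \beta_{below} e^{-2 q d_{j+1}}}
                    {1 + r_j \beta_{below} e^{-2 q d_{j+1}}},\qquad
  r_j = \frac{\epsilon_{j+1}-\epsilon_j}{\epsilon_{j+1}+\epsilon_j}.$$

For two layers this reduces to the Fresnel-like
$(\epsilon_2-\epsilon_1)/(\epsilon_2+\epsilon_1)$, independent of $q$ — an
exactness the tests assert to 1e-12. A zero-thickness layer drops out of
the recursion algebraically; `layer()` therefore accepts thickness 0 even
though physical films are strictly positive.

## Momentum weighting and the finite dipole

A point-dipole-like source at height $z$ weights momenta as $q e^{-2qz}$:

$$\beta_{eff}(z) = \frac{\int_0^\infty \beta(q)\, q e^{-2qz}\, dq}
                        {\int_0^\infty q e^{-2qz}\, dq}.$$

The integral uses a log-spaced grid of 400 nodes between $10^{-5}$ and
$10\,\mathrm{nm^{-1}}$ with the trapezoid rule; a $10^5$-node oracle in the
test suite bounds the relative error below $10^{-4}$ for 10 nm films. The
choice of a momentum-weighted $\beta$ (rather than a matrix Green's
function variant) is a design decision of this package: the published
description names the model family and its parameters but not the
equations, so we adopt the standard spheroid closed form with the empirical
charge factor:

$$\sigma(H) = 1 + \frac{\beta_0\, f_0(H)}{2\,(1-\beta_1 f_1(H))},\qquad
  f_i(H) = \Big(g - \tfrac{r+2H+W_i}{2L}\Big)
  \frac{\ln\frac{4L}{r+4H+2W_i}}{\ln\frac{4L}{r}},$$

with $W_0 = 1.31\, rL/(L+2r)$, $W_1 = r/2$, and $\beta_i$ evaluated at
height $H + W_i$. Defaults follow the reported tip: $a = 80$ nm tapping
amplitude, $r = 60$ nm apex radius, $L = 300$ nm spheroid length,
$g = 0.7e^{i0.06}$ with the exponent read as radians and $L$ as the full
spheroid length (both stated as our interpretation of the printed values).
The closest approach `min_height` defaults to 0 nm (tip touches the
membrane at the bottom of the tap).

## Demodulation and referencing

The tap is $H(\theta) = h_{min} + a(1+\cos\theta)$;
$\sigma_n = \frac{1}{2\pi}\oint \sigma(H(\theta)) e^{-in\theta} d\theta$
is computed by uniform sampling (power-of-two count, default 256) and an
FFT. Because the integrand is smooth and periodic this converges
spectrally; the suite checks agreement with 1e4-point quadrature to
1e-8 relative. Spectra are referenced as
$\eta_n = \sigma_n^{sample}/\sigma_n^{ref}$ against silicon or the
surrounding D$_2$O.

One subtlety: "lossless media give zero referenced phase" holds only when
the empirical tip factor $g$ is real. The default complex
$g = 0.7e^{i0.06}$ imprints roughly 1.8 degrees even on purely real
permittivity stacks, and the imprint differs between sample and reference,
so it does not cancel. The corresponding invariant is therefore tested
with $g = 0.7$.

## Hanging sphere vs flattened vesicle

To mirror the geometric argument for vesicle flattening, `sphere_profile()`
predicts the lateral $\varphi_2$ profile of a rigid sphere hanging from a
point contact under the membrane: at offset $x$ the local stack contains a
D$_2$O gap $d(x) = R - \sqrt{R^2-x^2}$ and a sphere-material chord
$2\sqrt{R^2-x^2}$, truncated at a visibility depth of 200 nm (the reported
bound beyond which objects are invisible; sensitivity reaches ~100 nm).
This thin-film locality approximation ignores lateral coupling — adequate
for comparing profile *shapes*. A flattened vesicle is modelled as a disc
of the same footprint hugging the membrane with constant thickness
(default 100 nm). The acceptance suite verifies the sphere profile is
strictly narrower (FWHM) than the disc profile, the direction the
measured-vs-model comparison relies on.

## Material surrogates

`builtin_materials()` ships Lorentz-oscillator surrogates
($\epsilon(\nu) = \epsilon_\infty + \sum_j S_j\nu_j^2/(\nu_j^2-\nu^2-
i\gamma_j\nu)$): lipid bands at 1466/1496/1603/1740 cm$^{-1}$ (the 1603
ring-breathing band weakened in the cis table, the 1740 carbonyl
unchanged), a SiN phonon in the 800–1150 cm$^{-1}$ window, flat lossy
D$_2$O, and $\epsilon = 11.7$ silicon. These are illustrative fixtures in
an editable CSV, not literature fits. Strengths are chosen so peak
$\mathrm{Im}\,\epsilon \lesssim 0.3$: in this weak-band regime the
referenced phase at a band center grows monotonically with oscillator
strength (a tested property); much stronger bands saturate and turn over,
which is physical but outside the regime these lipid bands occupy.

# Synthetic scenes and what they do (not) establish

The generator states the world the analysis is tested against:

* **Images** (`render_image`): vesicles are flat-top discs in amplitude and
  phase (interior phase above 25 degrees against background) with a
  raised-cosine fringe ramp of ~100 nm width centered on the true boundary,
  plus i.i.d. Gaussian pixel noise. The fringe is a rendering device to
  challenge segmentation the way measured fringes do, not modelled physics.
  The boundary may carry a low-order radial harmonic
  $r(\varphi) = R(1+A\cos k\varphi)$; analytic truth (area, perimeter,
  circularity) is always computed from the continuous boundary by dense
  quadrature, never from the raster, so discretization error stays
  attributable to the analysis.
* **State pairs** (`render_state_pair`): the cis state scales the trans
  disc to a target area factor (default 1.10) and adds a harmonic
  (default order 3, gentle lobes) whose amplitude is found by bisection so
  the true circularity ratio hits the target (default 0.92). Area of the
  perturbed shape is $\pi R_c^2 (1+A^2/2)$, used to solve for $R_c$.
* **Traces** (`render_trace`): per epoch
  $f(t) = C + L/(1+e^{-(t-t_d)/\tau})$, evaluated as its boxcar average
  over each sampling window of width $t_p$ (32 sub-samples) — the same
  convolution the instrument's integration time imposes — plus Gaussian
  noise. The default schedule is the reported stated world: eight
  alternating 1-minute epochs at $t_p = 0.5$ s, amplitude steps of 8%
  (down under 365 nm, up under 465 nm), phase steps of 1.6 degrees, delays
  within 10.3–15.7 s and growth times within 0.7–3.9 s. Default noise
  (0.01 on normalized $s_2$, 0.2 degrees on $\varphi_2$) puts the step SNR
  near 8, a value we chose as realistic for the reported traces; it is not
  printed in the source.
* **Interferograms** (`render_interferogram`): discrete spectral components
  summed as $\mathrm{Re}\sum_k A_k e^{i(2\pi\nu_k \cdot 2x + \phi_k)}$
  over the mirror-position grid $x$. The factor 2 makes mirror travel half
  the optical path difference, so a 350 um scan yields the quoted
  1/(2 x 350 um) = 14.3 cm$^{-1}$ nominal resolution.

What a green test establishes: the estimators recover the stated world's
parameters at the stated noise levels. What it does not: correctness of the
noise model itself (measured images have correlated fringing, drift and
topography crosstalk that i.i.d. Gaussian noise does not emulate), or any
claim about the real instrument's values.

# Segmentation and shape statistics

The boundary rule follows the reported criterion: threshold the
background-subtracted amplitude at $1/e$ of the maximum at the particle
center (an absolute threshold, e.g. the reported 7.8 arb.units, is the
exposed alternative since that number is scene-specific). Background is
the median of a border frame (default fraction 0.15) — the source does not
specify its procedure; this one is recorded here. The particle center is
found by strict-ascent hill climbing from the seed; the mask is the
connected component of the peak with holes filled; components touching the
image edge are flagged, not rejected.

Circularity is $4\pi A/p^2$. Its fidelity hinges entirely on the perimeter
estimator: a raw marching-squares polygon on a binary disc mask
overestimates $p$ by ~5% and drags circularity to 0.90, which would
contradict the definition's promise that a disc scores 1. The package
therefore measures polygons as: sub-pixel iso-contour
(`grDevices::contourLines`) → resampling to 0.5 px vertex spacing →
corner detection at 3 px scale (vertices turning more than 50 degrees are
pinned, so genuine corners survive) → 50 iterations of neighbor-averaging
with every vertex clamped within 0.35 px of its original position. The
clamp confines the smoothing to the rasterization uncertainty band:
staircase artifacts are removed, real shape is not. On binary fixtures a
disc scores 0.999, an axis-aligned square $\pi/4 + 1.7\%$, and ellipse and
three-lobed blob perimeters land within 0.3% of analytic truth. For noisy
images, one 3x3 box-filter pass (`presmooth`) precedes thresholding; on the
locally linear fringe ramp a symmetric kernel does not move the boundary
to first order. Residual effects — the $1/e$ level sitting slightly
outside the true boundary on a 100 nm ramp (~+4% absolute area), and mild
lobe smoothing on perturbed shapes — are biases of the *absolute* numbers
that largely cancel in the trans/cis ratios the analysis reports; the
acceptance suite measures the recovered changes at +9.9% / -7.4% against
the +10% / -8% truth.

Line profiles are sampled with bilinear interpolation and fitted with a
Gaussian plus offset (initials: offset = min, amplitude = max - min,
center = argmax, sigma = length/6); FWHM $= 2\sqrt{2\ln 2}\,\sigma$ with
its standard error from the fit covariance.

# Transient analysis

Epochs are maximal constant-illumination runs; each local time axis starts
at the switch instant. The sigmoid $f(t) = C + L/(1+e^{-(t-t_d)/\tau})$ is
fitted by a package-internal Levenberg–Marquardt solver with analytic
Jacobian rather than `stats::nls`: the zero-noise fixtures the invariants
demand (equivariance to 1e-9 under time shifts and channel scaling) sit
exactly where nls's relative-offset criterion is unreliable.
Initialization follows the recorded recipe — $C$ from the first quartile
of samples, $L$ from the last, $t_d$ from the moving-average crossing of
$C + L/2$, $\tau$ from the 25–75% crossing spread divided by $\ln 9$ —
with multi-start over $\tau/3, \tau, 3\tau$. No deconvolution of the
sampling boxcar is attempted: when $\tau \lesssim t_p$ the fitted $\tau$
is biased toward $t_p$, and the fit reports $t_p$ alongside so readers can
apply the caveat that true dynamics are likely faster (the print method
flags $\tau < 2 t_p$).

Step statistics use plateau means outside a guard interval (default
$3\max(\tau, t_p)$) around the transition. Two deliberately distinct
conventions are reported, since the source prints both kinds of number
without defining either: SNR $= |\Delta\mu| / s_{pooled}$ (per-sample) and
significance $z = |\Delta\mu| / \sqrt{s_1^2/n_1 + s_2^2/n_2}$. The percent
amplitude change is referenced to the pre-transition mean, as defined;
note this makes the percent (but not the absolute) change asymmetric under
swapping pre/post.

The detection-power study scales per-sample noise as
$\sigma \propto 1/\sqrt{t_p}$ (integration averaging — our stated model,
the source gives none) calibrated to SNR 4 at $t_p = 30$ ms, and holds the
number of plateau samples fixed (default 100 per side) so that
$z \propto \sqrt{t_p}$. With fixed plateau *duration* instead, $z$ would be
independent of $t_p$; the fixed-count choice reproduces the reported trend
of significance growing from 30 ms to 100 ms sampling. The printed 3.72 and
5.5 sigma values are conventions of the original instrument analysis and
are not targets.

# Nano-FTIR processing

The asymmetric-Michelson interferogram is mean-subtracted, optionally
Hann-apodized (default none — boxcar is what makes the nominal resolution
$1/(2\,\mathrm{scan})$ the honest number), optionally zero-filled, and
Fourier-transformed one-sidedly without symmetrization or Mertz phase
correction: the asymmetric geometry delivers amplitude and phase directly.
The wavenumber axis is $\nu_k = k/(2\Delta x N)$ with $\Delta x$ the
mirror step in cm. Parseval consistency (no apodization/zero-fill) is
asserted to 1e-9. Referencing divides complex spectra pointwise, masking
bins where the reference amplitude is below 1% of its maximum; repeats are
averaged complex-first (phase noise partially cancels), and the white-light
value is the trapezoid-integrated amplitude over a band.

# Numerical choices and degenerate inputs

* Momentum grid $10^{-5}$–$10$ nm$^{-1}$, 400 nodes; $z = 0$ rejected
  (divergent weight). Interfaces with $\epsilon_{j+1}+\epsilon_j = 0$
  raise a singular-interface error.
* Demodulation requires a power-of-two sample count $\geq 64$ and
  $n < N/2$.
* Segmentation with no pixel above threshold errors; single-label traces
  split into one epoch with a warning; empty illumination labels are
  dropped with a warning.
* The LM optimizer treats "no descent step and small gradient" as
  convergence, so exact-data fits terminate cleanly at machine precision.
* All generators are pure functions of (spec, seed); the RNG state of the
  caller is saved and restored.

# Known limitations

* The forward model is quasi-static: no retardation, no far-field factor,
  no tip-shape tomography. Its absolute harmonic amplitudes are not
  comparable to measured arb.units; only referenced quantities are
  meaningful.
* The sphere/disc profile uses a locally layered approximation; it ranks
  profile widths correctly but is not a quantitative scattering solution.
* Absolute area and circularity inherit small threshold- and
  smoothing-dependent biases (quantified above); state-to-state relative
  changes are the robust outputs.
* The synthetic noise model is i.i.d. Gaussian with optional linear drift;
  1/f noise, scan artifacts and topography crosstalk are out of scope.
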