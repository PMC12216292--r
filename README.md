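# nanoswitch

Analysis toolkit for **transient mid-infrared nanoscopy of photoswitchable
lipid vesicles** — scattering-type scanning near-field optical microscopy
(s-SNOM) performed through a thin SiN membrane on vesicles suspended in
D₂O, with azobenzene photolipids toggled between their *trans* and *cis*
states by 365/465 nm illumination.

The package is aimed at near-field microscopists and biophysicists who
need a tested, reusable pipeline for this class of experiment:

* **Forward model** — quasi-static finite dipole model of a spheroidal tip
  (tapping amplitude *a*, apex radius *r*, length *L*, empirical charge
  factor *g*) over a multilayer sample described by the transfer-matrix
  reflection coefficient β(q); momentum-weighted β_eff, harmonic
  demodulation σₙ = (1/2π)∮σ(H(θ))e^(−inθ)dθ of the tapping cycle, and
  referencing to silicon or D₂O. Includes a hanging-sphere vs
  flattened-disc lateral profile comparison.
* **Image analysis** — vesicle segmentation at the 1/e-of-maximum (or an
  absolute s₂) boundary criterion, sub-pixel iso-contour area/perimeter,
  circularity **4πA/p²**, Gaussian line-profile FWHM, and per-state
  switching series (Δarea, Δcircularity per transition).
* **Transient analysis** — epoch splitting by illumination label, moving
  averages, sigmoidal switching fits
  **f(t) = L/(1+e^(−(t−t_d)/τ)) + C**, plateau step statistics (SNR and
  two-sample significance z), and a detection-power study versus sampling
  time t_p with σ ∝ 1/√t_p noise.
* **nano-FTIR** — asymmetric-Michelson interferogram → complex spectrum
  (one-sided DFT, no Mertz correction), substrate referencing, complex
  averaging, nominal resolution 1/(2·scan length) bookkeeping.
* **Synthetic scenes** — seeded generators for vesicle images (flat-top
  discs with ~100 nm fringes), trans/cis state pairs with exact analytic
  area/circularity factors, boxcar-convolved switching traces, and
  interferograms — each with a ground-truth record so every estimator is
  tested closed-loop.

## Worked example

```r
library(nanoswitch)

## referenced near-field spectrum of a lipid film under 10 nm SiN, vs silicon
tip  <- tip_model()                        # a = 80 nm, r = 60 nm, L = 300 nm, g = 0.7 e^{i 0.06}
mats <- builtin_materials()
stk  <- function(m) layer_stack(layer(1), layer(mats$sin, 10), layer(m))
normalized_spectrum(tip, stk(mats$lipid_trans), stk(mats$si),
                    c(1603, 1740), reference_label = "si")
#>   wavenumber   s_ratio phi_diff_deg
#> 1       1603 0.4246274     5.862722
#> 2       1740 0.4368082     9.275035
```

The amplitude ratio below 1 and the positive phase contrast at the
1603 cm⁻¹ azobenzene and 1740 cm⁻¹ carbonyl bands are the model's
prediction of lipid contrast against clean silicon.

```r
## segment a synthetic 660 nm vesicle and score its shape
sc  <- scene_spec(vesicles = data.frame(x = 640, y = 640, radius = 330,
         interior_phase = 28, interior_amplitude = 21.2, fringe_width = 100),
         background_amplitude = 0, background_phase = 10,
         noise_sigma = 0.5, seed = 7)
img <- render_image(sc)$image
segment_vesicle(img, seed_point = c(640, 640))
#> Segmentation: A = 3.573e+05 nm^2, p = 2119 nm, circularity 1.000 (threshold 7.88)
```

The disc scores circularity 1.000 under the 4πA/p² definition (the
threshold 7.88 is 1/e of the peak after background subtraction; the true
disc area is π·330² = 3.42e5 nm², the ~4% excess is the documented
1/e-level bias on the 100 nm fringe, which cancels in state-to-state
comparisons).

```r
## fit one switching epoch of a synthetic trace (8 epochs, t_p = 0.5 s)
tr  <- render_trace(trace_spec(seed = 7))$trace
ep  <- split_epochs(tr)
fit <- fit_sigmoid(ep[[2]], channel = "s2")
fit
#> Sigmoid fit (s2): L = 0.07663, t_d = 10.4 s, tau = 0.759 s, C = 0.9234 (rmse 0.00947)
#>   note: tau < 2 t_p (0.5 s); value is convolved with the sampling window
step_stats(ep[[2]], transition_time = fit$t_d,
           guard_interval = 3 * max(fit$tau, fit$t_p))
#> Step: amplitude +8.30% (SNR 7.87, 29.40 sigma), phase +1.63 deg (SNR 8.63, 35.52 sigma); n = 16/95
```

The generated epoch carried a +8% amplitude / +1.6° phase step with
t_d = 10.3 s and τ = 0.7 s; the fit recovers them within noise, and the
print method flags that τ of this order is convolved with the 0.5 s
sampling window (the true kinetics are at least this fast).

A command-line front end is installed at `inst/cli/nanoswitch`
(subcommands `simulate`, `forward`, `segment`, `series`, `fit-trace`,
`power`, `spectrum`, `plan`).

## Layout

```
R/                      forward-model.R, scene.R, image-analysis.R,
                        transient.R, nanoftir.R, io.R, cli.R, optim.R
tests/testthat/         unit + property suites, test-acceptance.R
scripts/acceptance.R    acceptance report (see above)
vignettes/              methods vignette (models, assumptions, choices)
inst/extdata/           editable material (Lorentz oscillator) table
inst/cli/nanoswitch     command-line entry point
```
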