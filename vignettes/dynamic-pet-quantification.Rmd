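---
title: "Quantifying irreversibly binding PET tracers: models, maps and repeatability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying irreversibly binding PET tracers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petkin)
```

## The problem

Radiolabelled HER2-targeting tracers (e.g. a ⁶⁸Ga-labelled Affibody molecule)
bind their receptor effectively irreversibly over the time scale of a PET
examination. Quantifying that binding in liver metastases is complicated by
the liver itself: hepatic tracer delivery is very high (K1 up to
~0.56 mL/cm³/min), so static uptake images show a bright liver background
that can hide or distort lesion reads. Kinetic analysis separates *delivery*
from *binding*: the net influx rate Ki reflects specific, irreversible uptake
and suppresses the non-specific background.

`petkin` implements the full quantification chain for a 45-min abdominal
dynamic acquisition (22 frames: 6×10 s, 3×20 s, 3×60 s, 5×180 s, 5×300 s):
compartment-model fitting of time–activity curves (TACs), Patlak graphical
analysis, basis-function parametric imaging, image-derived input functions,
SUV quantification with Ki↔SUV cutoff calibration, and test–retest
repeatability statistics. Because no patient data accompany the package, a
synthetic phantom generator with known ground truth stands in for the scans;
every statistical claim a test makes is computed from that stated world.

## Models

All three standard plasma-input compartment models are available, each with a
fitted fractional blood volume Vb:

* **1TC** — single tissue compartment: `C_T(t) = K1 e^(−k2 t) ⊗ Cp(t)`
  (3 free parameters).
* **2TC-3k** — irreversible two-tissue model:
  `C_T(t) = K1/(k2+k3) [k3 + k2 e^(−(k2+k3)t)] ⊗ Cp(t)` (4 parameters).
* **2TC-4k** — reversible two-tissue model, the bi-exponential solution with
  eigenvalues derived from (k2, k3, k4) (5 parameters).

The measured signal is `(1−Vb)·C_T(t) + Vb·C_b(t)`. Aorta curves serve as
both `Cp` and `C_b` — the acquisition protocol provides no metabolite or
plasma-fraction correction, so whole blood equals plasma by convention here.
The net influx rate is `Ki = K1·k3/(k2+k3)` and the non-displaceable
distribution volume is `VND = K1/k2`.

Units everywhere: minutes, 1/min, mL/cm³/min for K1 and Ki, kBq/mL for
concentrations (decay-corrected to injection, so no half-life enters the
forward model).

### Numerical core

The input function is piecewise linear with `Cp(0) = 0`. Convolutions with
`e^(−θt)` are computed *analytically* per linear segment (compiled kernel),
together with the running time-integral of the convolution. Frame values are
therefore exact analytic averages of the model curve over each frame
interval — never midpoint samples, which would be visibly biased for the
10-second early frames. Near θ = 0 the segment moments switch to series
expansions, so the θ → 0 limit (pure trapping) is reached without
cancellation.

## Fitting and model selection

`fit_tac()` minimizes the weighted residual sum of squares with box bounds
(K1, k2, k3, k4 ∈ [0, 5], Vb ∈ [0, 0.5] — a generous physiologic envelope).
Defaults that matter:

* **Weights**: frame durations (longer frames collect more counts). The
  protocol source is silent on weighting; uniform weights are one flag away.
* **Multi-start**: 3 log-spaced values per rate constant and Vb ∈
  {0.03, 0.1} are screened by objective value; the best three starts are
  polished with a bounded quasi-Newton optimizer (`nlminb`, relative
  tolerance 1e−12). This protects against the k2/k3 trade-off's local minima.
* **Convergence flag**: a fit is converged only if no coordinate step of
  curvature-appropriate size decreases the objective materially (a projected
  stationarity check). A raw finite-difference gradient norm is *not* used:
  in the sharply curved valleys of misspecified models it is dominated by
  cancellation noise even at the true optimum.
* **AIC**: `n·ln(RSS/n) + 2p` (Gaussian constant dropped; plain AIC, not
  AICc, matching the analysis it reimplements). RSS below numerical noise is
  clamped to a common data-scaled floor so that zero-RSS fits tie and the
  fewest-parameter model wins — that is what makes "noise-free 1TC data
  selects 1TC" deterministic.

## Patlak analysis

`patlak_fit()` regresses `C(t)/Cp(t)` on `∫₀ᵗCp/Cp(t)` over frames with
mid-time ≥ t\* (default 15 min, i.e. the last five 5-min frames minus the
first; the choice is configurable and t\* ∈ {10, 15, 20} is worth reporting
in sensitivity analyses). Two properties deserve emphasis because they are
easy to mistake for bugs:

1. **What the slope estimates.** For a measured TAC
   `(1−Vb)C_T + Vb·C_b` the Patlak slope estimates `(1−Vb)·Ki`, not Ki —
   a ~5–12% attenuation at realistic blood volumes. Under the unscaled
   convention `C_T + Vb·C_b` the slope targets Ki exactly; the package
   supports both (`vb_scale` in `model_tac()`).
2. **The transient drift.** The Patlak intercept term decays toward its
   asymptote while the input tail is still changing; the residual slope bias
   scales roughly with the intercept-to-slope ratio `K1k2/θ² : Ki`. For
   HER2-positive-lesion kinetics (Ki ≳ 0.02 mL/cm³/min) the bias at
   t\* = 15 min is ≲ 1%; for liver-like kinetics (Ki = 0.015 with a 45-fold
   intercept-to-slope ratio) it is several percent and decays monotonically
   with t\*. This is the same physics that makes the Patlak liver Ki read
   ~30–50% below the compartmental value in clinical material, and it is why
   Patlak Ki images show *better* tumour-to-liver contrast: an accepted,
   fortunate artefact of assuming irreversibility in tissue that is not.
   With truly reversible kinetics (k4 > 0) the slope drops further below Ki
   and the intercept (Ve) inflates.

The intercept Ve is reported as fitted, without blood-volume subtraction.
Its irreversible-kinetics asymptote is `K1k2/(k2+k3)² + Vb`, which exceeds
VND only when k3 ≪ k2 (liver); for lesions with k3 comparable to k2 it falls
below VND — the familiar "Ve includes blood volume, VND does not" comparison
is a statement about liver-like kinetics.

## Parametric imaging

`parametric_maps()` produces voxel-wise K1, Ki, Vb, VND (basis-function
irreversible 2TC) and Patlak Ki, Ve maps. The basis method linearizes the
2TC-3k model over a grid of θ = k2+k3 (default 64 log-spaced values in
[0.006, 3] 1/min, spanning the kinetics implied by reported liver/lesion
values with margin): for each θ the model is linear in
(Vb, Ki, K1k2/θ) with non-negative coefficients. Design choices:

* **Non-negativity** by exact small-support enumeration (the optimum of a
  3-column NNLS lies on a face, where it is the unconstrained least-squares
  solution of its support); negative Vb or Ki are unphysical and destabilize
  θ selection.
* **Vectorization**: one normal-equation solve per (θ, support) pair covers
  every voxel simultaneously, so a 64×64×32 study fits in seconds.
* **The (1−Vb) convention**: the linear solve uses `C = Vb·C_b + tissue`
  and by default reports coefficients *without* the (1−Vb) correction,
  because the source analysis does not state its convention. This changes K1
  and Ki by ~5–10% (exactly the factor 1−Vb); `vb_correction = TRUE` applies
  it. VOI-level NLLS always uses the (1−Vb)-scaled convention, so parametric
  and VOI values agree up to that documented factor.
* **Masking**: voxels whose duration-weighted time-summed activity exceeds
  1% of the image maximum; no spatial smoothing is applied before fitting
  (reconstruction already filters the data; an optional pre-smoothing flag is
  out of scope here).

## Quantification and contrast

`extract_idif()` implements the aorta rule: segment at the frame where the
first pass peaks (ties → earlier frame; a last-frame peak raises a
suspicious-timing warning), then keep labelled voxels ≥ 50% of that frame's
label maximum to counteract partial volume at vessel edges.
`compute_suv()` is the definitional `conc × weight / injected activity`,
invariant to any decay-correction convention shared by image and activity.
`calibrate_cutoff()` regresses lesion Ki on lesion SUVmean and converts a
reference SUV (default 6.0) into a Ki cutoff with a 95% CI propagated from
the coefficient covariance (the covariance-free variant is a flag; the
covariance-aware formula reduces to it when the covariance vanishes).

## Repeatability

`bland_altman()` uses relative within-pair differences
`d = (retest − test)/mean × 100%`; `repeatability_coefficient()` defaults to
`RC% = 1.96·√(mean d²)` — algebraically the `1.96·√2·wCV` form with the √2
absorbed by using paired differences directly. The `sd` and log-ratio wCV
estimators are available behind one flag and agree to first order at small
wCV; reports name the convention used. `deming_fit()` is errors-in-variables
regression with λ = 1 (the same instrument measures both visits), immune to
the attenuation that biases OLS slopes below 1 in test–retest scatter.

## The synthetic world

`make_phantom()` generates what the pipeline would otherwise read from disk:

* geometry: 64×64×32 voxels of 3.9×3.9×3.27 mm (the reported reconstruction
  grid), a liver block, an aorta cylinder (pure blood, 2 cm diameter), and
  12 spherical lesions with diameters 8–40 mm (down to sub-resolution);
* kinetics: liver K1 = 0.37, Ki = 0.015 (k2 = 0.5 chosen so the reported
  median K1/Ki pair is reproduced; an optional small liver k4 emulates the
  reversible component discussed for hepatic tissue); lesions span
  K1 0.05–0.38 and Ki 0.009–0.095 — the reported lesion ranges;
* input: a Feng-type tri-exponential-with-linear-rise curve with the classic
  parameter set (peak ~75 kBq/mL at ~0.75 min for a ~240 MBq injection),
  scaled linearly with dose;
* noise: independent Gaussian per voxel and frame with variance
  `noise_scale² · C/Δt`; the default `noise_scale = 1.5` gives ~15% voxel CV
  in late liver frames, typical of filtered dynamic reconstructions. VOI-level
  simulations use 0.3 (a ~20-voxel lesion average);
* statics: model concentrations at 120 and 240 min converted to SUV with
  241 MBq / 70 kg metadata.

What the phantom deliberately does **not** emulate: scanner resolution
(no point-spread blurring by default), motion, scatter/randoms structure,
partial-volume spill-over, and anatomical realism. A green end-to-end test
therefore establishes the *mathematical* consistency of the chain —
generation, IDIF, fitting, mapping, statistics — not robustness to
reconstruction physics. Sub-resolution lesions degrade accordingly and no
partial-volume correction is attempted.

`make_test_retest()` jitters each lesion's Ki by an independent lognormal
factor (re-deriving k3 so K1 and k2 are untouched) with independent noise
seeds; `simulate_retest_pairs()` is the lightweight counterpart for
statistical closure: a 10.8% within-subject CV yields RC ≈ 1.96·√2·10.8 ≈
30%.

## Reproducibility

Every stochastic step is seeded; identical seeds give bit-identical phantoms,
maps and tables. `run_study()` writes its resolved configuration and a log
beside the outputs; `run_demo()` is the one-command reduced study. The
command-line entry points in `scripts/` are thin wrappers over these
functions.

## Known limitations

* No NIfTI/DICOM I/O in this environment: images live as in-memory arrays
  with voxel geometry; tables, configs and manifests serialize to CSV/JSON.
* No dispersion/delay or metabolite correction of the input function.
* No motion correction, no partial-volume correction, no reversible-model
  (2TC-4k) parametric images.
* The Patlak t\* of the original analysis is unknown; 15 min is the package
  default and the sensitivity to {10, 15, 20} is one argument away.
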