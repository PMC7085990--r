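# petkin

Kinetic quantification for dynamic PET with irreversibly binding tracers —
compartment models, Patlak graphical analysis, basis-function parametric
imaging, SUV cutoff calibration, and test–retest repeatability statistics,
plus a synthetic phantom generator with known ground truth.

## Why

HER2-targeting tracers (e.g. ⁶⁸Ga-labelled Affibody molecules) bind their
receptor essentially irreversibly, so the net influx rate

&nbsp;&nbsp;&nbsp;&nbsp;**Ki = K1·k3 / (k2 + k3)** &nbsp;(mL/cm³/min)

quantifies specific binding while suppressing the high non-specific liver
background that dominates static SUV images (SUV = concentration ×
body weight / injected activity). `petkin` implements the whole chain for a
45-min abdominal dynamic acquisition (22 frames: 6×10, 3×20, 3×60, 5×180,
5×300 s):

* **kinetics core** — 1TC, irreversible 2TC-3k and reversible 2TC-4k
  compartment models with a fitted blood-volume term, driven by exact
  analytic convolution of a piecewise-linear input (compiled kernel), with
  exact frame-interval averaging;
* **model fitting** — weighted multi-start non-linear least squares with
  parameter standard errors and Akaike model selection
  (`AIC = n·ln(RSS/n) + 2p`);
* **Patlak analysis** — `C(t)/Cp(t)` vs `∫Cp/Cp(t)` regression past a
  configurable t* (default 15 min): slope → Ki, intercept → Ve;
* **parametric imaging** — voxel-wise basis-function 2TC-3k maps (K1, Ki,
  Vb, VND = K1/k2) and Patlak maps (Ki, Ve), fully vectorized over voxels;
* **quantification** — image-derived input function from the aorta
  (peak-frame rule + 50% threshold refinement), SUV, tumour-to-normal
  ratios, and Ki↔SUV cutoff calibration with covariance-aware 95% CIs;
* **repeatability** — Bland–Altman, relative repeatability coefficient
  (RC% = 1.96·√(mean d²), conventions selectable), Deming regression;
* **synthetic data** — seeded dynamic phantoms (liver / aorta / 12 spherical
  lesions spanning the reported kinetic ranges) with frame-duration-dependent
  noise, static SUV volumes, ground-truth maps, and test–retest pairs.

## Worked example

```r
library(petkin)

cp <- make_input_function()            # Feng-type arterial curve, kBq/mL
fs <- dynamic_schedule_45min()         # 22 frames over 45 min

truth <- kinetic_params(K1 = 0.2, k2 = 0.5, k3 = 0.07, vb = 0.05)
tac <- model_tac(truth, "2TC-3k", cp, fs)   # noise-free lesion TAC

fit_tac(tac, cp, "2TC-3k")
#> 2TC-3k fit: RSS = 2.425e-19, AIC = -449.8, converged = TRUE
#> K1 = 0.2 mL/cm^3/min, k2 = 0.5, k3 = 0.07, k4 = 0 1/min, Vb = 0.05 (Ki = 0.02456)

patlak_fit(tac, cp, t_star = 15)
#> Patlak: Ki = 0.02309 mL/cm^3/min, Ve = 0.3638 mL/cm^3 (t* = 15 min, R^2 = 1.0000, 7 frames)
```

The fit recovers the generating parameters exactly (Ki = 0.02456 =
0.2·0.07/0.57). The Patlak slope reads ~6% lower: the measured TAC is
(1−Vb)·C_T + Vb·C_b, so the slope estimates (1−Vb)·Ki with a further ~1%
transient drift — see the methods vignette for why that same physics improves
Patlak tumour-to-liver contrast in real studies.

A one-command reduced study (phantom → IDIF → VOI fits → parametric maps →
SUV/contrast → cutoff):

```r
res <- run_demo(outdir = tempfile(), seed = 1)
res$cutoff$tc2
#> Ki cutoff at SUV 6: 0.01136 mL/cm^3/min (95% CI 0.01076-0.01196)
#>   Ki = 0.002051 * SUV + -0.0009446 (R^2 = 0.999, n = 6); SUV CI 5.71-6.29
```

i.e. across this phantom's six lesions, a static SUVmean of 6 corresponds to
a basis-function Ki of ~0.011 mL/cm³/min, with the CI propagated from the
regression coefficient covariance. The same pipeline is scriptable:

```sh
Rscript scripts/pipeline.R demo  --out out/ --seed 1
Rscript scripts/pipeline.R study --out out/ --seed 1 --noise 1.5 --tstar 15
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the installed package's main computation end-to-end — phantom
generation, IDIF extraction, VOI compartment fits with AIC selection, all six
parametric maps, SUV/contrast tables and cutoff calibration — under the given
seed, and writes the JSON report to `--out`.

## Layout

```
R/                  implementation (kinetics, fitting, Patlak, parametric,
                    quantification, repeatability, synthetic data, pipeline)
src/                analytic convolution kernel (Rcpp)
tests/testthat/     unit, property and acceptance suites
scripts/            acceptance.R, pipeline.R (thin CLI wrappers)
vignettes/          methods vignette (model conventions, design choices)
```
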