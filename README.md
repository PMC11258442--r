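# outflowr

Aqueous humor dynamics from multi-step ocular perfusion experiments.

## What this is for

The conventional outflow pathway (trabecular meshwork and Schlemm's canal)
drains most of the aqueous humor from the eye and thereby sets intraocular
pressure (IOP); its hydraulic conductance — the **outflow facility** — is
the key functional readout in studies of IOP regulation, aging and
glaucoma risk. In mice, facility is measured by perfusing enucleated eyes
over a staircase of reservoir pressures (4.5–21 mmHg) while recording the
inflow required to hold each pressure.

`outflowr` is for researchers running or modelling such experiments. It
implements:

* **Trace processing** — Savitzky–Golay filtering, slope-based
  steady-state detection (stable when the flow slope stays under
  3 nL/min/min for a minute), and extraction of per-step steady-state
  (P, Q) points averaged over 4 min.
* **Facility fitting** — the power-law pressure–flow model
  `Q = C_r (P / P_rC)^beta · P` fitted in the log domain (where it is
  exactly linear), giving the reference facility `C_r` at `P_rC = 8` mmHg
  and the nonlinearity factor `beta` with 95% CIs.
* **Compliance estimation** — per-step ocular compliance by volume
  balance over each pressure-step transient, then the model
  `phi(P) = phi_r (P_rphi + gamma) / (P + gamma)` fitted by bounded
  nonlinear least squares (`phi_r` at `P_rphi = 13` mmHg).
* **Eye-size adjustment** — the diameter growth model
  `d = a1 · Age^a2 + a3`, diameter imputation, and adjustment of facility
  (`× d̄/d`) and compliance (`× (d̄/d)³`) to the 3.4-mm reference eye.
* **Cohort statistics** — per-age-group 2.5-MAD outlier screening in the
  log domain (accounting for each estimate's CI), interocular
  correlation, bilateral averaging with quadrature CIs, and OLS age
  regressions with Bonferroni correction (`p_B = 3p`).
* **Pressure responses** — relative Schlemm's canal area vs IOP with a
  fixed 100% intercept, iridocorneal angles from image segments under
  anisotropic pixel scales, the angle–pressure log law
  `theta − theta0 = zeta · ln(P − P0)`, and the normalized SC-area
  discrepancy `delta_nSCLA`.
* **A forward simulator** — pressure source + series resistance + eye
  (power-law outflow, pressure-dependent compliance) integrated as an
  ODE with an exact volume ledger, plus a synthetic cohort generator
  with realistic age trends, log-normal parameter scatter and correlated
  fellow eyes, so every estimator is validated by parameter recovery.

## A worked example

```r
library(outflowr)

params <- true_eye_params(Cr = 5, beta = 0.5, phir = 80, gamma = 5)
trace  <- simulate_perfusion_trace(params, perfusion_protocol(),
                                   noise_model(0, 0))
fit <- fit_eye(trace)

fit$facility
#> Outflow facility fit (n = 9, Pr_C = 8 mmHg)
#>   Cr   = 5.000 nL/min/mmHg  [5.000, 5.000]
#>   beta = 0.500             [0.500, 0.500]

fit$compliance
#> Ocular compliance fit (n = 8, Pr_phi = 13 mmHg)
#>   phir  = 80.39 nL/mmHg  [80.30, 80.49]
#>   gamma = 5.06 mmHg
```

The facility fit returns the truth exactly on noise-free data because the
model is log-linear; the compliance estimate lands within half a percent
of the simulated truth (80 nL/mmHg), the residual coming from assigning
each step's volume-balance estimate to its midpoint pressure.

A whole synthetic aging study, end to end:

```r
res <- run_ahd_pipeline(cohort_config(n_animals = 60, seed = 1))
res$regressions$beta
#> Age regression (n = 55)
#>   slope = -0.029 [-0.03657, -0.02136] per month, R^2 = 0.52,
#>   p = 4.27e-10, p_B = 1.28e-09
```

Here 60 animals (120 eyes) were simulated with the default trends, each
trace was processed and fitted, eyes were screened for outliers, fellow
eyes averaged, and the nonlinearity factor regressed on age: the recovered
decline of −0.029 per month sits inside the CI of the configured
−0.027 per month, with β reaching zero in the oldest animals.

## Documentation

The methods vignette (`vignettes/aqueous-humor-dynamics.Rmd`) describes
the models, the stability criteria, the simulator circuit, every generator
default and its rationale, numerical edge cases, and known limitations.
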