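# lvstiff

Non-invasive, model-based estimation of passive left-ventricular (LV)
myocardial stiffness. The package is aimed at cardiac-modelling researchers
who want a fully testable, desk-scale implementation of the volume-driven
diastolic estimation pipeline: personalised (here: idealized synthetic) LV
geometry, an incompressible hyperelastic finite-element model of diastolic
filling, and stiffness estimation by parameter sweeps with a non-invasive
pressure rescaling.

## The model in brief

The myocardium is incompressible and hyperelastic with the reduced
transversely isotropic exponential law

    Psi = a/(2b) (exp(b (II_F - 3)) - 1) + a_f/(2 b_f) (exp(b_f (II_Ff - 1)^2) - 1)

with isotropic scale `a` (Pa), fibre scale `a_f` (Pa) along a rule-based
fibre field (helix angle +theta to -theta across the wall), and fixed
exponents `b = b_f = 5`. Diastolic simulations are driven by the
cavity-volume trace through a scalar Lagrange multiplier `lambda_l` (the
model's filling pressure), with relaxed data-tracking boundary conditions on
the base and, optionally, over the RV attachment region of the epicardium
(weight field `H`). Displacement-only, volume-driven data identify only the
ratio `gamma = a/a_f`, which is estimated by sweeping forward simulations
against the data with the relative L2 displacement error

    J = sqrt( sum_n ||u_n - u_d,n||^2 / sum_n ||u_d,n||^2 ).

Absolute stiffness follows by rescaling with the estimated end-diastolic
pressure (Nagueh surrogate, `EDP = 1.24 E/Ea + 1.9` mmHg):
`a_f = 1000 * EDP / lambda_l^ED`, `a = gamma * a_f`.

Everything is exercised on synthetic subjects with known ground truth
(healthy-volunteer and dilated-cardiomyopathy presets anchored on published
group-level LV indices), so parameter recovery, identifiability and the
group contrast are verifiable end to end. See the methods vignette
(`vignettes/passive-stiffness-methods.Rmd`) for the full model description
and numerical choices.

## Worked example

```r
library(lvstiff)

# a synthetic healthy subject: idealized mesh, fibres, forward-simulated
# diastole at known gamma* = 0.5, EDP surrogate attached
subj <- generate_subject(subject_preset("volunteer", n_frames = 6),
                         seed = 1, nc = 14, nl = 6, ns = 1)
unlist(subj$truth[c("gamma", "a", "a_f", "edp_mmhg")])
#>    gamma        a      a_f edp_mmhg
#>      0.5    322.9    645.8     11.4

# estimate gamma by sweeping an 8-point grid, then refine near the minimum
sw <- refine_sweep(parameter_sweep(subj, lv_gamma_grid(8), warm_start = TRUE),
                   n_extra = 4)
c(gamma_hat = sw$gamma_hat, J_min = sw$J_min,
  a_Pa = sw$a_Pa, a_f_Pa = sw$a_f_Pa)
#> gamma_hat     J_min      a_Pa    a_f_Pa
#>  0.494286  0.001451  321.2329  649.8932
```

The estimate lands within one refined grid step of the ground-truth ratio
(the 0.494 grid value sits 1% from 0.5), the objective at the minimum is
at the grid-resolution floor (evaluating at the exact truth gives J below
1e-3: the forward and inverse problems are consistent by construction), and
the EDP rescaling recovers the absolute parameters to better than 1%. With
0.5 mm Gaussian tracking noise (`add_displacement_noise`) the recovered
ratio is unchanged here while the error floor rises to J_min ~ 0.13.

The numbered scripts under `analysis/` run the full study — subject
generation, recovery sweeps, the fibre-angle/boundary-condition/reference-
frame sensitivity table, and the clinical-metric group comparison — writing
tables, JSON summaries and a J-vs-gamma figure under `results/`:

```sh
Rscript analysis/01_generate_subjects.R
Rscript analysis/02_parameter_recovery.R
Rscript analysis/03_sensitivity.R
Rscript analysis/04_clinical_metrics.R
```

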