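---
title: "Estimating passive left-ventricular stiffness from volume-driven diastolic models"
author: "lvstiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating passive left-ventricular stiffness from volume-driven diastolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Passive myocardial stiffness — how strongly the relaxed ventricular wall
resists being stretched during diastolic filling — changes with disease, and
in dilated cardiomyopathy (DCM) it is expected to rise with the structural
remodelling of the tissue. Measuring it directly would require invasive
pressure instrumentation and excised-tissue testing. This package implements
a non-invasive, model-based route: a personalised finite-element model of the
left ventricle (LV) is driven through diastole by the cavity-volume trace
extracted from images, and the stiffness parameters of its constitutive law
are chosen so that the simulated wall motion best matches the motion data.
The absolute pressure scale, which volume-driven displacement data cannot
see, is restored afterwards from a non-invasive estimate of end-diastolic
pressure (EDP).

Because no patient images ship with the package, a synthetic-data module
generates complete subjects — idealized geometry, fibre field, forward-
simulated motion with known ground-truth stiffness, a tagged-MRI-like noise
model and an EDP surrogate — so every stage of the pipeline can be verified
end to end: parameter recovery, identifiability behaviour, boundary-condition
and fibre-angle sensitivity, and the clinical-metric group contrast.

## Mechanical model

The myocardium occupies a reference domain $\Omega_0$ (the end-systolic
frame, taken as stress-free) and deforms with displacement $\mathbf u$,
deformation gradient $\mathbf F = \nabla_X \mathbf u + \mathbf I$,
$J = \det \mathbf F$. The tissue is hyperelastic, incompressible and
transversely isotropic about the local fibre direction $\mathbf f_0$, with
the reduced exponential (Holzapfel–Ogden type) strain energy

$$\Psi = \frac{a}{2b}\left(e^{b(I\!I_F - 3)} - 1\right)
      + \frac{a_f}{2b_f}\left(e^{b_f(I\!I_{Ff} - 1)^2} - 1\right),
\qquad I\!I_F = \mathbf F : \mathbf F,\quad
I\!I_{Ff} = \mathbf F\mathbf f_0 \cdot \mathbf F \mathbf f_0 .$$

`a` (Pa) scales the isotropic response, `a_f` (Pa) the extra stiffness along
fibres; the exponents are fixed at $b = b_f = 5$ (they are not estimated —
fixing them keeps the remaining scales comparable across subjects). The
total potential is

$$\Pi(\mathbf u, p, \lambda) = \int_{\Omega_0}\!\Psi + p\,(J-1)\,dV
  \;-\; \lambda_\ell\,\big(V_{\rm cav}(\mathbf u) - V_{\rm data}\big)
  \;+\; \Pi^b_{\rm ext} + \Pi^e_{\rm ext},$$

whose saddle points are the quasi-static equilibria. The scalar multiplier
$\lambda_\ell$ enforces that the mesh lumen volume equals the data-derived
cavity volume at every frame; physically it *is* the endocardial filling
pressure, and its end-diastolic value $\lambda_\ell^{ED}$ anchors the
pressure rescaling below.

### Boundary conditions

Two relaxed data-tracking terms of the form
$\int_\Gamma \boldsymbol\lambda\cdot\big((\mathbf u-\mathbf u_d)H -
\tfrac{\epsilon}{2}\boldsymbol\lambda\big)\,dA$ complete the model:

* **Base**: the truncated basal plane softly follows the data displacement
  ($H \equiv 1$), relaxation $\epsilon_b = 5\times10^{-6}$ m/Pa. A much
  stiffer tie (e.g. $5\times10^{-8}$) behaves like a hard clamp and
  re-creates the basal stress peaks that a relaxed condition exists to
  avoid — in our experiments it produced a non-converging pointwise
  incompressibility defect concentrated at the basal corner, which is why
  the moderate value is the default.
* **Epicardium**: either traction-free (`NT`) or, in `RV` mode, relaxed
  tracking of the data over the right-ventricular attachment region, encoded
  by a smooth azimuthal weight $H \in [0,1]$ (cosine ramp; centre at the
  septal direction, half-width 60°, transition 15° by default — the
  anatomical extent is a documented package choice, the source protocol
  never quantifies it). Relaxation $\epsilon_e = 5\times10^{-6}$ m/Pa, the
  moderate of the three values examined in the source analysis.

The relaxation parameters are specified *at the reference fibre stiffness*
of 1000 Pa and scale inversely with the material scale. This preserves
exactly the linear-dependence property of the law — jointly scaling
$(a, a_f)$ leaves displacements unchanged and scales every pressure-like
quantity proportionally — on which the EDP rescaling rests. With a fixed
absolute $\epsilon$ the boundary springs would break that exactness.

### Fibres and geometry

Rule-based fibre architecture: the helix angle varies linearly from
$+\theta$ on the endocardium to $-\theta$ on the epicardium across a
normalized transmural coordinate (distance ratio
$d_{\rm endo}/(d_{\rm endo}+d_{\rm epi})$, exact on concentric shells). At
the apex the circumferential direction degenerates; the local basis falls
back to the azimuth of a fixed off-axis reference node — an arbitrary but
rotation-equivariant choice that keeps the field finite and unit-norm. Default
$\theta = 60°$; the sensitivity study sweeps $\{50°, 60°, 70°\}$.

Idealized geometry: a truncated prolate ellipsoid wall (long axis $+z$,
apex at $-z$, flat base), parameterized by endocardial semi-axes, equatorial
and apical wall thickness, and the retained long-axis fraction
$\tau$ (default 0.75; the source meshes are "truncated at the base" without
a stated height, so this is a documented guess). Meshes are built by
splitting the prisms of an extruded surface triangulation into conforming
tetrahedra (smallest-global-vertex diagonal rule), with quadratic
interpolation nodes at edge midpoints (subparametric, straight edges).

### Discretization and solver

Taylor–Hood-type mixed elements: quadratic displacement, linear pressure;
surface multipliers are quadratic nodal fields on the boundary triangles and
the endocardial multiplier is the single scalar $\lambda_\ell$. Quadrature:
a 14-point degree-5 rule on tetrahedra, 6-point degree-4 on triangles. The
cavity volume is computed exactly (divergence theorem) over the deformed,
sub-triangulated endocardial surface closed by a fan to the centroid of the
basal endocardial ring, and is differentiated analytically for the
constraint Jacobian.

Each frame is one Newton solve of the full saddle system (relative residual
$10^{-8}$ in a dimensionless block-scaled norm, absolute $10^{-9}$), with
backtracking line search guarded by $J > 0$ and bisection of the volume
increment (up to 8 levels) on divergence; a secant predictor extrapolates
the state along the volume trace. The relaxed surface multipliers are
condensed exactly into the displacement block (their stationarity ties them
algebraically to the displacement mismatch; the epicardial relaxation term
uses a diagonally-scaled lumped surface mass so the condensation stays
sparse), and the remaining system is factorized by a supernodal Cholesky of
the displacement block plus a small dense, equilibrated Schur complement
over the pressure and volume constraints, with iterative refinement and a
sparse-LU fallback.

Two numerical choices deserve emphasis:

* **Quasi-incompressibility augmentation.** The weak (P1-pressure)
  incompressibility constraint leaves pointwise volume errors at quadrature
  points that decay only slowly with mesh size at coarse desk-scale
  resolutions. A penalty $\tfrac{\kappa}{2}(J-1)^2$ with
  $\kappa = 3000 \times \max(a_f, a)$ augments the multiplier and keeps
  $|J - 1|$ at the $10^{-2}$ level on the meshes used here. $\kappa$ scales
  with the material, so the joint-scaling property remains exact. Larger
  $\kappa$ is counterproductive: the displacement-block condition number
  reaches $10^{15}$ and the linear solves lose the accuracy Newton needs.
* **Incompressibility tolerance.** The package's working tolerance for
  pointwise $|\det F - 1|$ is $10^{-2}$ at every quadrature point of every
  converged frame; it is met on the preset subjects at the resolutions the
  tests use, and decreases with refinement.

## Estimation

With volume-driven simulations and displacement-only observations the two
stiffness scales are not separately identifiable: scaling $(a, a_f)$ jointly
rescales $\lambda_\ell(t)$ but leaves $\mathbf u$ unchanged. The search is
therefore restricted to the ratio $\gamma = a/a_f$. For each $\gamma$ on a
grid (default: 23 linear values on $[0.3, 2]$) a forward simulation at
$a = \gamma\,a_f^{\rm sim}$, $a_f^{\rm sim} = 1000$ Pa is scored by the
relative $L^2(\Omega_0)$ displacement error accumulated over the diastolic
frames,

$$\mathcal J = \left(\frac{\sum_n \lVert \mathbf u^n -
\mathbf u_d^n\rVert^2}{\sum_n \lVert \mathbf u_d^n\rVert^2}\right)^{1/2},$$

computed through the displacement mass matrix. The grid minimiser (ties
broken towards smaller $\gamma$; failed runs scored $+\infty$) can be
refined by adding values within one coarse step of the estimate. Absolute
stiffness follows by matching the simulated end-diastolic pressure to the
estimated one:

$$a_f = a_f^{\rm sim}\,\frac{\rm EDP^{est}}{\lambda_\ell^{ED}},\qquad
a = \gamma\,a_f,$$

with EDP estimated non-invasively from the mitral velocity ratio,
${\rm EDP^{est}} = 1.24\,(E/E_a) + 1.9$ mmHg (the left-hand side of the
printed surrogate formula is read as the pressure estimate, the only
dimensionally coherent interpretation). Identifiability is characterized by
the shape of $\mathcal J(\gamma)$: its minimum value, the max–min
variation, a second-difference curvature at the minimiser (reporting only,
never selection), and a unique-strict-minimum flag.

The sensitivity study repeats the sweep over fibre angles, epicardial
boundary modes, and reference frames. Reference-frame variants rebuild the
reference configuration from the chosen data frame directly (no unloading is
attempted); objective values and ratio estimates are min–max normalized
across the fibre angles of each case for comparability.

## Synthetic subjects

The generator emulates the statistical structure the analysis assumes,
with group presets anchored on the reference cohort's group means:

| preset | ESV (ml) | EDV (ml) | EDP (mmHg) | LA/SA | wall (mm, ES) | deformation |
|---|---|---|---|---|---|---|
| volunteer | 55 | 119 | 11.4 | 1.45 | 10 | larger (EF ≈ 0.54) |
| dcm | 86 | 152 | 15.2 | 1.22 | 9.5 | smaller (EF ≈ 0.43), dilated/sphericalized |

Geometry is solved analytically so the truncated-ellipsoid cavity matches
the preset ESV and LA/SA ratio. The volume trace is a smooth, strictly
increasing two-phase curve (early filling, diastasis, late filling) with
exact endpoints. Basal data prescribe a modest longitudinal lift (4 mm
volunteer / 2.5 mm DCM at end diastole); in RV mode the epicardial data add
a 1.5 mm septal-band inward displacement emulating the push of the filling
right ventricle. The forward solution at the ground-truth ratio
$\gamma^\ast$ becomes the full-field motion data; the *prescribed* surface
targets are stored as the subject's boundary data. Storing the targets
actually used in generation (rather than re-deriving them from the solution
trace) keeps the inverse problem exactly consistent with the forward one —
at $\gamma^\ast$ the truth is an equilibrium of the estimation problem and
$\mathcal J(\gamma^\ast)$ vanishes to solver tolerance, which is the
property the recovery tests verify.

The absolute scale is calibrated through the exact scaling property: after
one forward pass at $a_f^{\rm sim} = 1000$ Pa, the truth is defined as
$a_f^\ast = 1000\cdot{\rm EDP}^{\rm preset}/\lambda_\ell^{ED}$, so the true
model EDP equals the preset EDP exactly and the stored $E/E_a$ pair inverts
the surrogate formula at $E_a = 0.1$ m/s. Tracking noise is iid Gaussian
per node, component and frame (default $\sigma = 0.5$ mm, motivated by a
tagged-MRI reconstructed resolution of about 1 mm), with the reference
frame left exact. A simplified wall-volume-conservation projection displaces
nodes along the transmural direction (scaled by the transmural coordinate,
so the endocardium — and hence the cavity trace — is untouched) by a single
per-frame factor until the deformed wall volume matches the reference
within 0.1%; corrections beyond 20% of the wall thickness are refused.

What the generator does *not* emulate: real tagged-MRI tracking error is
spatially correlated, not iid; real geometries are not ellipsoids and their
fibres not circumferentially symmetric; the reference frame in vivo is not
stress-free; and the "measured" boundary data here are self-consistent with
the model's own boundary terms. Passing recovery tests therefore
demonstrates correctness of the estimation machinery under the model's own
assumptions — an inverse-crime setting by design — not fidelity to clinical
data.

## Problem sizes and defaults

The analysis scripts and test suite run on meshes of roughly 150–900
tetrahedra (circumferential × longitudinal × transmural resolution 8×4×1 to
14×6×2, element size 5–8 mm) with 4–8 diastolic frames, chosen so a full
sweep completes in minutes on one core. These resolutions reproduce the
closed-form cavity volume to ~1%, keep the mean element quality above 0.6,
and — at transmural resolution 2 with the stronger penalty
($\kappa = 5000 \times a_f$) for the strongly inflating volunteer preset —
meet the pointwise incompressibility tolerance; estimates on finer meshes
move well within the recovery tolerances the tests assert. Reduced sweep
grids (3–8 points spanning $[0.3, 2]$, refined near the minimiser) are used
where only the minimiser location or curve ordering matters; the full
23-point grid remains the user-facing default.

## Known limitations

* Desk-scale meshes; no parallel assembly or solver.
* The apex fallback direction makes the fibre field discontinuous in a
  small neighbourhood of the apex singularity (bounded, unit-norm, but not
  smooth there).
* Diastole only, quasi-static, no viscoelasticity, no pericardial contact,
  no RV cavity pressure; the reference configuration is a data frame, not
  an estimated unloaded state.
* Identifiability diagnostics are grid-based; no gradient-based or adjoint
  optimization is provided.
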