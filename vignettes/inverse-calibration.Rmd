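---
title: "Group inverse calibration of tissue material parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group inverse calibration of tissue material parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calibfe)
```

## The calibration problem

Material parameters of phenomenological tissue models are not directly
measurable; they are identified by minimising the mismatch between a
forward model's prediction and an experiment performed on the same
specimen. When several specimens are available, a *group* calibration
minimises one objective aggregating all specimen-specific residuals and
yields a single shared parameter set that represents the cohort,
including its variability, rather than any one anatomy.

`calibfe` separates the problem into two objects. The *objective*
pairs each forward model with the observation of the same name
(`<specimen>.dat`), compares outputs to observations, and aggregates
across the group. The *optimisation manager* dispatches a minimiser
appropriate to the problem shape, tracks every objective evaluation,
and reports termination diagnostics, histories and confidence
intervals. Forward models implement one contract: a function from the
parameter vector to a scalar, a list, or an (x, y) curve — or a failure
sentinel.

## Objective construction

* **Curve comparison.** When model and experiment sample different
  abscissae, both are restricted to the overlap of their x-ranges and
  the sparser curve is linearly interpolated onto the grid of whichever
  curve has more samples inside the overlap (ties go to the
  experimental grid, preserving measured abscissae). No extrapolation
  is ever performed: values outside the jointly observed range have no
  experimental meaning for calibration.
* **Error forms.** Residuals are plain differences or relative errors;
  the relative normaliser is either the per-point experimental value or
  the specimen's maximum absolute experimental value. Per-point
  normalisation suits scalar stiffness data spread over a wide range;
  per-specimen-max suits curves and displacement lists that pass
  through zero, where per-point division would blow up.
* **Aggregation.** Scalar objectives use the root of the mean over
  contributing specimens of each specimen's mean-squared residual, so
  every specimen carries the same weight regardless of how many points
  it contributes. Functional objectives concatenate residual vectors in
  filename-sorted order, which makes the stacked residual deterministic
  whatever order the files were loaded in.
* **Failure policy.** A forward solve may fail (singular system,
  exponential overflow). Failure is data: the specimen is excluded from
  that evaluation and counted, and the objective is computed over the
  converged subset. Only if *every* model fails does the evaluation
  return a large finite penalty — $10^6$ times the last successful
  objective value ($10^6$ on a first evaluation) — so line searches
  retreat from pathological regions instead of crashing.

## Optimiser dispatch and termination

| parameters | objective | bounded | method |
|---|---|---|---|
| 1 | scalar | either | Brent |
| ≥ 2 | scalar | yes | L-BFGS-B |
| ≥ 2 | scalar | no | conjugate gradient |
| ≥ 2 | functional | yes | trust-region-reflective (bounded least squares) |
| ≥ 2 | functional | no | Levenberg–Marquardt |

A univariate functional objective has no cell and errors. A damped
Newton method with finite-difference derivatives is available by
explicit name (`method = "newton"`) for method comparisons but never
dispatched. The scalar methods run on `stats::optimize`/`stats::optim`;
both least-squares cells run on `minpack.lm::nls.lm`, whose box-bound
Levenberg–Marquardt variant serves as the bounded least-squares
backend.

Four termination criteria are reported: `objective_tol` (the scalar
objective fell below the absolute threshold `f_tol` — "normal
termination"), `parameter_tol`, `gradient_tol`, and `max_iterations`.
`f_tol` is checked at every evaluation by the tracking wrapper, which
interrupts the backend the moment the threshold is crossed; the other
criteria are the backends' native tests with `x_tol`/`g_tol` mapped
onto them. Case conventions for `f_tol` (0.1 RMS normalised difference
for the bone case; 5% of the largest observed load for the disc case;
0.01 for the interface case) are plain config values supplied by
`case_defaults()`, not hard-coded behaviour.

Numerical gradients are forward differences with step
`fd_step` × max(1, |parameter|); the step is taken as the actually
represented difference `(x + h) − x`, and probes at an active upper
bound switch to backward differences. All query points are projected
onto the feasible box before evaluation, because the material models
are only defined for positive parameters and some backends probe
marginally outside their bounds. Every evaluation — probes included —
is counted and, when history is on, recorded as one row (the initial
point is row 0). Iteration counts are the backends' native notions
(`nls.lm` iterations; gradient evaluations for `optim`; evaluations for
Brent) and should be read as informative diagnostics, not a contract.

## Confidence intervals

At the optimum, the residual variance is $s^2 = \mathrm{SSR}/(n-p)$ and
the parameter covariance is $s^2 (J^\top J)^{-1}$ for functional
problems ($J$ the residual Jacobian) or $2 s^2 H^{-1}$ for scalar
objectives ($H$ the finite-difference objective Hessian). Intervals use
the Student-t quantile with $n - p$ degrees of freedom at the 95% level
by default. A perfect fit gives zero-width intervals; a numerically
singular curvature matrix raises an error naming the null-space
parameter combination instead of silently inverting it.

## The three built-in forward models

The models are deliberately desk-scale structural analogues that keep
each case's parameter-to-output character — linear-in-slope scalar,
nonlinear two-parameter curve, linear two-parameter list — while
solving in microseconds.

**Greyscale chain** (`bone_greyscale`). A chain of uniaxial elastic
elements with per-element modulus $E_i = \mathrm{slope} \times GS_i$,
$GS_i \in (0,1]$ normalised greyscales, loaded by a prescribed end
displacement; the output is reaction force over displacement (N/mm),
exactly linear in the slope. A zero-area element makes the assembled
system singular and exercises the failure path.

**GOH specimen** (`osteodisc_goh`). A homogeneous incompressible
uniaxial specimen ($\lambda_r = \lambda_z^{-1/2}$) with strain energy
$$\Psi = c_{10}(\bar I_1 - 3) + \frac{k_1}{2k_2}\sum_{\alpha=1,2}
\left[e^{k_2 \langle \bar E_\alpha \rangle^2} - 1\right],\qquad
\bar E_\alpha = \kappa(\bar I_1 - 3) + (1 - 3\kappa)(\bar I_{4\alpha} - 1),$$
two symmetric fibre families at ±θ to the loading axis and the Macaulay
bracket applied to the dispersed invariant so fibres stiffen in tension
only (the common GOH convention). Force is nominal stress × reference
area, i.e. $A_0\,d\Psi/d\lambda$ under incompressibility — which is
what makes a finite-difference differentiation of $\Psi$ an independent
oracle for the implemented analytic stress. Choosing homogeneous
kinematics over a meshed boundary-value problem is what buys that
closed form. The fixed constants default to $c_{10} = 0.1$ MPa,
$\kappa = 0.1$, $\theta = 30°$ — conventional annulus-scale values
chosen as fixture conventions, since the calibration treats them as
known. The compressibility coefficient is retained in the type for
interface completeness but unused under the incompressible kinematics.
`expm1` keeps the fibre term accurate down to $k_2 \to 0$, where it
tends continuously to the quadratic $k_1\langle\bar E\rangle^2$ limit;
an overflowing exponential returns a failed output.

**Interface lattice** (`interface_slice`). Concentric lamellae — arcs
of nodes over an angular sector, each with axial and transverse chord
springs so lamellae deform elastically rather than rigidly — joined
node-by-node by interface springs with stiffness $k_r$ on the relative
displacement along the local radial direction and $k_t$ along the local
tangential direction. The outer lamella is fixed; a tension is applied
to the inner lamella at 45° to the local radial direction, loading the
interfaces in a mix of opening and sliding. That obliquity matters: a
purely radial pull leaves the observed radial displacements almost
insensitive to $k_t$ (under 1% output change for a 10% parameter
change), which makes $k_t$ practically unidentifiable from noisy data;
at 45° the two sensitivities are of the same order. The observable is
the radial displacement at 8–16 tracked interlamellar nodes.

## The synthetic-experiment generator

`fixture_recipe()`/`generate_case()` fabricate paired model/observation
files with the statistical structure of the three studies:

* `bone_greyscale`: 22 specimens, multiplicative observation noise at
  CoV 0.47 (the high experimental variability of the emulated cohort);
  true slope 1500 MPa per greyscale unit, giving apparent stiffnesses
  of a few thousand N/mm as for small vertebral bodies.
* `osteodisc_goh`: 6 specimens, CoV 0.05 ("relatively low" variance,
  quantified here as 5% since no figure is reported); true
  $k_1 = 2$ MPa, $k_2 = 40$; displacement grids to 10% nominal strain.
* `interface_slice`: 3 specimens, CoV 0.05; true $k_r = 10$,
  $k_t = 5$ N/mm.

Structural variation between specimens (element counts, greyscale
fields, geometry, lamella counts, tracked-point sets) is drawn from
documented uniform ranges so the group problem is genuinely
multi-model. Noise is multiplicative lognormal with unit mean — it
keeps stiffnesses, loads and displacements positive, which an additive
Gaussian would not. Identical (recipe, seed) pairs reproduce
byte-identical files.

What the generator does *not* emulate: image acquisition and meshing,
3D continuum kinematics, contact, experimental artefacts such as drift
or misalignment, and any correlation between a specimen's geometry and
its noise. Passing the recovery tests therefore demonstrates that the
calibration machinery is correct and well-conditioned on models with
the right mathematical character — not that any particular tissue model
is valid for real data.

## Numerical choices and problem sizes

* Test and verification problems are deliberately small: chains of
  15–25 elements, 11-point force–displacement curves, lattices of 3–5
  lamellae × 8–12 nodes. The full test suite runs in well under a
  minute; the end-to-end acceptance run takes seconds.
* The univariate bone calibration is cross-checked against a dense grid
  search at $10^{-4}$ of the bound interval; noiseless recoveries are
  checked to 1e-6 (slope), 1e-2 ($k_1,k_2$) and 1e-3 ($k_r,k_t$)
  relative from ±50%-perturbed starts.
* History files are plain tab-separated text at 17 significant digits;
  `.dat` and model YAML files round-trip doubles exactly.
* Ties in the interpolation grid choice go to the experimental grid;
  equal-length curves therefore compare on measured abscissae.

## Limitations

Only local, gradient-based methods are interfaced; a poor initial guess
on a multimodal objective will find a local minimum (the bone and toy
problems here are unimodal; the GOH group objective is well-behaved in
the fixture ranges). No global optimisation, no robust/weighted losses,
no parallel evaluation of specimens within an objective call. The
scalar-objective covariance $2 s^2 H^{-1}$ uses the Hessian of the
*aggregated* objective and should be read as an approximation whose
quality degrades when specimen residuals are strongly heteroscedastic;
the functional (least-squares) route is preferred when a residual
vector is available.
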