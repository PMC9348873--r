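---
title: "Free-form inversion of polydisperse small-angle scattering: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-form inversion of polydisperse small-angle scattering: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysas)
```

## The forward model

A polydisperse small-angle scattering (SAS) sample is described by `N`
model-parameter distributions rather than scalars: for spheres a single radius
density `w(r)`, for cylinders four densities over length, radius and the two
orientation angles of the axis relative to the beam. Discretizing each
parameter `p_k` by `n_k` grid points and the scattering vector by one (1D
curve) or two (2D detector image) axes, the observable intensity is a
multi-linear contraction

    I[i1..iM] = xi * sum_{j1..jN} G[i1..iM, j1..jN] * prod_k w_k[j_k]  +  b(q),

where `G`, the *Green tensor of polydispersity*, holds the squared scattering
amplitude (the form factor) of every monodisperse sub-population at every
observation point. `xi` compounds the total volume fraction over the mean
particle volume with the squared scattering-length-density contrast; because
only the product is observable, `G` is built with unit contrast and `xi`
absorbs the absolute scale. `b` is the source background, either a flat level
or an isotropic power law `A q^-B`.

Everything instrument- or interaction-specific that acts linearly on the
intensity is folded into `G`:

* **Form factors.** Spheres use the Rayleigh amplitude
  `Phi(x) = 3(sin x - x cos x)/x^3` with `x = q r`; cylinders use the standard
  amplitude `v * sinc(q l cos(alpha)/2) * 2 J1(q r sin(alpha))/(q r sin(alpha))`,
  with `alpha` the angle between the in-plane scattering vector and the
  cylinder axis. The orientation convention — `theta` from the beam axis to
  the cylinder axis, `phi` the rotation of the axis projection in the detector
  plane — is a package choice, verified against an independent scalar oracle
  in the test suite, since conventions differ across codes.
* **Structure factor.** Non-dilute systems multiply `G` along the q axes by
  the Percus–Yevick hard-sphere `S(q; r_eff, V_f)` (the `G = P S`
  factorization). "Hard sphere" is realized as the closed-form
  Percus–Yevick solution; nothing else in the pipeline depends on that
  choice.
* **Resolution smearing.** A row-stochastic matrix `W` acts on the q axis;
  rows are Gaussians of per-point width `dq`, truncated at ±3 `dq` and
  renormalized. Smearing `G` and smearing the predicted intensity commute
  with the contraction, which the tests assert.
* **Volume weighting.** Dividing `G` entry-wise by the particle volume makes
  the inversion return the volume-weighted density directly.

## The inverse problem

Given observed means `mu` and standard deviations `sigma` (when an experiment
provides no `sigma`, the mean itself stands in, i.e. error proportional to
signal), the maximum-likelihood estimate minimizes the chi-squared misfit

    chi2 = sum ( (I_pred - mu) / sigma )^2

subject to each `w_k` lying on the probability simplex. Normalizing by
`sigma` both weights the data by its certainty and regularizes the decades of
dynamic range in a SAS curve.

### Slack reformulation

The simplex constraints are eliminated, not enforced: each density is
parametrized as `w_i = s_i^2 / sum_j s_j^2`. Any real slack vector decodes to
a feasible density, so **every** iterate of the optimizer is feasible by
construction, and the equality constraint of the classical "squared slack on
the unit sphere" formulation disappears (the norm of `s` is a pure gauge,
reset to 1 after each accepted step). The scale enters as `xi = t^2` and a
flat background is an unconstrained linear variable. This differs from the
equality-constrained trust-region treatment that inspired it in one respect
only: the constraint is removed by normalization rather than kept and handled
by a Byrd–Omojokun step, because no equality-constrained trust-region solver
of that class exists in the R ecosystem. The surface — feasible iterates,
monotone chi-squared, analytic Jacobian — is the same, and is what the tests
pin down.

### Automatic rescaling

Before solving, `mu` and `sigma` are divided by `max(mu)` and `G` by
`max(G)`. Sphere Green tensors contain `v^2 ~ r^6`, numerically ~1e17 for
500 Å particles, and raw intensities carry arbitrary instrument units;
without rescaling the optimizer's termination logic operates in a regime
where floating-point granularity, not information, decides. chi-squared is
invariant under the rescaling and the solution maps back exactly
(`xi = xi_s * c_I / c_G`, `b = b_s * c_I`). The tests assert bit-level
equality of solutions across twelve decades of input scale.

### Trust-region iteration

The solver is a damped Gauss–Newton (Levenberg–Marquardt) iteration on the
slack variables with the analytic Jacobian of the residual (verified against
central finite differences to 1e-6 in the suite). Steps solve the augmented
least-squares system `[J; sqrt(lambda) D^1/2] delta = [-r; 0]` with Marquardt
scaling `D = diag(J'J)`; rejected steps raise `lambda`, accepted steps lower
it, so chi-squared is non-increasing along accepted iterations. Defaults:
`max_iter = 500`, initial `lambda = 1e-3`, termination when an accepted step
reduces chi-squared by less than `ftol_abs = 1e-18` (the benchmarks live at
1e-13 and below, so the floor must sit far beneath them), when the relative
step falls below `xtol = 1e-14`, or when the gradient's infinity norm falls
below `gtol = 1e-14`.

### Conditionally-linear polish

On noise-free data the misfit surface near the optimum is a nearly flat
valley (the structural-ambiguity phenomenon), and a quasi-Newton iteration
creeps along it. The forward map, however, is *linear* in `u_k = xi * w_k`
jointly with the background once the other distributions are held fixed. The
solver therefore finishes with an exact convex step per distribution: the
weighted least-squares correction from the current iterate, computed by SVD
pseudo-inverse (relative cutoff 1e-12) after column equilibration — without
equilibration the background column `1/sigma`, which spans the data's dynamic
range, dominates the spectrum and hides the directions the residual lives in.
Because the correction is computed *from the current iterate*, only its
row-space component moves, preserving the implicit regularization that makes
free-form recovery land on the generating distribution rather than an
arbitrary member of the exact-fit family. When the unconstrained step exits
the non-negativity cone, the solver alternates projections between the
least-squares affine set (one reused SVD) and the cone — both convex, with
non-empty intersection on the recovery problems of interest — and keeps the
result only if chi-squared decreased. This stage is what carries the misfit
from the trust-region plateau (~1e-10) to the 1e-24..1e-28 the acceptance
suite demonstrates; it can be disabled with `polish = FALSE`.

### On-the-fly dimension reduction

Every `monitor_every = 10` accepted iterations the distributions are
recorded; a distribution whose successive records differ by less than
`reduce_tol = 1e-4` in L1 is declared converged and its slack variables are
frozen, removing `n_k` columns from the Jacobian for all later iterations.
Freezing does not move the iterate, so the objective is continuous at the
freeze. By default the mechanism activates only for problems with two or more
distributions: for `N = 1` the lone distribution *is* the convergence target,
and freezing it at an L1 change of 1e-4 would truncate exactly the
high-precision descent the single-parameter benchmarks require. This
default is a deliberate narrowing of the feature to the multi-parameter
workload it was designed for.

### Structure-factor variables and initialization

`r_eff` and `V_f` enter `G` nonlinearly and break convexity. They are
optimized as `r_eff = exp(u1)`, `V_f = 0.74 * plogis(u2)` (in-domain by
construction), with Jacobian columns by central finite differences of the
cheap closed-form `S(q)` — all other Jacobian blocks stay analytic. Because
the result depends on the starting pair, `grid_search_structure_init()` runs
a short solve (default 40 iterations plus polish) for every candidate on a
coarse grid and returns the pair with the lowest chi-squared, ties broken
toward the smaller volume fraction. On synthetic data whose truth lies on a
5 x 7 candidate grid the search executes exactly 35 short solves and selects
the truth; the polish inside the short solves is what separates the true
pair's misfit (~1e-5 at 10% assumed errors) from its neighbours (~1e2) by
seven orders of magnitude.

Default initialization elsewhere: uniform weights, with `xi` and the
background level from a two-variable linear least-squares fit of the observed
mean against the uniform forward curve and a constant. For large 2D problems
`sas_solve_2d_prep()` first solves on a strided-subsampled q grid and feeds
the result forward as the starting state.

## Post-fit analysis

**Sensitivity.** With `X` the flattened variable vector (all weights, `xi`,
background), the package scores each variable by `|H_aa| * X_a^2` normalized
to unit maximum, where `H_aa` is the diagonal curvature of chi-squared.
Because the model is linear in every individual variable, `H_aa = 2 sum_q
(dI_q/dX_a / sigma_q)^2` is exact, not a Gauss–Newton approximation. The
normalization and the precise functional form are implementation-defined (the
source formulation leaves them open); scores are comparable within one
analysis, not across datasets.

**Uncertainty.** At the MLE the model is linear in each `w_k` separately, so
the linearized posterior covariance is available analytically without
sampling: with `G~` the Green tensor contracted with all MLE weights except
parameter k, `C = diag(sigma^2)`, the per-bin error bars are

    delta_w_k = sqrt( diag( (xi^2 G~' C^-1 G~)^-1 ) ),

the no-prior case of the standard linear-Gaussian posterior. Rank-deficient
normal matrices (more bins than informative data directions — the norm, not
the exception, in free-form inversion) are pseudo-inverted at a relative
singular-value cutoff of 1e-10 and flagged. The simplex constraint couples
the bins; those correlations are reported through the rank/conditioning
diagnostics rather than folded into the per-bin bars. The suite checks the
bars against a Monte-Carlo oracle (10,000 perturbed re-solves of the linear
subproblem) to within three standard errors, plus exact scalar and
sigma-linearity cases.

## The synthetic world

All benchmarks are generated, not downloaded, and each generator is a pure
function of its seed:

* **Bimodal spheres** — radius density = equal-mass Gaussian (centre 500 Å,
  width 20 Å) plus two-sided exponential ("Boltzmann", centre 650 Å, width
  30 Å) on 500 bins over [400, 800] Å; 200 log-spaced q points in [1e-3, 1]
  Å⁻¹; the observed mean is the exact forward curve and the assumed error is
  drawn per point uniformly in 20–30% of the mean. Because the mean is exact,
  the MLE coincides with the generating truth no matter the assumed error —
  which is precisely what makes it a recovery benchmark. The component
  centres/widths are package choices (the originating description does not
  print them); the acceptance claims depend on exact recovery, not on these
  values.
* **Stochastic spheres** — positive white-noise density over 300 bins,
  sigma = mean, 2000 q points. Radius and q ranges reuse the bimodal case's
  (also not printed at the source); the acceptance claim for this system is
  the chi-squared level only, which is insensitive to that choice.
* **Cylinders (mini)** — four smooth unimodal truths over 10 bins each,
  32 x 32 image on [-1, 1] Å⁻¹. The `phi` grid sits at midpoints of its
  pi-period so that a uniform orientation truth produces an exactly
  azimuthally symmetric image — a symmetry the tests exploit as an oracle.
  The paper-scale problem (40 bins/parameter, 120 x 120 image) is refused
  with its 295 GB size estimate unless explicitly acknowledged.

What a green suite establishes: exact-recovery behaviour of the solver on
noise-free means with proportional assumed errors, at desk scale. What it
does not establish: behaviour under additive noise realizations, real
instrument resolution functions, model mismatch, or the full 295 GB
out-of-core workload (the chunked store and chunk-invariant contraction are
tested, the full-scale run is not).

## Numerical choices

* Removable singularities: `Phi` switches to its series below `x = 0.01`
  (the closed form loses `~3 eps/x^2` digits to cancellation; the series
  truncation error there is below machine epsilon); `sinc` and `2J1(x)/x`
  switch below 1e-4; the Percus–Yevick terms switch to a series in
  `u = 2 q r_eff` below 0.03, where the third closed-form term (numerator
  `O(u^6)`) has lost all significance.
* Green tensors are validated non-negative and finite at construction.
* The q dynamic range enters the misfit only through `mu/sigma`, so
  proportional-error data are well conditioned by construction.
* Tie-break in the structure grid search: smallest `V_f` at equal
  chi-squared.
* Persistence: Green tensors go to a directory store (JSON metadata, CSV
  grids, raw little-endian double chunks along the first q axis, each chunk
  at most a quarter of the memory budget). An HDF5 store would be the
  conventional choice; this stack has no R HDF5 bindings, and the directory
  store preserves the chunked architecture the out-of-core path needs.
* 2D data interchange uses long-format text (`qx qy mean std`), the non-HDF5
  alternative, for the same reason.

## Known limitations

* Sphere and cylinder geometries only; no core–shell or ellipsoid kernels,
  no anisotropic structure factors, no mixtures of different form models.
* The structure-factor search is initialization, not global optimization; a
  truth far off the candidate grid can still trap the solve.
* Per-bin error bars ignore the simplex-induced correlations (reported as
  diagnostics instead).
* Smearing is implemented for 1D data.
* The monitor/freeze heuristic can, in principle, freeze a distribution that
  would still have moved under a later re-expansion; frozen parameters are
  never un-frozen.
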