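---
title: "Estimating sinking velocity with dynamically scaled free-falling models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sinking velocity with dynamically scaled free-falling models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinkscale)
```

## The problem

Small biological particles — planktonic foraminifera tests, spores, seeds,
phytoplankton — settle at speeds that shape their dispersal, their
contribution to carbon export, and even paleoclimate reconstructions built on
microfossil distributions. Measuring those speeds directly is hard: the
particles are sub-millimetre, sink slowly, and have intricate shapes.

Dynamic scaling sidesteps the measurement problem. An enlarged, geometrically
similar model settling in a viscous working fluid experiences *the same
dimensionless flow physics* as the original particle in seawater, provided the
Reynolds number
$$Re = \frac{L\,U\,\rho_{fluid}}{\mu}$$
is matched. At matched $Re$ the drag coefficient $C_D(\psi, Re)$ — a function
only of shape $\psi$ and $Re$ — is also matched, and every kinematic quantity
of interest is proportional between model and original.

The catch unique to sedimentation: the speed $U$, hence $Re$, of the original
particle is the *unknown*. One cannot pick the correct model scale in
advance. The method implemented here resolves that circularity iteratively.

## Force balance and the operating point

A particle sinking steadily at terminal velocity satisfies
$F_{weight} = F_{buoyancy} + F_{drag}$. Eliminating $U$ through the
definition of $Re$ turns the balance into a one-parameter constraint curve in
the $(Re, C_D)$ plane:
$$C_D^F(Re) = \frac{2\,g\,V\,(\rho_{particle}-\rho_{fluid})\,L^2\,\rho_{fluid}}
                    {A\,\mu^2\,Re^2},$$
with $L$ the maximum length parallel to the flow, $A$ the projected frontal
area and $V$ the solid volume (excluding fluid-filled cavities). The
prefactor is twice the Archimedes number, $Ar = g L_{Ar}^3 \rho_{fluid}
(\rho_{particle}-\rho_{fluid}) / \mu^2$ with $L_{Ar}^3 = V L^2 / A$, so
$C_D^F = 2\,Ar/Re^2$ — `cd_force_balance()` and `archimedes()` implement the
two forms and a test asserts their identity.

The particle's true drag curve $C_D^E(Re)$ is a second, shape-specific
relation. The **operating point** $(Re^O, C_D^O)$ is where the two curves
cross; $U^O$ then follows from $Re^O$. Because $C_D^F \propto Re^{-2}$ falls
faster than any physical drag curve at low-to-moderate $Re$, the crossing is
unique — the package exploits this by root-finding the *difference of
logarithms* on $\log_{10} Re$ with `uniroot`, which is robust and
derivative-free.

## The iterative loop

`run_estimation()` implements the full loop:

1. **Initial guess** (`initial_operating_guess()`): pretend the particle is a
   sphere and intersect $C_D^F$ with the Morrison sphere correlation — a
   four-term empirical fit valid for $0 < Re < 10^6$ that recovers the Stokes
   limit $24/Re$ and gives $C_D \approx 0.5$ at $Re = 1000$.
2. **Plan three scales** (`plan_first_scales()`): $S_1$ is the scale whose
   model (ideal volume $S^3 V^O$) should land at the guessed $Re$ in the
   tank, wall effects included; $S_2 < S_1 < S_3$ are chosen so the expected
   tank $Re$ span the literature range for the taxon (default 18–55 for
   foraminifera) together with the guess.
3. **Sink and convert**: each measured model yields a mean speed (replicates
   filtered at ±5% of their median), a measured volume from weighing, hence
   a point $(Re, C_D^{walls})$ via the force balance, wall-corrected to
   $C_D^\infty$.
4. **Fit** (`fit_drag_spline()`): a shape-constrained spline through the
   points, in both cubic and linear variants.
5. **Solve** (`solve_operating_point()`) and **check**
   (`check_convergence()`): stop when (1) the operating point is not
   extrapolated beyond the data, (2) cubic- and linear-fit $U^O$ agree within
   5%, and (3) the nearest measured $Re$ is within 15% of $Re^O$. Otherwise
   `next_scale()` plans a model aimed exactly at the current estimate and the
   loop repeats.

Scale factors are rounded to one decimal place before use, matching the
precision with which physical models are scaled for printing. If `max_iter`
(default 10) models are sunk without convergence, the best estimate is
returned *flagged*, with a warning — never silently.

## Numerical choices

**Drag-curve fitting.** Drag curves of compact particles are near power laws,
so fitting happens in $(\log_{10} Re, \log_{10} C_D)$. Three spline knots are
used: the two ends of the data range plus one interior knot whose position is
selected by least squares over a small candidate grid (midpoint fallback).
The curve is constrained to be monotonically decreasing and concave-up within
the data range — enforced at a 201-point grid via an escalating quadratic
penalty, started from a ridge solution; a curve that is decreasing and convex
in log–log coordinates is automatically decreasing and convex in linear
coordinates too (if $g' \in [-1, 0)$ and $g'' \ge 0$ for $\ln C_D = g(\ln
Re)$, then $C_D''(Re) \propto g'' + g'(g'-1) > 0$). With only three points
the cubic basis (5 degrees of freedom) is under-determined; a tiny curvature
penalty ($10^{-7}$ relative) selects the smoothest interpolant without
measurably biasing well-determined fits. Data that *rise* by more than 20%
between consecutive $Re$ cannot be explained by replicate-level noise; the
fit then warns and returns the best feasible curve. Outside the data range
the curve continues linearly in log–log space and evaluations are flagged as
extrapolated — criterion (1) above consumes that flag.

**Wall effects.** A particle settling in a tank feels extra drag from the
walls. For small particle-to-tank diameter ratios $\lambda = d/D$ (we take
$d = L$), the walls multiply the drag force at a given speed by
$$K(\lambda) = \frac{1}{1 - 2.1\,\lambda},$$
so the apparent drag coefficient at the measured $Re$ converts as
$C_D^\infty = C_D^{walls} / K(\lambda)$ (`cd_unbounded()`, with
`cd_bounded()` its exact inverse for planning). $K$ gives 1.0057 at
$\lambda = 0.0027$ and 1.0377 at $\lambda = 0.0173$ — the range spanned by
cm-scale models in a 0.9 m tank. The correction is derived for $Re \lesssim
50$; above that the package applies it unchanged and logs a warning rather
than failing, since the error committed is far smaller than ignoring walls
altogether. Ratios beyond $\lambda = 0.1$ are refused: different corrections
are needed there.

**Volume prediction.** Printed models systematically exceed the ideal
$S^3 V^O$ volume (excess resin is hardest to remove from small models), so
volumes are always *measured* by weighing, and predicted for planning from
the accumulated $(S, V)$ data: cubic-spline interpolation once at least four
pairs bracket the target (four pairs being the minimum that meaningfully
supports a cubic), cubic scaling from the nearest pair otherwise.

**Transient settling.** `solve_transient()` integrates
$M\,dU/dt = Vg\Delta\rho - F_{drag}(U)$, $dZ/dt = U$ from rest with an
adaptive Runge–Kutta (relative tolerance $10^{-8}$). The drag coefficient
diverges at $U = 0$, so the force is written as
$F_{drag}(U) = \frac{12 \mu A}{L} U + \tfrac{1}{2}\rho A U^2 [C_D(Re) - 24/Re]$:
algebraically identical for $U > 0$, regular at rest, and exactly
$3\pi\mu d U$ for a sphere in the Stokes limit. `depth_to_fraction()` reports
the depth at which a stated fraction of terminal velocity is reached —
used to confirm that a tracking window sits entirely in the terminal regime.
Added-mass and history forces are neglected.

**Mesh morphometrics.** $L$, $A$, $V$ come from STL surface meshes:
volume by the divergence theorem (watertightness verified by directed-edge
matching, with the open-edge count reported on failure), $L$ as the range of
vertex projections on the sinking direction, and $A$ by rasterizing the union
of projected faces — concave shadows have no cheap exact formula — on a grid
of 1024 cells along the longer shadow axis, refined until the area changes by
under 0.1%. The enclosed volume includes voids sealed by the surface and
excludes cavities open to the exterior; for shells whose lumina connect to
the outside through apertures the mesh itself decides, and the measured value
can be overridden by constructing the `particle_geometry` directly.

## What the virtual tank emulates — and what it does not

`sink_model()` simulates one experiment end-to-end: the printing-volume bias
$V = S^3 V^O (1 + c/S)$ with $c = 0.3$ by default (excess volume shrinking
with scale, mirroring the direction observed when weighing printed models),
the terminal force balance in the tank against a ground-truth drag curve
amplified by $K(\lambda)$, and five replicate speeds with i.i.d.
multiplicative lognormal noise of unit mean (default CV 1%) — positive by
construction and appropriate for small relative errors. Everything is
deterministic under a fixed seed, with per-model streams derived from the
seed and the scale factor. `make_tracks()` additionally synthesizes the
two-camera centroid tracks with variable frame intervals and timestamp
jitter.

The default virtual particle (`L = 1` mm, circular frontal area of the same
diameter, 13% solidity, calcite walls) operates near $Re \approx 42$ in
seawater — squarely inside the span reported for real foraminifera — and its
planned models come out at $S \approx 9$–15, i.e. cm-scale bodies sinking at
several cm/s in oil, matching the physical experiment's regime.

The simulator does *not* emulate: release-mechanism disturbances, convection,
air bubbles trapped in complex geometries, residual uncured resin, camera
segmentation error, or drag curves outside the perturbed-sphere family
(`perturbed_cd()` scales the sphere curve and tilts its log–log slope).
Closed-loop tests therefore demonstrate the *estimator's* correctness —
recovery of a known truth through the full plan/measure/fit/solve cycle —
not the fidelity of any physical apparatus. Consistent with the idealization,
the virtual loop typically converges with 3 models (occasionally more under
noise), at the fast end of the 3–6 models physical experiments require;
real-world nuisances like bubbles and resin residue, which slowed convergence
for the most ornate physical specimens, are exactly what the simulator leaves
out.

## Fixed defaults

| Quantity | Default | Why |
|---|---|---|
| Seawater | $\rho = 1025$ kg m$^{-3}$, $\mu = 1.22\times10^{-3}$ Pa s | standard values near 15 °C, 35 PSU — a water-column average |
| Test material | calcite, $\rho = 2710$ kg m$^{-3}$ | $V$ counts only solid wall material, so the material density is the mineral's |
| Mineral oil | $\rho = 830$ kg m$^{-3}$, $\mu = 0.022$ Pa s | the working fluid used in the tank experiments |
| Printing resin | $\rho = 1121.43$ kg m$^{-3}$ | measured density of cured clear resin |
| Tank | $D = 0.9$ m, oil depth ~1.18 m | the physical settling tank |
| $g$ | 9.80665 m s$^{-2}$ | standard gravity; configurable |
| Re bracket | [18, 55] | published operating range for foraminifera |
| Replicates | 5, filtered at ±5% of median | the experimental drop protocol |

All are config values (`load_config()`), never hard-coded in operations.

## A complete virtual run

```{r}
geom <- particle_geometry(L = 1e-3, A = pi / 4 * 1e-6, V = 1e-10,
                          "virtual foram test")
truth <- virtual_particle_truth(geom, perturbed_cd(morrison_correlation(), 1.2),
                                calcite())
src <- virtual_experiment_source(truth, 0.9, mineral_oil(), printing_resin(),
                                 noise_model(velocity_cv = 0.01, seed = 42))
run <- run_estimation(geom, seawater(), calcite(), 0.9, mineral_oil(),
                      printing_resin(), src)
run
run$history[, c("S", "U_mean", "Re", "C_D_inf")]
```

The recovered $U^O$ can be compared against the truth solved directly from
the ground-truth curve:

```{r}
h <- function(lre) {
  re <- 10^lre
  log10(cd_force_balance(re, geom, calcite(), seawater())) -
    log10(eval_drag(truth$drag, re))
}
Re_true <- 10^uniroot(h, c(-3, 5), tol = 1e-12)$root
U_true <- speed_from_reynolds(Re_true, geom$L, seawater())
c(U_estimated = run$operating_point$U_O, U_true = U_true,
  rel_error = abs(run$operating_point$U_O - U_true) / U_true)
```

## Problem sizes used in the test suite

The suite exercises the closed loop a few dozen times (noiseless recovery
across five ground-truth curves; twenty seeded noisy runs for the
iteration-count statistic; small noise-scaling and Monte-Carlo sweeps), fits
transient trajectories for mm- to cm-scale spheres, and benchmarks mesh
morphometrics on an icosphere with 5120 faces at grid resolutions up to
1024. These sizes keep every quantity's discretization or Monte-Carlo error
well below the tolerance being asserted while the whole suite runs in well
under a minute.

## Known limitations

- The wall correction is a small-$\lambda$, low-$Re$ result; above $Re = 50$
  it is applied with a logged caveat, and above $\lambda = 0.1$ the package
  refuses rather than guessing.
- The empirical drag curve carries no uncertainty band; replicate spread is
  the only error source surfaced.
- Shape enters only through data: nothing is predicted from geometry beyond
  the sphere-based first guess, so a particle whose drag departs wildly from
  the sphere family simply needs more iterations.
- `measure_mesh()` trusts the mesh: segmentation artifacts, unsealed
  apertures or interior shells change $V$ in ways the package cannot detect
  beyond the watertightness check.
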