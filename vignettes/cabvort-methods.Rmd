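---
title: "Models and numerics behind cabvort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind cabvort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cabvort)
```

## The problem

The carotid artery bifurcation (CAB) — where the common carotid (CCA) splits
into the internal (ICA) and external (ECA) carotid — is the predominant site
of atherosclerotic plaque formation, and the ICA sinus (the bulbous widening
of the proximal ICA) is its most affected region. The local hemodynamics are
widely believed to drive this localization: endothelial cells respond to wall
shear stress (WSS), and low or disturbed WSS is proatherogenic. Large
coherent vortical structures that form in the sinus during the cardiac cycle
reshape the instantaneous WSS field, so quantifying *where* and *when* those
structures live, and how they differ between a healthy anatomy and one with
known anatomical risk factors, is a concrete, computable question.

cabvort implements the complete post-processing chain for that question:
parametric vessel geometries, a calibrated pulsatile inflow model, lambda2
vortex identification and tracking, instantaneous WSS and TAWSS,
pressure-minimum vortex-core kinematics, secondary-flow decomposition, and
axial pressure-gradient analysis. It deliberately does **not** contain a
Navier-Stokes solver: the flow fields it consumes come either from an
external CFD solution or from the package's own analytic generators, which
exist so that every stage can be verified against exact ground truth.

## Parametric geometry

Both anatomies are planar-symmetric branch unions of three straight-axis
canal surfaces. The *healthy* preset is a symmetric 60° bifurcation (ICA and
ECA at 30° from the CCA axis) with a 6.5 mm circular CCA inlet and an
ICA/CCA diameter ratio of 0.7 (CCA measured at the inlet, ICA downstream of
the sinus). The *predisposed* preset carries the two anatomical risk
factors — the ICA angle widened to 45° (75° total) and the diameter ratio
reduced to 0.5 — with CCA and ECA unchanged.

Several dimensions have no published values and are therefore explicit,
configurable parameters with documented defaults chosen to look like a
typical adult carotid:

* **Sinus bulge**: a smooth `sin^2` radial bulge over `sinus_length`
  (default 3 ICA diameters) peaking at `sinus_max_diameter` (default 1.1 x
  the CCA inlet diameter). A peak equal to the downstream diameter
  degenerates to a plain tube.
* **CCA taper**: linear, default ratio 0.9 from inlet to bifurcation.
* **ECA diameter** 0.7 x inlet; **entry extension** 3 inlet diameters;
  **exit extensions** 8 local diameters, long enough to keep outlet effects
  away from the junction.
* **Apex blend**: a polynomial smooth-minimum with fillet width 0.2 x the
  CCA radius joins the three canals. Because the surface is the zero level
  of one implicit function, the union can never self-intersect; the builder
  instead checks that the ICA and ECA, having separated once, never re-touch
  (a sinus bulge too wide for the branch angle is a construction error).

The triangulated surface is extracted by marching tetrahedra (Kuhn
six-tetrahedra decomposition of each grid cell), which guarantees a closed
manifold: every edge is shared by exactly two faces, and the test suite
asserts zero boundary and zero non-manifold edges on every build. Each
iso-surface vertex is then projected onto the exact implicit surface by
bisection along its grid edge, so measured diameters and angles carry the
accuracy of the implicit function rather than of the grid. The default cell
size is 30% of the smallest branch radius; measurements move by less than
0.2% when the resolution is halved, and `measure_geometry()` recovers random
parameter sets to well under 1% in lengths and 0.5° in angles.

The sinus-anchored frame used by all kinematics has its origin at the
bifurcation apex and its axial unit vector along the ICA sinus center axis;
the in-plane pair completes a right-handed orthonormal basis (orthonormal to
1e-12 by construction).

## Inflow and outlets

The inlet Reynolds number is defined as `Re = U D / nu` with `U` the
spatial-mean inlet velocity, `D = 6.5 mm`, and a blood-analog kinematic
viscosity `nu = 6.95e-7 m^2/s`. The physiological target waveform peaks at
Re = 1530 with a cycle mean of 385 over a 1 s period. The digitized
patient-averaged trace itself is not published, so `make_waveform()` ships a
smooth surrogate: a fixed base shape (a systolic Gaussian pulse near
t/T = 0.15 plus a smaller diastolic bump, truncated to 8 Fourier harmonics)
calibrated *affinely* so that the peak and mean Reynolds numbers are met
exactly. Because the calibration is a linear map fixed by two equations, it
is deterministic and idempotent; the constructor refuses targets that would
drive the inlet velocity negative. Users with their own digitized trace can
exchange it via the two-column CSV interface.

Note one consequence of the printed targets: peak/mean = 1530/385 is about
4, considerably peakier than typical CCA flow, so the surrogate's diastolic
velocity is low (a few percent of systole). The calibration honors the two
printed constants rather than a typical waveform shape.

Outlets are purely resistive (a degenerate Windkessel): `dp = R Q` with
`R_ICA = 1.5e6` and `R_ECA = 11e6` Pa s/m^3, and the ECA takes whatever the
ICA does not (`Q_eca = Q_cca - Q_ica`, exactly). Density is not needed by
the Reynolds matching and is never published with it; the default
`rho = 1050 kg/m^3` (whole blood) enters only through `mu = rho nu`, and
every WSS output records the fluid used. A CFL utility
(`cfl_number()`/`cfl_max_dt()`) supports time-step checks of transport
computations.

## Synthetic flow fields as ground truth

Because no raw fields are deposited with the study conditions, the package
generates analytic stand-ins whose properties are known exactly; they are
first-class, tested code:

* **Poiseuille** (`poiseuille_snapshot`): steady parabolic pipe flow with
  wall shear `4 mu U / a` and favorable gradient `-8 mu U / a^2` attached.
* **Womersley** (`womersley_series`): the exact unsteady solution whose
  cross-section mean reproduces the calibrated waveform harmonic by
  harmonic. At the packaged conditions the fundamental Womersley number is
  `alpha = a sqrt(2 pi / (T nu)) ~ 9.8`. The analytic wall-shear trace is
  attached. Complex-argument Bessel functions J0/J1 are evaluated by power
  series (no installed R package provides them); the alternating series
  loses roughly one digit per unit of `|Im z|`, leaving ~1e-8 relative
  accuracy at the largest Womersley numbers used (alpha <= ~30), far inside
  the 2% verification band.
* **Vortex tubes** (`vortex_tube_field`): rigid rotation (lambda2 exactly
  `-omega^2`), pure shear (lambda2 exactly 0), and Lamb-Oseen swirl with
  pressure from radial-momentum quadrature (`p(Inf) = 0`); the `r = 0` axis
  is handled by series limits.
* **Hairpin filaments** (`hairpin_field`): Biot-Savart integration over a
  Lambda-shaped polyline with Gaussian-core regularization
  `q(x) = erf(x) - (2/sqrt(pi)) x e^{-x^2}`, chosen because a straight
  filament then induces *exactly* the Lamb-Oseen swirl — the regularization
  is verified against that closed form, not just smoothness. The quadrature
  doubles the segment count until the velocity change is below tolerance
  and reports the step size on failure. Note that the tolerance is absolute
  (m/s): for unit circulation on millimeter scales the induced velocities
  are large, so set it relative to `Gamma / (2 pi r_c)`.
* **Moving pressure wells** (`moving_min_series`): a Gaussian pressure
  minimum following a prescribed trajectory — the tracking oracle, with the
  exact path (and analytic velocity, if supplied) attached.

What these fixtures emulate is the *kinematic structure* of pulsatile
bifurcation flow: realistic shear and unsteady wall-stress levels, coherent
counter-rotating and hairpin-shaped vortices, advecting wall-pressure
minima, and periodic cycles. What they do not emulate is the Navier-Stokes
dynamics itself: no pressure-velocity coupling, no instability, no
turbulence-like breakdown, and the hairpin's pressure is a Bernoulli
estimate rather than a Poisson solution. Green tests therefore demonstrate
that the *measurement chain* is correct on fields with known answers — not
that any particular CFD result is reproduced. Headline quantities of the
underlying study that derive from a multi-million-element solve (lifespan
windows, percent differences between geometry variants) are out of reach at
desk scale by construction, and the package makes no claim to reproduce
them.

## The lambda2 pipeline

From each snapshot the velocity-gradient tensor `J` is computed — by
second-order central differences on structured grids (second-order one-sided
at boundaries) or by distance-weighted least squares over neighbor sets on
unstructured points (exact for affine fields; a coplanar neighborhood is a
named error). `J` splits into the strain-rate tensor `S = (J + J')/2` and
rotation-rate tensor `O = (J - J')/2`; the eigenvalues of `S^2 + O^2` are
sorted `lambda1 >= lambda2 >= lambda3` and a point is in a vortex core when
`lambda2 < 0`.

The per-point symmetric eigensolve uses vectorized cyclic Jacobi sweeps
rather than the closed-form trigonometric method: the trig method loses
~1e-9 relative accuracy precisely in the degenerate-pair cases that matter
here (rigid rotation gives eigenvalues `{0, -omega^2, -omega^2}`), while
Jacobi converges quadratically to near machine precision and vectorizes
cleanly. The suite checks the implementation point-for-point against base
R's `eigen()` as an independent oracle, including a 100% sign match on a
Lamb-Oseen field.

Vortex regions are connected components of `{lambda2 < threshold}` under
voxel 26-connectivity (structured) or mesh adjacency (unstructured), with
components below `min_size = 10` points discarded as noise. Published
lambda2 analyses rarely report their numeric iso-value, and none is fixed
here either: the default threshold is scale-free — minus 5% of the 99th percentile of `|lambda2|` —
always user-overridable and recorded in the output; lifespan endpoints
necessarily depend on it, which is why `region_presence_window()` insists on
one constant threshold across all phases (and the comparative pipeline
shares one value across geometry runs). Frame-to-frame matching is by
maximum bounding-box overlap, tie-broken by centroid distance then region
id — fully deterministic.

## Wall mechanics

`WSS = mu (du/dy)_wall` is evaluated per wall face from the no-slip
condition and the tangentially-projected velocity at a wall-adjacent sample:
first-order `mu u_t(y)/y` by default, with a two-point second-order option
`mu (4 u_t(y) - u_t(2y))/(2y)` for oscillatory boundary layers (at the
packaged Womersley conditions with samples at `a/64`, the first-order form
is good to ~10% of the cycle maximum and the second-order form to ~2%).
TAWSS is the cycle mean of `|tau_w|`; for uniform periodic sampling the
periodic trapezoidal rule *is* the arithmetic mean over phases, which the
suite verifies against closed forms (`2A/pi` for `A|sin|`) and dense Simpson
quadrature.

The spatial association between the high-WSS band and the vortex is scored
with the Szymkiewicz-Simpson overlap `|A & B| / min(|A|, |B|)` between the
top-quantile WSS faces (default top 20%) and the wall footprint of the
vortex regions (faces within distance `d` of a member point, default two
cell sizes). The band is described visually, not numerically, in the
literature, so both knobs are configuration; a permutation test against
random same-size footprints provides the significance baseline in the
suite.

## Core tracking and kinematics

The vortex core is a local pressure minimum; inside a search window
(axis-aligned in the sinus frame, stationary or advected with the bulk
velocity) the global candidate argmin is taken per phase — verified to equal
an exhaustive argmin at every tested phase. Ties break to the candidate
nearest the previous core, or most upstream at the first frame; repeated
runs are byte-identical. Core pressure is nondimensionalized by `P0`, the
pressure at a reference point at t/T = 0.191 (configurable). If the window
holds no candidates for more than 3 consecutive frames the trajectory is
truncated and flagged as deterioration.

Velocity and acceleration come from central differences of the axial
coordinate after an optional 3-point moving average. Because the located
core is grid-quantized, a stall produces a plateau of exact zeros in the
velocity; events are therefore detected by interpolating the zero crossing
between the flanking nonzero velocities, which centers the stillstand on
the plateau — the suite recovers a prescribed decelerate-stall-reverse
profile to one grid cell and the stall phase to one time step.

## Secondary flow and the axial pressure gradient

Six planes (configurable), uniformly spaced in arc length across the sinus
and perpendicular to the ICA axis, carry Cartesian in-plane grids masked to
the local lumen radius. Velocity is interpolated trilinearly and split into
the axial component `u . n` and the in-plane secondary components — the
split conserves `|u|^2` to 1e-10 — with `u/U` nondimensionalized by the mean
inlet speed at the reference phase (default t/T = 0.27). Counter-rotating
(Dean-type) pairs are counted from in-plane vorticity blobs: threshold at
20% of the maximum magnitude, 8-connected labeling, circulation by area
integral, and pairing of opposite-signed blobs of comparable strength
(ratio within [0.5, 2]) by smallest separation.

The axial gradient trace is `dP/dxi = (P_exit - P_entry) / delta_xi` per
phase, with area-averaged station pressures by default (point probes
retained as an option) and `delta_xi` spanning the sinus. Negative values
are favorable (flow-driving), positive adverse; extrema are classified
accordingly, filtered by prominence (default 10% of the trace range,
measured against neighboring opposite extrema, circularly), and percent
differences between two traces pair extrema of the same class by nearest
phase as `(a - b)/|b| * 100`.

## The comparative pipeline

`run_pipeline()` executes geometry -> synthetic series -> all analyses for
each configured preset and aggregates a comparative report. The synthetic
series is a deterministic construction in the sinus frame: bulk axial flow
scaled by continuity into the ICA, a hairpin vortex whose circulation grows
with inflow *deceleration* (the phase in which sinus vortices form) and
with the branch angle, and an advecting wall-pressure well. The
unit-circulation induced field is computed once and scaled per phase, which
keeps the end-to-end run to seconds. Both geometry runs share one lambda2
threshold, reports echo the normalized configuration with a content hash,
and reruns are byte-identical — the suite checks the `report.json` hash.

## Problem sizes and tolerances

The test and verification sizes are chosen so the whole suite runs in a few
minutes on one core while every tolerance retains a margin: 13-41 point
grids per axis for the analytic fields, 200 phases for Womersley/TAWSS
quadrature checks, 20 random geometry round-trips at default resolution, 500
permutations for the overlap baseline, and a 14^3-cell, 12-phase coarse
configuration for the end-to-end determinism check. Tolerances stated in
tests are the quantity's verification band (e.g. 1% for first-order WSS at
`y = a/100`, 2% for second-order Womersley shear at `y = a/64`), not tuned
numbers: each traces to a discretization-error estimate given in the
relevant section above.

## Known limitations

* No Navier-Stokes solve: all dynamics enter through the generators or
  external data; rigid walls and Newtonian rheology are assumed throughout.
* The geometry is an idealized planar-symmetric union of straight-axis
  canals — no patient-specific curvature, non-planarity, or plaque.
* The waveform surrogate matches two integral constraints of the
  physiological trace, not its full shape.
* Lambda2 lifespans depend on the (unpublished) iso-value; the scale-free
  default makes runs comparable, not absolutely anchored.
* Unstructured-grid support expects caller-supplied adjacency for large
  point sets; the built-in kNN fallback is quadratic and meant for small
  fixtures.
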