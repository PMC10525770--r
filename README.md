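# cabvort

Vortex and wall-shear-stress analysis for pulsatile flow in the carotid
artery bifurcation (CAB).

The CAB — where the common carotid artery (CCA) splits into the internal
(ICA) and external (ECA) branches — is the predominant site of
atherosclerotic plaque formation, concentrated in the ICA sinus. The local
flow there develops large coherent vortical structures over the cardiac
cycle, and these reshape the instantaneous wall shear stress (WSS) that
endothelial cells respond to. `cabvort` is a post-processing toolkit for
quantifying exactly that, for anyone analyzing time-resolved vascular flow
fields (CFD output or analytic models): it builds the vessel models, the
inflow/outlet boundary descriptions, and the full measurement chain for
vortices, wall stresses and secondary flows.

What it computes, in standard notation:

* **Geometry** — watertight parametric CAB surfaces with branch centerlines:
  a `healthy` preset (symmetric 60° bifurcation, ICA/CCA diameter ratio
  0.7) and a `predisposed` preset carrying the two anatomical risk factors
  (ICA angle 45°, 75° total; ratio 0.5), plus a sinus-anchored coordinate
  frame (origin at the apex, axial coordinate ξ down the ICA sinus axis).
* **Boundary models** — a pulsatile CCA inflow waveform calibrated so that
  Re(t) = U(t)·D/ν attains peak 1530 and mean 385 over T = 1 s
  (D = 6.5 mm, ν = 6.95·10⁻⁷ m²/s); resistive outlets Δp = R·Q; continuity
  split Q_ECA = Q_CCA − Q_ICA; CFL utilities.
* **λ2 vortex identification** — J = ∇u, S = (J+Jᵀ)/2, Ω = (J−Jᵀ)/2;
  eigenvalues of S² + Ω² sorted λ1 ≥ λ2 ≥ λ3; vortex regions are connected
  components of {λ2 < threshold}, tracked over the cycle into presence
  (lifespan) windows.
* **Wall mechanics** — instantaneous WSS τ_w = μ(∂u/∂y)_wall, its cycle
  average TAWSS = (1/T)∫|τ_w|dt, and the spatial overlap between the
  high-WSS band and the vortex wall footprint.
* **Core tracking** — the vortex core as a wall pressure minimum inside a
  stationary or advected search window, its trajectory ξ(t) in the sinus
  frame, velocity/acceleration, and stillstand / upstream-motion /
  deterioration events; pressure nondimensionalized by P0 = P(t/T = 0.191).
* **Secondary flow** — velocity decomposition on six planes perpendicular
  to the ICA centerline (u/U with U the mean inlet speed at t/T = 0.27),
  counter-rotating (Dean) pair counting, and the axial pressure-gradient
  trace ΔP/Δξ_ICA with favorable (< 0) / adverse (> 0) extrema.
* **Synthetic flows with ground truth** — Poiseuille and exact Womersley
  pipe flow, Lamb–Oseen / rigid-rotation / shear tubes, Biot–Savart hairpin
  filaments, and moving pressure wells: every generator attaches its
  analytic answer, so the whole measurement chain is verifiable.

The package contains no Navier–Stokes solver; see the methods vignette
(`vignettes/cabvort-methods.Rmd`) for the models, defaults and numerics.

## Worked example

```r
library(cabvort)

# calibrated physiological inflow
wf <- make_waveform()       # T = 1 s, peak Re 1530, mean Re 385, D = 6.5 mm
wf
#> inflow waveform: T = 1 s, D = 6.5 mm, peak Re 1530 / mean Re 385 (8 harmonics)
re <- waveform_reynolds(wf, (0:999) / 1000)
sprintf("peak Re = %.2f at t/T = %.3f; mean Re = %.2f",
        max(re), which.max(re) / 1000, mean(re))
#> "peak Re = 1529.96 at t/T = 0.152; mean Re = 385.00"

# the at-risk anatomy, built and measured back
geom <- build_geometry(cab_preset("predisposed"))
geom
#> CAB geometry: 27184 vertices / 54364 faces (h = 0.487 mm), ICA 45 deg, ECA 30 deg
m <- measure_geometry(geom)
sprintf("total angle %.2f deg, ICA/CCA ratio %.3f, sinus %.2f mm",
        m$total_branch_angle, m$ica_cca_diameter_ratio, 1e3 * m$sinus_max_diameter)
#> "total angle 75.00 deg, ICA/CCA ratio 0.500, sinus 7.15 mm"

womersley_alpha(3.25e-3, 1, 6.95e-7)   # pulsatility at the packaged conditions
#> 9.77
```

The peak Reynolds number is read off a 1000-point phase grid (hence 1529.96
rather than the exact calibrated 1530.00), the measured anatomy reproduces
the preset's risk-factor values, and α ≈ 9.8 confirms the flow is strongly
pulsatile — viscous and inertial effects both matter in the sinus.

End-to-end comparative runs (geometry → synthetic sinus flow → λ2 / WSS /
tracking / secondary analyses → `report.json`) go through `run_pipeline()`,
or the CLI in `inst/exec/cabvort`:

```sh
cabvort geometry --preset healthy --out mesh.stl
cabvort waveform --peak-re 1530 --mean-re 385 --out wave.csv
cabvort run config.yaml
```

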