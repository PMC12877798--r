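---
title: "Modelling thrombus growth and flow cessation in stenosed coronary bifurcations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thrombus growth and flow cessation in stenosed coronary bifurcations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clotflow)
```

## The model

`clotflow` couples three sub-models on a shared two-dimensional channel
domain:

1. **Hemodynamics.** Incompressible Newtonian flow with a Brinkman
   (porous-medium) sink,
   $\rho(\mathbf{V}\cdot\nabla)\mathbf{V} =
   -\nabla p + \mu\nabla^2\mathbf{V} - \frac{\mu}{G_{clot}}\mathbf{V}$,
   $\nabla\cdot\mathbf{V}=0$. In clot-free cells $1/G_{clot}=0$ and the
   equation reduces to Navier-Stokes; inside the growing clot the Darcy
   drag dominates and the cells behave as (nearly) solid.
2. **Coagulation biochemistry.** Nine species — resting and activated
   platelets (RP, AP), ADP, thromboxane (TX), prothrombin (PT), thrombin
   (T), antithrombin (AT), fibrinogen (FG), fibrin (F) — each governed by
   a convection-diffusion-reaction equation. Platelets activate at rate
   $\Omega/t_{Act}$ once the combined agonist index
   $\Omega = C_{ADP}/C_{ADP,cri} + C_{TX}/C_{TX,cri} + C_{T}/C_{T,cri}$
   exceeds one; thrombin is generated on platelet surfaces and removed by
   the Griffith template kinetics of heparin-catalysed inactivation by
   antithrombin; fibrinogen converts to fibrin by thrombin-catalysed
   Michaelis-Menten kinetics. Fibrin is immobile (no convection); all
   other species advect with the flow. Platelet diffusivity is
   shear-enhanced, $D = (13.61\,\dot\gamma + 1.58)\times 10^{-13}$ m²/s.
3. **Deposition and clot resistance.** On thrombogenic wall faces,
   platelets deposit at rate
   $M_{DP} = qK_{RPD}C_{RP} + qK_{APD}C_{AP} + K_{APA}C_{AP}\varphi$,
   with coverage $\varphi = \min(1, \int M_{DP}\,dt / M_{max})$ and free
   fraction $q = 1-\varphi$. Coverage and the local fibrin fraction
   $\psi = \min(1, C_F/C_{FG,inlet})$ set the hydraulic resistance
   $1/G_{clot} = 1/G_{DP} + 1/G_F$ with
   $1/G_{DP} = (1/G_{DP}^{max})\,\varphi^2/(\varphi_{cri}^2+\varphi^2)$
   (half-maximal at $\varphi_{cri}$) and the Davis fibrous-media law
   $1/G_F = 16\psi^{1.5}(1+56\psi^3)/r_F^2$.

The risk layer classifies stenoses by peak wall shear stress against the
7 Pa thrombogenic threshold and provides the separable power-law model
$\tau_{max} = a\dot V^b D_{LMCA}^c D_{Ste}^d\,\varepsilon^e(1-\varepsilon)^f$
together with a log-linear least-squares refit from simulated sweeps.

## Units

Platelet concentrations are carried in PLT/ml, small species in µM and
thrombin in U/ml. In these units every tabulated rate constant combines
without conversion factors (nmol/ml ≡ µM); thrombin converts to µM via
$\beta = 9.11\times10^{-3}$ nmol/U wherever a molar balance requires it,
and the deposition rate picks up a single $10^6$ ml→m³ factor against
$M_{max}$ (PLT/m²). Geometry is described in mm; the mesh and solver work
in SI metres.

## The planar idealization and what it can and cannot show

Patient vessels are described by a parameter table (parent and daughter
diameters, stenosed branch, stenosis degree by diameter, stenosis
length). `build_bifurcation()` realizes these as a planar Y-channel:
channel width equals vessel diameter, daughters leave the junction at
±30° by default, and the stenosis is a smooth cosine diameter-reduction
bump whose throat width is exactly `base × (1 − degree)`. The inlet flow
rate is mapped so that the mean velocity of the equivalent circular
vessel is preserved (`q̄ = Q/(πD²/4) · w`).

Two consequences of planarity matter for interpretation:

* A planar throat accelerates flow as $1/w$, a circular one as $1/d^2$.
  Planar velocity-gradient wall shear in a stenosis is therefore several
  times lower than in the vessel the parameters describe. Since the 7 Pa
  threshold is a statement about the real (circular) vessel, risk
  classification and the $\tau_{max}$ sweeps use the **equivalent-vessel
  wall shear** $\tau_{eq}(s) = 32\mu Q_{branch}/(\pi d(s)^3)$, where
  $Q_{branch}$ is the branch's share of the inlet flow *from the solved
  planar flow division* and $d(s)$ the local diameter. The
  velocity-gradient shear from `wall_shear()` remains the quantity used
  for the flow-solver verification (plane-Poiseuille closed form) and for
  the shear-enhanced platelet diffusivity, which are genuinely planar
  quantities.
* The flow division between daughters is set by planar (width-cubed)
  resistances, so branch fractions are comparable to, but not identical
  with, the three-dimensional ones.

## Numerics

The flow solver is a staggered (MAC) finite-volume scheme on a uniform
Cartesian grid with solid masking of out-of-lumen cells: axis-aligned
straight sections are resolved exactly, oblique walls are staircase.
Advection is first-order implicit upwind with a deferred second-order
upwind correction, diffusion is central, and the no-slip wall flux uses a
quadratic fit that is exact for locally parabolic profiles (plane
Poiseuille is reproduced to well under 1% with 20 cells across the
channel). The monolithic velocity-pressure system is solved by sparse LU
with row equilibration (the Brinkman-penalized rows are many orders
larger than the continuity rows); discrete continuity is enforced
exactly, so global mass balance holds to round-off. Picard iteration with
under-relaxation (0.85) handles the advection nonlinearity; the
convergence tolerance is 1e-4 on the relative velocity change by default.

Species transport uses implicit Euler with upwind fluxes taken from the
staggered velocity field, inlet Dirichlet at normal-blood composition,
outlet zero-diffusive-flux, and species-specific fluxes on active
deposition faces. Reactions are integrated by positivity-preserving
semi-implicit (Patankar) sub-stepping that resolves the locally fastest
loss rate; the standalone well-mixed reactor (`simulate_wellmixed()`)
uses an adaptive Cash-Karp 4/5 Runge-Kutta scheme instead and conserves
FG+F and RP+AP to near round-off.

Two wall-scale closures deal with the coarse grid:

* **Boundary-layer-limited capture.** The platelet concentration boundary
  layer above a depositing wall (~tens of µm) is thinner than a cell, so
  the kinetic capture coefficients are combined in series with the
  half-cell diffusive conductance evaluated with the local
  shear-dependent platelet diffusivity:
  $1/K_{eff} = 1/K + (h/2)/D(\dot\gamma_{wall})$. $K_{eff}\to K$ under
  refinement. This closure is what transmits the shear-enhanced
  diffusivity mechanism — and hence the mid-stenosis deposition peak seen
  in tube perfusion experiments — to the coarse grid.
* **Fibrin on a platelet scaffold.** Thrombin generated on circulating
  platelets produces a small but nonzero volumetric fibrin source, and
  fibrin does not advect; taken literally with the Davis law this would
  assign large hydraulic resistance to the whole domain within the
  simulated window. Physically a load-bearing fibrin network needs a
  scaffold, so fibrin contributes to $1/G_{clot}$ only in cells whose
  platelet coverage exceeds `phi_scaffold` (default 0.1) or that are
  already clot.

Clot surface propagation marks a cell as clot when its coverage reaches
`phi_full` (default 0.9) **or** when its combined resistance makes it
effectively solid (`solidify_frac × 1/G_DP^max`, default one half); the
fluid-facing sides of a new clot cell become fresh deposition surfaces
with zero coverage. The clot set never shrinks (no embolization or lysis
is modelled).

## Scaled-down runs

Physical cessation times (tens of seconds to minutes) at a fixed
$10^{-3}$ s coupling step are beyond a desk-scale budget, so the pipeline
provides a kinetics time-scale factor that multiplies every reaction,
surface-flux and deposition rate. A factor $k$ compresses the clot
timeline by about $k$; transport is not rescaled, so large factors
(≳50) over-deplete near-wall platelets and distort the regime — the
packaged study conditions use $k = 10$ with a 0.1 s coupling step and a
mesh resolution of (stenosis throat)/4.5. The stenosed-tube perfusion
case instead runs at $k = 1$ for a short window: its reported quantity is
the *pattern* of per-segment deposition fractions, which is set by the
quasi-steady wall flux and does not require reaching saturation.
Per-segment deposits are reported as per-unit-area fluxes over the five
equal-arclength segments so that the staircase face count of the masked
boundary does not bias the comparison.

Cessation is operationalized as the stenosed-branch outlet fraction
staying below 1% of the inlet flow for a sustain window (default
$\max(1/k, 2\,\Delta t)$); the cessation report also states whether a
connected path of non-clot cells still crosses the stenosis — the
bifurcation mechanism of interest is precisely that flow stops by
hydraulic diversion *before* geometric occlusion.

## Known limitations

* On a coarse grid the clot advances in whole-cell layers, so branch-flow
  histories decline in steps rather than smoothly; the initiation /
  acceleration / terminal-slowdown structure is visible but compressed.
* The planar resistance model weakens the geometric discrimination
  between patients whose throat widths are similar; comparative cessation
  times are meaningful as an ordering under matched numerics, not as
  absolute times. In particular, a short mild lesion (small active band)
  can outlast a wide one at desk scale, because growth here is
  capture-rate-limited rather than volume-limited; three-dimensional
  studies weight the stenotic lumen volume more heavily.
* The packaged power-law coefficients for $\tau_{max}$ carry an explicit
  unit-convention tag; their printed form does not reproduce Pa-scale
  values under any natural unit pairing, so refitting on the package's
  own sweeps (`fit_powerlaw()` on `simulate_shear_sweep()` records) is
  the supported calibration path.
* Two boundary-table entries (`j_TX = -φ s_TX`,
  `j_PT = β φ k_{AP,T} C_{PT}`) are implemented exactly as tabulated;
  their magnitudes (~1e-11) make them numerically irrelevant, but their
  printed units are per-platelet rather than flux-like.
* No pulsatility, Windkessel outlets, fibrinolysis, embolization, moving
  walls or non-Newtonian rheology.

## Problem sizes used by the packaged experiments

Flow-solver verification uses a 2 mm channel with 20 cells across the
width. The tube perfusion case runs a 2 mm tube with a 35% stenosis at
0.1 mm resolution (≈3,000 cells) for 2 s at unscaled kinetics. The
patient bifurcation runs use branch lengths of 3 local diameters
(extended to fit the stenosis), throat/4.5 resolution (≈500-8,000 cells
depending on the patient), a 0.1 s coupling step and kinetics factor 10.
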