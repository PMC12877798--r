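# clotflow

Coupled hemodynamics–coagulation modelling of thrombus growth and flow
cessation in stenosed vessels and idealized coronary bifurcations.

Blood clots forming in a stenosed coronary branch raise its hydraulic
resistance; in a bifurcation the flow is diverted into the healthy
branch, so perfusion of the stenosed branch can stop long before the
lumen is geometrically occluded. `clotflow` is for researchers studying
that mechanism at desk scale: it couples

* **Brinkman flow** — incompressible Newtonian momentum with a Darcy sink,
  `ρ(V·∇)V = −∇p + μ∇²V − (μ/G_clot)V`, solved by a staggered
  finite-volume scheme on a masked Cartesian grid, where the growing clot
  enters through a deposition- and fibrin-dependent inverse permeability
  `1/G_clot = 1/G_DP + 1/G_F` with
  `1/G_DP = (1/G_DP^max)·φ²/(φ_cri²+φ²)` and the Davis fibrous-media law
  `1/G_F = 16ψ^1.5(1+56ψ³)/r_F²`;
* a **nine-species coagulation network** (resting/activated platelets,
  ADP, thromboxane, prothrombin, thrombin, antithrombin, fibrinogen,
  fibrin) transported by convection–diffusion–reaction equations, with
  platelet activation at rate `Ω/t_Act` once
  `Ω = C_ADP/C_ADP,cri + C_TX/C_TX,cri + C_T/C_T,cri > 1`, Griffith
  template kinetics for heparin-catalysed thrombin inactivation, and
  shear-enhanced platelet diffusivity `D = (13.61 γ̇ + 1.58)×10⁻¹³` m²/s;
* **platelet deposition** on thrombogenic wall faces,
  `M_DP = qK_RPD·C_RP + qK_APD·C_AP + K_APA·C_AP·φ`, with surface
  coverage `φ = min(1, ∫M_DP dt / M_max)`;
* a **risk layer**: thrombogenic-area identification by the 7 Pa wall
  shear threshold, the separable power law
  `τ_max = a·V̇^b·D_LMCA^c·D_Ste^d·ε^e·(1−ε)^f`, its log-linear
  least-squares refit from simulated sweeps, and the strict
  high-risk/low-risk classifier at 7 Pa.

Synthetic geometries stand in for angiographic reconstructions: a
parameter table (vessel diameters, stenosed branch, stenosis degree and
length) builds planar Y-bifurcations and stenosed tubes with a smooth
cosine diameter-reduction bump. Six reference patient parameter sets are
packaged (`patient_table()`).

## Worked example

Baseline risk screening of packaged patient 6 (LMCA 4.10 mm, LAD 2.90 mm
with a 65% stenosis over 17 mm, LCX 2.70 mm) at 2 cc/s, followed by a
scaled clot-growth run on patient 1:

```r
library(clotflow)
pt <- patient_table()

geom <- build_bifurcation(pt[6, ], length_factor = 3)
mesh <- generate_mesh(geom, resolution = 0.225)    # mm
flow <- solve_flow(mesh, NULL, boundary_conditions(2e-6))
ws   <- equivalent_tube_shear(wall_shear(flow, mesh), flow, mesh, 2e-6)
tau  <- stenosis_peak_shear(ws, measure = "equivalent")
round(tau, 2)
#> [1] 14.03
classify_risk(tau)
#> [1] high_risk
#> Levels: low_risk high_risk
```

The peak equivalent-vessel wall shear in the stenosis is about 14 Pa —
well above the 7 Pa threshold, so the stenosis is classified as a
thrombogenic (high-risk) site and its above-threshold faces become the
injury surface for the growth simulation:

```r
cfg <- simulation_config(build_bifurcation(pt[1, ], length_factor = 3),
                         dt = 0.1, t_max = 60, kinetics_scale = 10)
res <- run_simulation(cfg)
signif(res$report$final_fraction, 3)  # stenosed-branch share of inlet flow
#> [1] 0.000159
res$report$open_channel      # flow stopped without geometric occlusion
#> [1] TRUE
```

On the compressed clock (kinetics factor 10) the stenosed LAD's flow
fraction falls from 23% to below 0.1% of the inlet flow while a connected
open channel remains across the stenosis — flow cessation by hydraulic
diversion, not occlusion. `res$series` holds the full time series
(`t_s, frac_branch1, frac_branch2, n_clot_cells, tau_max_pa,
total_dep_plt`), and `export_results(res, "out/")` writes CSV/JSON/VTK.

The stenosed-tube perfusion experiment (2 mm tube, 35% stenosis,
10 ml/min) reports per-segment deposition fractions over five equal
segments of the stenosis:

```r
vc <- run_validation_case(duration = 2, kinetics_scale = 1)
round(vc$segment_fractions, 3)
#> [1] 0.147 0.228 0.373 0.173 0.079
```

Deposition is maximal in the third (apex) segment, driven by the
shear-enhanced platelet diffusivity, and collapses in the fifth where the
post-stenotic vortex lowers the shear rate below its upstream value.

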