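# fruitdrop

Explicit-dynamics finite element simulation of fruit drop impacts and the
bruise-susceptibility analysis built on it, for postharvest-engineering
researchers who want a fully scripted, testable alternative to running a
commercial FE code by hand.

Kiwifruit bruise when dropped: the flesh yields plastically under the
impact stress and later browns. The package models the whole chain:

1. **Tissue mechanics** — reduce force–displacement tests to engineering
   stress–strain (σ = F/S, ε = ΔL/L) and fit the bilinear elastic–plastic
   law (Young's modulus *E*, bio-yield stress σ<sub>y</sub>, tangent modulus
   *E*<sub>t</sub>); a built-in library carries the measured parameters for
   kiwifruit skin, flesh and core and the three contact-surface materials.
2. **Synthetic fruit** — a parametric multiscale solid (0.3 mm skin
   membrane, flesh, ellipsoidal core) meshed as a conformal structured
   tetrahedral grid from the three measured fruit diameters.
3. **Explicit solver** — lumped-mass central-difference integration,
   constant-strain tetrahedra + membrane skin, J2 radial-return plasticity
   with linear hardening *H* = *E E*<sub>t</sub>/(*E* − *E*<sub>t</sub>),
   elastic-foundation penalty contact with a planar surface, full energy
   audit (kinetic, internal, plastic, contact, viscous, hourglass ≡ 0).
4. **Damage metrics** — an element is bruised when its peak Von Mises
   stress exceeds its tissue's bio-yield threshold (flesh 0.26 MPa, skin
   0.52 MPa, core 1.12 MPa); bruise susceptibility is

   **BS = V<sub>b</sub> / E<sub>t</sub>**  [mm³/J]

   (bruised volume per unit absorbed impact energy).
5. **Experiments & response surfaces** — the 27-scenario factorial sweep
   (heights 0.25/0.5/1 m × angles 0/45/90° × steel/PVC/neoprene), mesh
   sensitivity study, rebound/restitution analysis, and per-surface
   quadratic response-surface fits BS(*X*, *Y*) in drop height *X* (m) and
   collision angle *Y* (deg) — including direct evaluation of the published
   prediction polynomials for the three surfaces.

## Worked example

```r
library(fruitdrop)

mesh <- generate_mesh(fruit_geometry(), element_size = 3)
mesh
#> <fruit_mesh> 4096 nodes, 20250 tets (378 core), 2700 skin triangles
#>   target element size 3 mm, total volume 90696.8 mm^3

res <- run_drop_simulation(mesh, scenario = drop_scenario(0.5, 0, "steel"))
res
#> <simulation_result> h=0.5 m, angle=0 deg, surface=steel
#>   13929 steps (dt 1.23e-05 / 3.57e-07 s), peak contact force 249.98 N
#>   peak flesh VM 0.349 MPa, peak skin VM 0.530 MPa

damage_report(res)
#> <damage_report>
#>   bruise volume: 4558.6 mm^3 (flesh 4558.6, core 0.0)
#>   bruised skin area: 30.5 mm^2
#>   absorbed energy (peak_internal): 0.4708 J
#>   bruise susceptibility: 9682.4 mm^3/J

evaluate_printed_model("steel", X = 1, Y = 90)      # published polynomial
#> [1] 6716.065
```

Read it as: dropped 0.5 m onto steel lying on its side, the fruit sees a
quarter-kilonewton peak contact force; about 4.6 cm³ of flesh is stressed
past its bio-yield point while absorbing 0.47 J, i.e. ~9700 mm³ of bruise
per joule (the skin stays almost entirely below its own yield). The published steel-surface response polynomial predicts its own
maximum (1 m, end-on) at 6716 mm³/J.

A full analysis mirrors the numbered drivers in `analysis/`:
`01_materials.R` (parameter reduction), `02_mesh_convergence.R`,
`03_drop_simulations.R` (the 27-cell sweep, cached and resumable) and
`04_response_surface.R` (fits, significance, extrema, surface plots).
Outputs land in `results/` as tidy CSV, JSON (with a hashed run manifest)
and legacy-ASCII VTK for ParaView.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch: the published steel and neoprene response-surface
polynomials at their extremum settings; the peak contact force and peak
flesh Von Mises stress of the steel-surface 1 m drops at 0° and 90° on a
2 mm mesh; and the hourglass/internal energy ratio of the baseline
(steel, 0.5 m, 0°) run. It writes one JSON object with one numeric entry
per quantity (~6–10 minutes on one CPU).

## Column dictionaries

`results/grid.csv` (one row per scenario): `height_m`, `angle_deg`,
`surface`, `failed`, `vb_mm3` (bruised volume), `skin_area_mm2`, `et_J`
(absorbed energy), `bs_mm3_per_J`, `peak_force_N`, `peak_vm_flesh_MPa`,
`peak_vm_skin_MPa`, `restitution`, `rebound_height_m`.

Time-series CSV (`as_timeseries()`): `time_s`, `contact_force_N`
(impulse-averaged per output frame), `com_velocity_mps`, `ke_J`, `ie_J`,
`ce_J`, `plastic_J`, `hourglass_J`, `viscous_J`.

Configuration is JSON (`load_config()`), with every material, geometry,
solver and damage default overridable; unknown keys are rejected with their
path. See the methods vignette (`vignettes/fruitdrop-methods.Rmd`) for the
model, its assumptions, numerical choices and known limitations.
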