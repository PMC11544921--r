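---
title: "Drop-impact bruising of kiwifruit: model, solver and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drop-impact bruising of kiwifruit: model, solver and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Kiwifruit bruise when they are dropped during harvest and post-harvest
handling: the subcutaneous flesh yields plastically under the impact stress,
browns over the following days, and the fruit loses commercial value.
`fruitdrop` models the drop impact with an explicit-dynamics finite element
simulation of a multiscale fruit body (skin, flesh, core), extracts the
bruised tissue volume with a Von Mises yield criterion, and condenses each
scenario into a single bruise-susceptibility index

$$\mathrm{BS} = V_b / E_t \quad [\mathrm{mm}^3\,\mathrm{J}^{-1}],$$

the bruised volume per unit of energy absorbed by the fruit during the
collision. A full factorial sweep over drop height (0.25, 0.5, 1 m),
collision angle (0°, 45°, 90°) and contact surface material (steel, PVC,
neoprene) is then summarised by per-surface quadratic response-surface
models $\mathrm{BS}(X, Y)$ in height $X$ and angle $Y$, and the package also
carries the published prediction polynomials for the three surfaces so they
can be evaluated directly.

## Constitutive model and tissue parameters

All tissues are isotropic bilinear elastic–plastic (J2 flow theory with
linear isotropic hardening). A uniaxial record is characterised by the
Young's modulus $E$ (initial slope), the bio-yield stress $\sigma_y$ (the
stress at which irreversible cell damage begins) and the tangent modulus
$E_t$ (post-yield slope). The hardening modulus used by the radial-return
update is $H = E E_t / (E - E_t)$, which makes the uniaxial elastic–plastic
tangent exactly $E_t$; materials without a tangent modulus are treated as
elastic–perfectly-plastic ($H = 0$), and materials without a yield stress as
purely elastic.

The built-in library (`material_library()`) carries the laboratory means:
flesh $E = 1.57$ MPa, $E_t = 0.92$, $\sigma_y = 0.26$, $\rho = 1030$,
$\nu = 0.40$; core $5.11 / 0.83 / 1.12 / 1120 / 0.40$; skin
$E = 10.69$ MPa, $\sigma_y = 0.53$, $\rho = 960$, $\nu = 0.30$ (no tangent
modulus: the skin fractures in tension before a hardening branch is
observed, so the membrane is perfectly plastic). Measurement spreads ride
along as metadata. Two tabulated oddities are preserved deliberately: the
PVC density of 60 kg m⁻³ (physically implausible for bulk PVC, but unused
because contact surfaces are massless foundations here), and the skin yield
which is tabulated as 0.53 MPa while the damage analysis applied 0.52 MPa —
the damage threshold defaults to 0.52 with 0.53 one keyword away.

`fit_bilinear_params()` reduces a measured stress–strain curve to these
parameters by continuous two-segment piecewise-linear least squares: the
breakpoint minimising the SSE over a grid of the data strains is polished
with a 1-D optimiser, $E$ and $E_t$ are the segment slopes and $\sigma_y$
the stress at the breakpoint. The bio-yield point is reported at the
breakpoint itself rather than via an engineering 0.2%-offset rule, matching
how bio-yield is read off fruit-tissue curves. A curve whose two slopes
differ by less than 2% (relative) is declared purely linear and gets no
yield parameters; no smoothing is applied by default (an odd moving-average
window is available). Under 1% Gaussian stress noise the generator→fit round
trip recovers all three parameters within 5% (verified over 100 seeded
replicates with 200-point records, a realistic sampling density for a 3
mm/min crosshead test).

## Synthetic fruit geometry

Only three outer dimensions of the reference fruit are available (length
64.18 mm, equatorial diameters 53.46 and 50.72 mm), so the scanned free-form
surface is replaced by a tri-axial ellipsoid with semi-axes $(L/2,
d_{max}/2, d_{min}/2)$. The scanned surface area (10,182 mm²) is within
about 3% of the ellipsoid's Thomsen approximation (9,852 mm²), which
supports the stand-in; the scanned *volume* as tabulated (195,931 mm³) is
inconsistent with any body fitting inside the measured bounding box
(174,000 mm³) and is disregarded in favour of the analytic ellipsoid volume
(91,118 mm³).

No core dimensions were published, so the core is a coaxial ellipsoid at
0.55 of the length and 0.25 of each diameter — visually consistent with a
cut fruit, configurable, and flagged as an assumption. The skin is a
membrane of the boundary triangles, 0.3 mm thick, sharing nodes with the
flesh (a fully bonded "tie" by construction); the core–flesh interface is
conformal shared-node labelling rather than an embedded-mesh coupling,
which is equivalent for fully bonded behaviour.

### Meshing

The mesher is a structured spherified cube: a hexahedral grid on
$[-1,1]^3$ is mapped smoothly onto the unit ball, scaled to the ellipsoid
semi-axes, and each hexahedron is split into 6 tetrahedra (Kuhn split).
Two refinements keep the minimum element quality resolution-independent
(≈0.45–0.55 on the quality scale where a regular tetrahedron scores 1):

* the smooth cube-to-ball map has a singular Jacobian along the cube-corner
  diagonals, which radially crushes the outermost cell layers there; it is
  blended (weight $m^2$ in the max-norm shell coordinate $m$) with the
  shell-equalised map $m\,S(p/m)$ that assigns every grid shell the exact
  radius $m$;
* a fixed Kuhn diagonal produces boundary slivers whose four nodes all lie
  on the surface; mirroring the split per octant so the diagonal always
  points radially outward removes them, and stays conformal because a face
  diagonal is invariant under the mirror normal to its shared face.

This choice replaces a subdivided-icosphere/radial-layer construction,
which cannot keep the element size uniform: its angular resolution is set
by the surface and persists to the centre, collapsing both the central
element size (and with it the stable time step) and the element budget.
The spherified cube keeps near-uniform element volume everywhere. Meshing
is deterministic; a seeded jitter-retry path exists behind the quality
floor (default 0.05) but is never triggered by the structured construction.

## Explicit solver

Lumped-mass central-difference integration (semi-implicit update) of 4-node
constant-strain tetrahedra with single-point exact integration, plus 3-node
plane-stress membrane triangles for the skin. The formulation is
updated-Lagrangian: shape-function gradients are recomputed on current
coordinates and the stress is rotated with the Jaumann increment before the
radial-return update (a `geometric_nonlinearity = FALSE` switch selects
linear kinematics for benchmarks against linear-elastic closed forms).
Because the elements are fully integrated, hourglass modes do not exist and
the hourglass-energy channel is identically zero — the "hourglass below
0.08% of internal energy" rationality bound holds trivially, and is still
asserted from the recorded channel.

* **Time step.** Per-element maximum eigenfrequencies are computed by power
  iteration on the assembled element stiffness against the lumped mass and
  the step is $\Delta t = s\,\cdot 2/\omega_{max}$ (safety $s = 0.9$). This
  is used instead of the characteristic-length/wave-speed estimate because
  it is an exact bound (the estimate can err on either side of the 1%
  verification tolerance). Penalty contact adds its spring frequency
  $\sqrt{k_i/m_i}$ in quadrature and a spring–damper factor
  $\sqrt{1+\zeta^2}-\zeta$; the solver switches between the structural and
  the (much smaller) contact-stable step adaptively, using a proximity band
  below which any skin node could reach the plane within two structural
  steps. With a steel surface the contact step is ~30× smaller than the
  structural one, so the adaptive switch is what makes 27-scenario sweeps
  affordable.
* **Contact.** The surface is a rigid plane carrying an elastic foundation:
  each penetrating skin node feels the pressure $(E_{surf}/h_{ref})\,\delta$
  over its tributary area (reference $h_{ref}$ = 10 mm), frictionless. The
  published study gives only the plate materials' moduli, not the plate
  geometry or contact algorithm, so the foundation stiffness is a stated
  assumption with $h_{ref}$ configurable. A light viscous damper per
  penetrating node (10% of critical, dissipation tracked) suppresses the
  single-node ringing that penalty springs otherwise superimpose on the
  contact force; the *reported* force history is additionally
  impulse-averaged per output frame (the frame mean of $F\,dt$), which is
  the standard antialiasing for explicit contact output and makes the
  trapezoid of the reported history equal the true impulse.
* **Bulk viscosity.** A linear volumetric viscosity (coefficient 0.06)
  stabilises the compression shock; its dissipation is tracked.
* **Energy audit.** At every output frame the solver records kinetic energy
  (from time-synchronised velocities), internal stress work (elastic +
  plastic, with plastic dissipation separately), contact spring energy,
  contact damper and bulk-viscosity dissipation, and gravity work. The
  closure defect is normalised by the impact kinetic energy and stays below
  1% in the verification runs; exceeding 5% aborts the run with a
  diagnostic.
* **Initial state.** The fruit is rotated so its polar axis makes the
  collision angle with the plane (0° side impact, 90° end impact), placed
  touching the plane, and given the free-fall speed $v_0 = \sqrt{2gh}$
  downward; gravity (9.8 m s⁻²) stays on through the 0.02 s event.

### Verification against closed forms

The solver is verified against independent oracles in the test suite: the
single-element critical time step against an R-side assembled eigenvalue
problem; the constitutive point update against the bilinear law under a
uniaxial-stress driver (slopes $E$ and $E_t$ within 1%, perfectly plastic
dissipation $\sigma_y\,\bar\varepsilon_p$ exactly); the contact model
against brute-force summation and against the exact Winkler impact closed
form $F = (E_s/h_{ref})\,\pi R\,\delta^2$ for a stiff sphere on a soft
foundation (within ~2%); momentum against the impulse of the recorded
force; and the classic elastic-sphere drop against the quasistatic Hertz
peak force $F = \tfrac43 E^* \sqrt{R}\,\delta_{max}^{3/2}$.

The Hertz comparison deserves its honest footnote. The quasistatic theory
is the $v \to 0$ limit; a dynamic simulation carries stress-wave effects
that raise the peak force by roughly $\propto v^{0.4}$ (about +13% at
1 m s⁻¹, +8% at 0.35 m s⁻¹, +5% at 0.1 m s⁻¹ in this solver, essentially
independent of mesh size, Poisson ratio and kinematics — behaviour
consistent with published FEM studies of elastic impacts). At the lowest
speed that still resolves the contact patch within a two-minute test budget
(0.1 m s⁻¹ on a 0.5 mm mesh) the solver lands at +5.1%, a hair outside the
5% acceptance bound, which is therefore left red rather than tuned away;
the Winkler oracle — exact for this contact model — is the green
verification that the contact and integration are correct.

## Damage metrics

An element is bruised iff its peak-over-time Von Mises stress strictly
exceeds its region's threshold (flesh 0.26, skin 0.52, core 1.12 MPa; ties
are not bruised — a measure-zero convention). Peak-over-time is the
conservative reading of "stress during the collision exceeding yield";
final-time stress would miss the transient. $V_b$ sums the *undeformed*
volumes of bruised flesh and core tetrahedra (deformations are moderate and
this removes any dependence on output-frame timing); bruised skin area is
reported separately since it is unclear whether published bruise volumes
include the shell.

The absorbed energy $E_t$ in $\mathrm{BS} = V_b/E_t$ is not operationally
pinned down by its sources; the default is the peak of the fruit's internal
energy over the event (all the energy taken up at maximal compression,
including the recoverable part), with plastic-dissipation-only and
kinetic-energy-loss definitions computed side by side in every damage
report.

## Experiments and response surfaces

`run_scenario_grid()` runs the 27-cell factorial (resumable, per-cell
caching, a failed cell is annotated rather than fatal). The full 3×3
factorial is used as the computational design; a Box–Behnken design is not
meaningful for two continuous factors and the printed per-surface
polynomials imply the full grid anyway. `fit_quadratic_surface()` fits
$\,[1, X, Y, XY, X^2, Y^2]\,$ by OLS in raw factor units (consistent with
the raw-unit published coefficients), reports $R^2$ and t-test p-values
with the explicit caveat that 9 points minus 6 parameters leave 3 degrees
of freedom, and compares factors by standardised effects
$|b|\cdot\mathrm{sd}(\text{factor})$. Extrema are located by closed-form
stationary points checked against a dense grid over the factor box
$[0.25, 1]\,\mathrm{m} \times [0, 90]°$.

Direct evaluation of the published steel polynomial at (1 m, 90°) gives
6716.06 (the printed 6716.07 differs in the last rounding unit from its own
printed coefficients); the neoprene polynomial at (0.25 m, 0°) gives
1570.59 exactly.

## What the synthetic world does and does not establish

The generator's defaults are the measured reference fruit and the tabulated
tissue parameters, and the sweep reproduces the qualitative structure of
the published results: peak force, peak stress and bruised volume increase
with drop height in every cell, and bruise susceptibility increases with
height in its main effect (the per-cell BS shows a ~2% saturation dip at
the 90°/1 m corner, where absorbed energy outgrows the bruised volume);
peak flesh stress increases from side (0°) to end (90°) impact; stiffer
surfaces are at least as damaging (steel ≥ PVC ≥ neoprene); on steel and
PVC the fitted height effect dominates the angle effect. Absolute values differ from the published ones by tens of percent
(BS runs ~1.5× higher), which is the expected envelope when the scanned
geometry, the plate/contact formulation and solver details of the original
study are not published.

One qualitative disagreement is structural and documented rather than
hidden: on the ellipsoidal stand-in the *peak contact force* is larger for
the side impact than for the end impact (the ellipsoid's side is flatter,
radii ≈ 41/28 mm, than its end, ≈ 22/20 mm, and a flatter contact is
stiffer), whereas the published study reports the end impact force as
larger. A real kiwifruit has blunt, nearly flat stem/blossom ends that make
end impacts stiff; an ellipsoid cannot be both consistent with the scanned
surface area (which pins the shape exponent near 2.16 — still sharp-ended)
and blunt enough to flip this ordering. The corresponding acceptance
assertion is left red with this explanation; the stress ordering, which is
controlled by concentration rather than patch stiffness, is reproduced.

## Numerical choices and degenerate inputs

Ties at damage thresholds are not bruised; zero absorbed energy yields
BS = 0 with a degenerate flag; a zero-height scenario runs as a gravity
settling problem and produces zero bruise; mesh sizes are accepted in
[0.5, 10] mm and refused when they cannot resolve the core (the limiting
dimension is named); inverted elements or an energy-audit blow-up abort a
run with diagnostics, and a sweep cell that aborts is marked failed without
stopping the sweep. All randomness (only the mesh jitter-retry path) is
governed by one seed; the solver itself is deterministic, and re-running a
pipeline with the same seed reproduces byte-identical CSV reports.

## Known limitations

Constant-strain tetrahedra with $\nu = 0.4$ carry mild volumetric locking
(a few percent on contact stiffness at practical resolutions); the membrane
skin has no bending stiffness and uses an approximate radial-scaling
plane-stress return (exact for the reported Von Mises level, approximate in
the plastic-flow direction); contact is frictionless; the hypoelastic rate
form is adequate for the ≤15–30% local strains seen here but is not a
finite-strain hyperelastic model; and the ellipsoidal geometry limits
fidelity at the fruit ends as discussed above.
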