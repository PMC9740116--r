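---
title: "Methods: coupled electrokinetics, flow and tissue mechanics in the aqueous outflow pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled electrokinetics, flow and tissue mechanics in the aqueous outflow pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

outflowEFSI simulates, at desk scale, how the charged endothelial glycocalyx
that coats the human conventional aqueous outflow pathway — trabecular
meshwork (TM), juxtacanalicular tissue (JCT) and the inner wall of Schlemm's
canal (SC) — interacts with the aqueous humor draining through it and with
the elastic tissue it covers. Three physics are coupled: a Debye–Hückel
electric double layer on every tissue–fluid interface, incompressible
laminar flow with an electric body force, and quasi-static
near-incompressible linear elasticity, driven by a linear intraocular
pressure (IOP) ramp from 0 to 15 mmHg over 1 s in 100 steps.

This vignette is the package's account of its model: what is solved, which
parameters matter, what the synthetic geometry does and does not emulate,
and where genuinely open modelling choices were decided.

## The idealized geometry

No tissue-resolved outflow geometry is distributed with the package;
`build_outflow_domain()` generates an idealized 2D slice instead, a radial
cut along the flow axis:

* an aqueous channel of height 2 µm (one trabecular/JCT flow space,
  a homogeneous permeable-channel idealization of the open spaces between
  beams — beams are not resolved individually),
* flanked on both sides by 10 µm of elastic tissue, labelled TM for the
  first 40 µm of the path and JCT for the next 14 µm,
* terminated by the SC inner wall (2.2 µm thick, including its basement
  membrane), perforated by pore gaps of width 1.3 µm.

In this 2D slice the measured 3D pore statistics (835 pores/mm², diameter
1.3 µm) map to a mean wall-gap spacing of $1/\sqrt{835\ \mathrm{mm^{-2}}}
\approx 34.6$ µm. A 2 µm tall wall cross-section therefore carries a single
centred pore gap; a zero density closes the wall entirely. The planar patch
generator `place_inner_wall_pores()` is defined independently of the slice:
grid mode places exactly `round(density × area)` pores on a centred lattice
(the deterministic default, since the source geometry placed pores
manually); jittered mode perturbs that lattice with a mandatory seed under a
non-overlap constraint.

Every tissue–fluid facet is tagged `glycocalyx_wall`; the anterior-chamber
face is the traction `inlet`; the pore exits form the open `outlet_open`
boundary; outer tissue faces are `anchor`ed, and remaining exterior tissue
faces are `free` (this tag extends the nominal tag set: the posterior SC
wall face and the anterior tissue face are traction-free/loadable, not
anchored). Meshes are tensor-product triangulations, which makes
boundary-layer grading (`refine_near_wall()`) cheap and deterministic.

The default channel height (2 µm) and TM depth (40 µm) were chosen once so
that the pressure-driven flow is firmly in the creeping regime (Re « 1) and
the peak velocity at 15 mmHg lands at tens of mm/s, the order reported for
outflow micro-channels; they are study conditions, not tuning knobs.

What the synthetic slice does **not** emulate: the tortuous 3D beam
network, curved SC lumen, giant vacuoles, spatially varying glycocalyx
thickness, or segmental (high/low-flow) variation. Passing tests therefore
demonstrate correctness of the numerics and the qualitative physics on an
idealized topology, not quantitative agreement with any particular eye.

## Electrostatics of the glycocalyx double layer

The glycocalyx (~109 nm thick) is represented as a charged boundary
condition, not a meshed solid layer: the potential at the slipping plane is
the zeta potential ζ = −19.5 mV. The quiescent potential solves the
linearized Poisson–Boltzmann (Debye–Hückel) closure

$$\nabla^2 \Phi = \kappa^2 \Phi, \qquad
  \rho_f = -\varepsilon \kappa^2 \Phi, \qquad
  \mathbf{E} = -\nabla\Phi,$$

with Φ = ζ on glycocalyx facets and zero normal gradient on open
boundaries. Linearization is justified because |ζ| = 19.5 mV is below the
25.7 mV thermal scale. The ionic strength of aqueous humor is not among the
printed constants, so the Debye length κ⁻¹ is a configuration parameter
with a physiological-saline default of 10 nm; no validation quantity
depends on its particular value. The −70 mV endothelial membrane potential,
the conductivity (179×10⁻⁴ ohm⁻¹cm⁻¹) and the 50 Ω reference impedance are
recorded as metadata: the field equations actually solved use only ζ and
κ⁻¹, because the source constants never state how the membrane potential
enters them, and no tissue-conduction subproblem is included in this
release.

Two treatments are available. `resolved` meshes the layer (the wall-normal
element size must be at most κ⁻¹/3; `refine_near_wall()` inserts a geometric
grading with first layer κ⁻¹/3 and growth 1.5 by default). `thin-EDL`
keeps the bulk uncharged and represents electroosmosis by the
Helmholtz–Smoluchowski slip $u_s = -\varepsilon \zeta E_t/\mu$; with the
default zero applied field the walls are equipotential, the tangential
field vanishes and thin-EDL slip is identically zero — which is why the
canonical scenarios run in resolved mode (the configuration in which the
double-layer force exists at all).

With lumped mass in the Helmholtz term the discrete operator is an
M-matrix on these meshes, so the computed potential respects the maximum
principle Φ ∈ [ζ, 0] exactly — one of the property tests.

## The electric body force and the equilibrium correction

The momentum equation carries the electric body force ρ_f **E**. In
Debye–Hückel equilibrium this quiescent force is an exact gradient,

$$\rho_f \mathbf{E} = \nabla W, \qquad W = \tfrac12\,\varepsilon\kappa^2\Phi^2,$$

balanced by the equilibrium electrokinetic pressure: in the continuum it
drives no flow in any geometry. Truncating the double layer at an open
boundary while prescribing the raw normal stress unbalances this gradient
and produces strong artificial corner jets (we measured them at the same
order as the physical flow). `body_force_field()` therefore subtracts
∇W, evaluated on the same P1 interpolation, so that the solver's pressure
is the *dynamic* pressure and open boundaries behave as reservoirs in
double-layer equilibrium — the standard dynamic-pressure formulation of
computational electrokinetics. The raw product is available via
`equilibrium_correction = FALSE` for sensitivity studies.

Two force contributions then remain:

* an applied tangential field (`applied_field` / the scenario's
  `inlet_field`, default 0) acting on the layer charge — the genuine
  electroosmotic drive, integrated with exact P1 quadrature because the
  profile decays over κ⁻¹;
* the *discrete imbalance* of the quiescent force: the one-point-quadrature
  force and the interpolated ∇W differ at O(h), concentrated where the
  walls corner (the pore constriction and the wall ends). This is the only
  mechanism that moves fluid at zero IOP in the canonical configuration,
  and it converges to zero under refinement — consistent with the
  vanishingly small zero-IOP velocities reported for this class of model.

The sign with which the force enters the momentum balance is a genuine
ambiguity of the source equations (the printed momentum equation carries
−ρ_f **E**; the textbook electrokinetic form is +ρ_f **E**).
`body_force_field()` defaults to the textbook sign; `scenario_config()`
defaults to the printed sign (`electric_sign = -1`), because the scenarios
exist to reproduce the printed model and, with the conservative part
balanced, the sign determines only the direction of the small residual
effect — the printed sign yields the reported direction (a slightly slower
charged outflow).

## Aqueous humor flow

The humor is Newtonian, homogeneous and laminar (ρ = 1000 kg/m³,
µ = 0.7185 mPa·s). The discretization is equal-order P1–P1
velocity–pressure with Brezzi–Pitkäranta pressure stabilization
(δ_K = α·2|K|/µ, α = 0.01 — small enough that the Poiseuille oracle is
reproduced to 0.1–0.2 %, large enough to suppress pressure checkerboards on
these graded anisotropic meshes), implicit Euler in time with dt = 0.01 s,
and the convective term linearized with the previous-step velocity (an
Oseen lag consistent with the first-order time stepping; a Picard loop is
used for steady solves). At the default conditions Re ≈ 0.1, and dropping
convection changes the maximum velocity by well under 0.1 %.

Boundary conditions: prescribed normal traction −p(t)·n at the inlet with
p(t) the linear IOP ramp; zero normal stress (f₀ = 0) at the pore exits,
which also fixes the pressure gauge; no-slip (or prescribed wall velocity,
from the coupled tissue motion) on glycocalyx walls; free-slip on symmetry
facets. Because the continuity equation is tested by constants (no pressure
Dirichlet data) the discrete velocity is globally conservative: the net
boundary flux vanishes to solver roundoff, which the conservation check
(net < 10⁻⁶ × gross) verifies on every accepted solution.

## Tissue mechanics

TM, JCT and SC inner wall are isotropic linear elastic with Young's moduli
4, 4 and 7.48 kPa and Poisson's ratio 0.495, in plane strain (the slice has
long circumferential extent; plane stress is a flag). The stress is split
as

$$\sigma_{total} = \sigma_t + \sigma_i, \qquad
  \sigma_t = \lambda e I + 2\mu \bar E, \qquad
  \sigma_i = -P_i I,$$

with $\bar E$ the infinitesimal strain, $e = \mathrm{tr}\,\bar E$, and
$P_i$ the interstitial pressure, taken as the fluid pressure at the
interface extended constantly inward (no interstitial-flow model is
provided by the source constants; the tissue continuity equation is
honoured diagnostically through the reported velocity field rather than as
a poroelastic field equation). The volume fraction ε_t multiplying the
equilibrium divergence defaults to 1, reducing the balance to standard
equilibrium. Near-incompressibility is handled by a two-field mixed
formulation in (u, φ) with φ = λe interpolated P1 and stabilized like the
fluid pressure; the slab and patch oracles are reproduced to machine
precision at ν = 0.495, and reported stresses use φ for the volumetric term
(the stable quantity at near-incompressibility). A pure-displacement mode
exists for moderate ν.

**Pre-tension.** The ~500 µN ciliary pre-tension is applied as a statically
equivalent distributed traction along the anterior TM face (nodal point
forces would be mesh-dependent), and `solve_quasistatic()` verifies that
anchor reactions balance the applied resultant to 10⁻⁸. Mapping the 3D
resultant into the 2D slice is a modelling choice: the resultant acts over
the full TM anchoring cross-section (~36 mm of circumference × ~150 µm of
anchoring height), so the slice applies the corresponding anchoring
*stress* (≈ 93 Pa) over its own anterior face rather than the full 500 µN,
which a single 20 µm face could not carry at 4 kPa stiffness. The transient
starts from the pre-tensioned static equilibrium and displacements are
reported relative to that reference state.

## The segregated EFSI solution

`run_scenario()` executes: geometry build (with boundary-layer refinement in
resolved mode) → quiescent potential, charge and field, solved once since
the mesh is fixed → the time loop. Each step solves the fluid implicitly,
extracts the interface traction −p n + µ(∇u)n, loads the solid with it
(plus P_i and pre-tension), and sub-iterates this Dirichlet–Neumann loop
until the relative interface-displacement increment falls below 10⁻⁶
(`couple_step()`, plain fixed-point by default with optional Aitken
under-relaxation; in this viscous-dominated, quasi-static regime 2–4
iterations suffice). Interface displacements are sub-µm against µm-scale
channels, so the fluid mesh is not deformed (small-displacement regime); the
tissue motion feeds back as a wall-velocity Dirichlet condition. Both
factorizations are cached: the solid matrix once per run, the fluid matrix
once per step (it changes only through the lagged convection field).

The three canonical scenarios — FSI @ 15 mmHg, EFSI @ 0 mmHg, EFSI @ 15
mmHg — share a single mesh (`canonical_suite()` builds it once and asserts
the hash), and the zero-charge limit (ζ = 0, electricity enabled) runs
through the identical code path, reproducing the FSI series to roundoff —
the pipeline's master property.

```{r canonical, eval = FALSE}
library(outflowEFSI)
suite <- canonical_suite()   # ~2 minutes on one core at the default sizes
suite$summary
tidy(suite$deltas$EFSI15_vs_FSI15)
```

## Numerical choices and problem sizes

* Default scenario mesh: resolution 0.5 µm across the channel (the
  coarsest the builder accepts, 4 cells across), axial spacing relaxed 4×,
  double layer resolved by a geometric fan (first layer κ⁻¹/3, growth 1.5):
  ≈ 4,900 cells, ≈ 6,200 fluid unknowns. The full three-scenario suite runs
  in about two minutes on one core; the oracle meshes are smaller still.
  These sizes are the package's desk-scale study conditions.
* Oracle refinements: the double-layer and electroosmotic channels grade
  with growth 1.1 and first layer κ⁻¹/10, chosen so that interpolation of
  the exponential layer (the dominant error term, controlled by the growth
  ratio) sits well inside the validation tolerances.
* Linear solves use sparse LU after symmetric diagonal equilibration
  (SI units at micrometre scale mix magnitudes badly enough to trip
  conditioning heuristics otherwise).
* Ties/degenerate inputs: zero forcing returns exact zeros; a zero pore
  density produces a closed cavity whose flux report is identically zero;
  an unanchored solid is rejected as singular rather than regularized.

## Known limitations

* The electrical problem is quiescent: no ion transport (Nernst–Planck), no
  streaming-current feedback, hence no electroviscous retardation. The
  EFSI-vs-FSI differences at the canonical conditions are therefore
  discretization-scale, and their direction is set by the printed sign
  convention — the package reproduces the *sign and smallness* of the
  reported effects, not their magnitudes, which belong to the eye-specific
  geometry.
* Linear small-strain elasticity is used even though the soft moduli put
  local strains at the idealized square pore corners beyond the small-strain
  regime; reported maxima at those corners are stress-concentration
  artifacts of the idealized geometry.
* The fluid mesh is fixed (no moving-mesh/ALE); valid while interface
  displacements stay far below the channel height, which holds at the
  default conditions but should be rechecked for softer configurations.
* `slab-3D` geometry is reserved but not implemented; the slice is
  plane-2D.
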