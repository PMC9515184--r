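---
title: "An electro-thermal-fluid model of endocardial catheter ablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An electro-thermal-fluid model of endocardial catheter ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ablatr)
```

`ablatr` simulates catheter ablation of myocardium inside the blood-filled
cardiac chamber and measures the resulting lesions. This vignette is the
package's own account of the model: what is solved, which parameters matter,
what the numerical machinery does, and where the model's limits are.

## Geometry and scenarios

The chamber is idealised as a three-layer slab: 40 mm of flowing blood over
20 mm of myocardium over 60 mm of skeletal muscle, on an 80 × 80 mm
footprint. Blood flows along +x; z = 0 is the undeformed endocardial plane.
A 7 Fr (2.33 mm) non-irrigated catheter touches the surface at the slab
centre:

* **Monopolar**: a 4 mm tip electrode (hemispherically capped) inserted
  1.25 mm into the myocardium, energized against a dispersive ground
  electrode covering the slab bottom. The catheter can tilt by α (0–60°)
  about the contact point, with the tilt direction rotated by β from the
  flow axis.
* **Bipolar**: a horizontal ring array lying on the surface (0.5 mm
  insertion), four 4 mm rings with 2 mm gaps at alternating polarity. Ring
  dimensions for such arrays are not standardized; 4 mm × 2 mm spacing is
  this package's documented choice, exposed in the geometry code, and the
  bipolar lesion sizes should be read with that caveat (see *Limitations*).

RFA scenarios embed a 0.3 × 0.3 × 0.75 mm temperature-sensor box inside the
tip electrode. Its axial position is a free design choice with first-order
consequences: at operating heat fluxes the 4 mm Pt–Ir tip supports a
~25 °C end-to-end gradient, so a sensor at the blood-cooled proximal end
reads cold and drives the controller to roughly half again more power than a
sensor at the tissue-warmed distal end. Real non-irrigated ablation
catheters embed the thermistor at the tip apex; the package therefore places
the sensor distally (0.3 mm behind the apex), which also reproduces the
published reference lesion volume and peak temperatures. The proximal
alternative can be recovered by editing the geometry.

`scenario_config()` collects modality, catheter configuration, inlet
velocity (0–0.2 m/s), angles, applied burst voltage, duration, mesh
resolution and the symmetry flag; `half_domain = TRUE` simulates only
y ≥ 0 across the mirror plane and is allowed exactly when the scenario is
mirror-symmetric (β = 0).

## Meshing

No tetrahedral mesh generator exists in this R stack, so the package
generates its own: tensor-product grids with smoothly graded axis spacings,
each hexahedral cell split into six Kuhn tetrahedra sharing one diagonal
orientation (hence conforming). Grid planes are forced exactly onto the
layer interfaces, the sensor-box faces and — for the flow-aligned bipolar
array — the ring boundaries; the curved catheter surface is resolved by
per-element centroid classification on a locally refined core.

Resolution presets set two core spacings, around the electrode and over the
lesion-forming region:

| preset  | electrode core | lesion band | intended use |
|---------|---------------|-------------|--------------|
| `paper`  | 1.3 mm | 2.6 mm | matches the published ~46k-element budget of the reference monopolar model |
| `coarse` | 1.0 mm | 2.0 mm | full 30 s RFA protocol runs |
| `medium` | 0.75 mm | 1.2 mm | bipolar field solves, convergence checks |
| `fine`   | 0.5 mm | 0.6 mm | reference PFA lesion morphometry |

The refinement ladder for convergence purposes is `paper` < `coarse` <
`medium` < `fine` — the "paper" preset replicates an element *budget*, which
for this structured generator is the coarsest rung. Tensor grading
necessarily leaves anisotropic cells where a fine band crosses the far
field; the mesh-quality audit (`mesh_quality()`, regular-tetrahedron
normalised) treats those as intentional and enforces a floor of 0.005 with a
much higher interior median. Element counts at the `fine` preset
(half-domain monopolar ≈ 150k tetrahedra) keep every linear solve inside a
few GB of memory.

## Electric problem

Both modalities solve quasi-static conduction ∇·(σ∇Φ) = 0 with P1 elements;
the electrode interiors stay in the domain with their metallic/insulating
conductivities, the active electrode nodes carry the applied RMS-equivalent
voltage (V_P/√2 for the RFA sinusoid, V_P for the biphasic PFA burst) and
the dispersive patch or ground rings carry 0 V. Delivered current is the sum
of residual fluxes over electrode nodes; active/ground current balance is
conserved to solver precision and is audited at 10⁻⁴ in the tests.

Conductivities at 500 kHz (RFA) and 150 kHz (PFA) are the tabulated
baselines with:

* a temperature factor exp(0.015·(T − 37)) for biological materials, with
  cardiac tissue collapsing linearly by a factor 10⁻⁴ across 100–105 °C as
  it desiccates and staying at that floor above (parameterized continuously
  from σ(100 °C) = σ₀·e^{0.015·63}, so the law has no jump at the
  desiccation onset). Blood and
  skeletal muscle keep the exponential branch — the vapor phase is tabulated
  only for cardiac tissue;
* for PFA, the electroporation rise
  σ(E) = σ₀ + 0.1·exp(−exp(−0.01·(|E| − 500))) S/m (|E| in V/cm) applied to
  all biological materials. The coupled fixed point σ(|E|, T) ↔ Φ is found
  by successive substitution with damping 0.7, converged when the relative
  L2 change of the element field magnitude drops below 0.1 % (typically 5–7
  iterations; the sigmoid is ~saturated at the 1000 V/cm lesion threshold,
  which keeps the iteration benign).

Thermal conductivity is k₀ + 0.0012·(T − 37) W/(m K) up to 100 °C and
constant above — the slope printed as "0.12 %/°C" is read as the absolute
slope 0.0012 W/(m K °C), which is what makes the printed cap 0.6356
(= 0.56 + 0.0012·63) continuous.

## Blood flow

The stationary incompressible Navier–Stokes problem is discretized with
equal-order P1/P1 elements, Brezzi–Pitkäranta pressure stabilization
(τ = 0.2 h²/(4μ + 2ρ|u|h) on the volume-equivalent element size) and
streamline-diffusion damping of the convective term. Uniform normal inflow
enters one wall, the opposite wall is a do-nothing (zero-pressure) outflow,
and every other boundary — chamber walls, endocardium, catheter — is no-slip;
the symmetry plane of half-domain runs is free-slip. Blood density is
1050 kg/m³; the dynamic viscosity is not stated by the source and defaults
to 0.0021 Pa s, a standard cardiac-CFD value, exposed in the scenario
config.

Two solution paths share this discretization. Small verification meshes use
damped Picard iteration on the coupled saddle system. Chamber meshes would
need ~15 s per coupled factorization with the available sparse LU, so they
instead march a pseudo-time projection scheme (implicit viscosity, explicit
streamline-damped advection, pressure-Poisson projection — all SPD with
cached Cholesky factorizations) to a pseudo-steady state and finish with one
coupled Oseen solve at the converged advection field. The returned field
therefore satisfies the discrete continuity equation exactly (global flux
balance below 0.1 %, audited in the tests). At the chamber's transitional
Reynolds number (~1200 on the blood-layer height at 6 cm/s) a steady
solution is only marginally stable and successive Picard iterates keep
changing by a few percent; the residual history is reported in the
`flow_field` object rather than hidden, and the frozen advection field
should be understood as a representative steady flow.

## Thermal problem

The Pennes bioheat equation (zero perfusion and metabolic terms, as
specified for this tissue bed) is integrated by operator-split backward
Euler: per step, blood advection is advanced explicitly with
streamline-damped transport sub-steps (local CFL-limited, typically 2–4 per
control interval), then conduction plus the Joule source implicitly with the
SPD matrix Cap/dt + K(k(T)). All exterior boundaries are clamped at 37 °C,
which is also the initial state.

The latent heat of vaporization enters through the enthalpy method: the
apparent heat capacity is ρc of the liquid phase below 99 °C, L = 2.162·10⁹
J/(m³ K) across the 99–100 °C band, and the vapor-phase ρc above. Because a
strongly heated node can cross the whole band within one implicit step, each
step ends with an *enthalpy inversion*: the energy the node gained in the
linearised step is pushed through the exact piecewise-linear nodal enthalpy
curve and the temperature re-read from it. This conserves the latent heat to
machine precision (the insulated-block audit in the tests balances injected
against stored energy at 10⁻⁸) and reproduces the ~543-fold slope reduction
inside the band exactly. Following the single-valued enthalpy curve makes
the phase change reversible on cooling; vapor hysteresis is not modelled.

Factorizations are reused aggressively: the conductivity matrix is rebuilt
only when any node has drifted more than 2 °C since the last build (k drifts
0.21 %/°C at most), and up to three nodes may sit on a stale capacity
segment between rebuilds — harmless, because the enthalpy inversion keeps
every step energy-consistent regardless of the capacity used in the matrix.

## Treatment protocols

**RFA** runs a 30 s closed loop at 20 ms sampling: read the sensor (maximum
nodal temperature in the sensor box), update the position-form PI controller
(K_P = 4.6 V/°C, K_I = 5.8 V/(°C s), setpoint 55 °C, output clamped at 0 V
with a frozen integral as anti-windup), re-solve the field with the current
σ(T) map, advance the bioheat step. Because the potential is exactly linear
in the applied voltage, the field is re-solved from scratch only when the
temperature has drifted 1.5 °C since the last conductivity map; in between,
the per-step "re-solve" is the exact rescaling Φ = V·Φ₁ of the unit
solution. The controller reaches the setpoint in ~3 s and holds it within
0.03 °C.

**PFA** applies 20 bursts at 1 Hz, each burst a 100 µs DC pulse at the burst
amplitude (the RMS equivalence of the biphasic waveform). The nonlinear
field is re-solved before each burst at the current temperature; during the
burst the Joule source is integrated at 25 µs steps, and the 1 s inter-burst
interval relaxes with geometrically growing steps capped at 50 ms. Per-burst
during-pulse peaks and end-of-pulse values of the blood and cardiac maxima
are recorded — the characteristic PFA signature of sharp intra-pulse spikes
decaying between bursts.

## Lesions and morphometry

Lesion criteria are applied to running maxima, so lesions never shrink: the
50 °C isotherm of the maximum-over-time temperature (RFA), the 1000 V/cm
contour of the maximum-over-bursts field magnitude (PFA), or Ω ≥ 1 of the
Arrhenius integral (collateral thermal damage in PFA, reported separately
and never added to the field-defined lesion). Field magnitudes are
element-wise; for morphometry they are volume-averaged to nodes over tissue
elements only, so the conductivity jump at the blood interface cannot
contaminate surface values.

Metrics are computed from the exact sub-element isosurface: the clipped
volume of each tetrahedron comes from the closed-form simplex
truncated-power formula (verified against Monte Carlo integration), and the
boundary point set from edge interpolation. Depth is reported in two
conventions: `depth_mm`, measured from the electrode contact plane (the
deepest point of the inserted catheter), and `depth_endocardial_mm` from the
undeformed endocardial plane z = 0; the two differ by the insertion depth.
The contact-plane number is primary because it reproduces the published
depth measurements across the whole velocity sweep (4.0/5.0/5.5 mm at
3/6/9 cm/s) and the published depth-matching calibration between modalities,
which the z = 0 convention misses by almost exactly the insertion depth.
Width is the maximum lesion caliper parallel to the endocardial plane
(convex hull diameter of the projected boundary set); for the bipolar array
the width of the transversal section at the array mid-plane (points within
0.75 mm of it) is reported as the published convention. The symmetry ratio
splits the clipped volume by the plane through the electrode centre normal
to the flow; straddling tetrahedra are split by deterministic barycentric
sampling renormalised to their exact clipped volume, so the two components
close to 100 % by construction.

## Verification fixtures

`make_analytic_fixture()` builds four independently solvable problems used
as oracles: a parallel-plate capacitor (uniform field, exact), a
hemispherical electrode on a half-space (Φ = V₀a/r, with the truncated far
boundary carrying the analytic potential so only discretization error
remains; L2 error < 2 % and monotone under refinement), 1-D step-heated
transient conduction (erfc profile within 2 %), and plane Poiseuille flow
(peak/mean = 1.5 ± 2 %). The Arrhenius accumulator is checked against its
constant-temperature closed form at 10⁻⁶.

## Problem sizes and study design

The reference morphometry uses the `fine` preset on half domains
(≈150k tetrahedra, nonlinear field solve ≈1–2 min); the full 30 s RFA
protocol runs at `coarse` (≈50k tetrahedra, 1500 control steps, ≈3 min
including the flow solve); sweeps reuse meshes across velocity points. These
sizes were chosen so the reference metrics are within a few percent of their
refinement limit (lesion-volume drift between successive presets stays under
~10 %) while a
full velocity sweep remains a desk-scale computation. Everything is
deterministic: identical configs give bit-identical traces (the recorded
seed only labels the scenario).

## What the model does and does not show

The slab-and-uniform-inflow geometry emulates the *local* environment of an
ablation site, not a beating chamber: one flow direction, laminar steady
flow, rigid tissue, isotropic properties, no contact-force mechanics, no
irrigation, no multi-sensor catheters. Within that scope the simulations
reproduce the published reference behaviour — equal-depth PFA lesions are
wider, larger and more symmetric than RFA lesions; RFA morphology depends
strongly on blood velocity (the temperature-controlled paradox: more cooling
→ more delivered power → larger lesions) while the PFA field, hence lesion,
is essentially velocity-independent; tilting the catheter grows PFA lesions
and shrinks RFA lesions.

Known quantitative limitations: the bipolar lesion depths hinge on the
unpublished ring-array dimensions (with the 4 mm/2 mm default the model
gives roughly twice the published bipolar depth); the peak blood temperature
sits at the singular electrode edge and is therefore resolution-dependent;
and steady-flow convergence at transitional Re is approximate as described
above.
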