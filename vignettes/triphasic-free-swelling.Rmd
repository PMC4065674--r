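---
title: "Triphasic free swelling of articular cartilage: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triphasic free swelling of articular cartilage: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Articular cartilage is modelled as a triphasic mixture: an intrinsically
incompressible, isotropic linear elastic solid matrix (collagen,
proteoglycans), interstitial water, and two monovalent mobile ion species
(Na⁺, Cl⁻). Glycosaminoglycan side chains carry covalently bound negative
charges — the fixed charge density (FCD) `cF`, expressed per fluid volume —
which force an excess of mobile counter-ions into the tissue. The resulting
imbalance in osmolarity between the interstitial fluid and the external bath
(Donnan equilibrium) pressurizes the tissue; a drop in bath salinity raises
that pressure difference and the sample swells against its matrix stiffness.

Four fields are solved per node: the solid displacement **u** and the
*modified* potentials of water and of each ion species,

* `eps_w = P/(RT) − Φ(c⁺ + c⁻) + (Bw/RT)·θ`
* `eps± = γ± c± exp(± Fc ψ / RT)`,

a transformation that eliminates the electrical potential `ψ` from the
solved system (it is recovered only as a diagnostic). The governing balances
are quasi-static mixture momentum, mixture mass, and one charge balance per
ion species including the convective transport of ions riding on the moving
solid (`Φw c± vs`), a coupling term that matters whenever the matrix moves
while carrying a non-trivial ion load. Constitutively,

* stress: `σ = −P I + λs θ I + 2 μs ε` (small strain, `θ = div u`),
* porosity: `Φw = 1 − φ0s/(1+θ)`,
* FCD dilution: `cF = c0F / (1 + θ/Φ0w)`,
* electroneutrality: `c⁺ − c⁻ = cF`, which with the potential definitions
  gives `c⁺` as the nonnegative root of
  `c⁺(c⁺ − cF) = eps⁺ eps⁻/(γ⁺γ⁻)`,
* fluxes: `Jw = −(RT Φw/α)(∇eps_w + (c⁺/eps⁺)∇eps⁺ + (c⁻/eps⁻)∇eps⁻)` and
  `J± = c± Jw − Φw D± (c±/eps±) ∇eps±`, where `α` is the solid–water drag
  (`k = Φw/α` is the permeability) and `D±` the ion diffusivities.

The flux law for `J⁺` is implemented in the form above, which follows from
the mixture momentum balances and is dimensionally consistent; it treats the
coefficient of `∇eps⁻` as `c⁺c⁻/eps⁻` (the symmetric counterpart of the
`J⁻` expression).

Two conventions anchor the gauges: the bath is at `P* = 0` and `ψ* = 0`, and
the free-swollen equilibrium with the *initial* bath is the reference
configuration — displacements are measured from it and only the pressure
increment `P − P_ref` (with `P_ref` the initial Donnan pressure) loads the
matrix. Both free-swelling experiments start from that state and step the
bath from 0.15 M to 0.125 M NaCl at `t = 0` with no ramp.

## Discretization and solution

Trilinear 8-node hexahedra with 2×2×2 Gauss integration discretize all four
fields. The weak form is the straightforward Galerkin statement of the four
balances: the water row combines `∫ δεw ∇·vs` with `−∫ ∇δεw · Jw`, each ion
row combines its storage term `∂t(Φw c±)` with its total (diffusive +
convective) flux, and no-flux walls are natural boundary conditions. Time
integration is Crank–Nicolson (weight 0.5 on the spatial terms, backward
difference for `vs`); each step is solved by Newton iteration.

Numerical choices worth knowing:

* **Tangent.** The Newton matrix is a consistent *numerical* tangent:
  element-level central differences of the element residual with per-field
  steps (1e-5 of the element height for displacements, 1e-5 of the initial
  bath concentration for potentials). Directional finite differences of the
  global residual agree with tangent–vector products to ~1e-13 relative, far
  inside the 1e-5 consistency contract, and the approach removes an entire
  class of hand-linearization defects in this strongly coupled system.
* **Scaling.** Unknowns are kept in SI units; instead of nondimensionalizing
  the fields, the linear solves equilibrate the tangent (columns scaled by
  per-field characteristic magnitudes — 1 µm, the initial bath
  concentration — rows to unit norm) before a direct sparse LU, and Newton
  convergence is declared on the equivalently scaled increment norm
  (default tolerance 1e-6, i.e. sub-picometre displacements). This is
  algebraically the same conditioning fix with less plumbing, and a direct
  solver is scale-invariant beyond that.
* **Stepping.** The bath step creates a thin boundary layer under the top
  surface, so the default schedule refines the start: `dt = 0.5 s` for the
  first 50 s, then `dt = 5 s` to 3600 s (≈810 steps). The tangent is
  refactorized lazily (every 25 steps, or whenever an attempt stalls);
  failed steps are retried with a fresh tangent and then halved down to a
  floor of 1 ms before the run aborts with the failing time reported.
  Halving the time step or doubling the mesh changes the peak displacement
  by well under 0.1%.
* **Boundary fluxes.** Reported surface fluxes are *consistent* (variational)
  fluxes — the unconstrained residual rows of the prescribed-potential top
  nodes — so the discrete water balance `d/dt ∫θ dV = influx` and ion
  balances `d/dt ∫Φw c± dV = total influx` close to solver tolerance
  (a per-run check; a direct face-quadrature evaluation is also available
  and agrees to a few percent). Note the conserved water quantity paired
  with the boundary flux is the water *volume* `∫(1+θ−φ0s) dV`, not
  `∫Φw dV`, whose increments differ by the factor `φ0s/(1+θ)²`.
* **Degenerate inputs.** Ion-potential products must stay nonnegative
  (guarded with invalid-state errors in the pointwise laws; non-finite
  assembly aborts the Newton attempt and triggers step halving), and
  dilatations at or below `θ = −1` or `θ = −Φ0w` are rejected as degenerate.

## Geometry, meshes and scenarios

The sample is a 0.5 mm high cylinder, 1.5 mm in diameter, confined in an
impermeable chamber: lateral walls and bottom block normal displacement
(laterally `ux = uy = 0`, bottom fully fixed) and carry no flux; only the
top face exchanges water and ions with the bath, where the three potentials
are prescribed to their bath values.

* The **quasi-1D validation** uses a single-element-wide column (cross
  section four orders of magnitude below the height, 50 elements in depth,
  204 nodes) with `ux = uy = 0` everywhere, and the ideal-solution parameter
  set (unit activity and osmotic coefficients, `E = 3.85e5` Pa, `ν = 0.28`,
  `α = 7e14` N·s·m⁻⁴, `D⁺ = 5e-10`, `D⁻ = 8e-10` m²/s, `c0F = 200` mol/m³,
  `Φ0w = 0.75`). Diffusivity units are taken as m²/s (the tabulated "m/s" is
  dimensionally impossible in the flux law) and mEq/mL converts to mol/m³
  ×1000 for monovalent ions. `Bw` has no published value and defaults to 0.
* The **full 3D scenario** keeps the sample height and replaces the circular
  cross-section by a square block of equal area. Under the confined boundary
  conditions the continuum solution is uniform in-plane (verified discretely
  to 1e-10), so in-plane resolution is free; the default block is 2×2×50.
  The published 3D mesh (760 elements, 1026 nodes) is not reconstructible
  from any structured block and its counts are not meaningful acceptance
  quantities here; the 204-node column is.
* **Sweeps** rerun the 3D scenario varying one parameter with a shared mesh:
  FCD `{200, 135, 110, 60}` mol/m³ (young healthy, aged healthy, and the two
  published degenerated values; a third pathological value was never named
  and can be supplied by the user), porosity `{0.70, 0.75, 0.78, 0.85}`
  (bracketing the physiological 75–78% range), osmotic coefficient
  `{0.6, 0.7, 0.8}` (0.8 physiological). The bath uses the tissue's own
  `γ±` and `Φ` (so the Donnan product is exactly `c*²`); unity-bath variants
  remain available through the bath-side arguments of `bath_potentials()`.

An independent scalar **oracle** cross-checks every run: at the final
confined equilibrium the dilatation is uniform and uniaxial, and traction
balance on the free face reduces to one equation,
`(λs + 2μs + Bw)·θ = RT·Φ·[√(cF(θ)² + 4c*₂²) − 2c*₂] − RT·Φ·[√(c0F² +
4c*₁²) − 2c*₁]`, solved by bracketed root finding on `θ ∈ (−Φ0w+10⁻⁶, 5)` to
1e-12. Every FEM plateau in the test suite agrees with it to well under 2%.

## Phase segmentation

The swelling response is segmented into the five canonical phases from the
computed series (thresholds configurable): Phase I ends when the top water
flux first exceeds 5% of its overall maximum; II ends at maximal water
influx; III ends when the displacement reaches 99% of its peak; IV ends when
all three fluxes drop below 1% of their maxima. Because the bath steps with
no ramp, the flux maximum occurs at the first stored step and Phases I–II
degenerate to the first instants — a faithful consequence of the step
boundary condition. Shrink-delay metrics record the most negative
displacement and the first time the displacement exceeds 1e-6 mm. The
reported "time of maximal deformation" is the *plateau onset* (first time
within 1% of the maximum): the trajectory is monotone to its plateau, so
the literal argmax would merely return the final time.

## What the computations show — and what they do not

With the healthy column parameters the package reproduces the published
quasi-1D behaviour quantitatively: peak displacement 0.0134 mm (published
0.013 mm; 0.0135 mm in the antecedent 1D study), plateau onset ≈1035 s
(published ≈900 s, antecedent 1000 s), and a 100 s cation profile of
≈273 mol/m³ at the bottom and ≈255 mol/m³ at the top (published 274/257).
The initial interior cation concentration is the Donnan value
280.28 mol/m³.

Three published 3D claims do **not** follow from the printed constitutive
laws, and this package reports what those laws give:

* The healthy 3D peak (published 0.143 mm for `c0F = 200` mol/m³ and
  0.0984 mm for 135) computes to 0.0118 / 0.0078 mm here — about 12× smaller
  — while agreeing with the independent equilibrium oracle to <0.1%. A
  small-strain confined Donnan balance cannot produce 0.143 mm at these
  parameters (that displacement implies θ ≈ 0.29, i.e. ≈140 kPa of extra
  osmotic pressure, an order of magnitude above the full Donnan step).
  Whatever unstated modelling choice produced the published magnitude
  (effective stiffness, lateral condition, strain measure) is deliberately
  not guessed at.
* The published degenerated-FCD displacements (≤1.7e-5 mm, three-plus orders
  below healthy) likewise conflict with any finite Donnan pressure change:
  the computed ratios are factors of 2–6, strictly ordered in `c0F`.
* The porosity trend: with `c0F` defined per fluid volume and held fixed,
  `Φ0w` enters the equilibrium only through the FCD-dilution denominator,
  so the plateau *rises* slightly with porosity (0.0114→0.0123 mm across
  0.70–0.85) and low porosity produces no shrink-delay, contrary to the
  published direction.

What does reproduce robustly in 3D: strict ordering of swelling with FCD,
and the initial shrink-delay for degenerated tissue — low FCD (and low
osmotic coefficient) weakens the osmotic inflow enough that the early
ion efflux through the top boundary layer transiently dehydrates the
sample (e.g. `c0F = 110`: minimum −0.0036 mm, positive swelling only after
≈370 s), which never happens at healthy FCD.

## Problem sizes and determinism

The defaults used throughout the tests and the acceptance script are the
50-element column (1224 dofs, ≈810 steps, a few seconds) and the 2×2×50
block (2754 dofs, ≈15 s); sweeps reuse one mesh per sweep. The solver has no
stochastic component: repeated runs are bit-identical, and the `seed`
element of `solver_config()` exists only as an interface placeholder.

## Limitations

Small-strain kinematics throughout (the computed dilatations of a few
percent are comfortably within range; the 0.143 mm published value would
not be); isotropic elasticity without proteoglycan-repulsion or fibril
anisotropy; two monovalent species only; isothermal; single bath step per
run (no multi-step salt schedules); structured uniform-brick meshes only.
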