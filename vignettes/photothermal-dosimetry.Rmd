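---
title: "Photothermal dosimetry for pulsed-laser scar therapy: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photothermal dosimetry for pulsed-laser scar therapy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`scartherm` simulates the thermal response of hypertrophic scar (HPS) and
normal skin to a single pulsed dye laser pulse and ranks clinical dose
parameters by their predicted therapeutic effect. This vignette is the
package's own account of the model: its assumptions, the parameters that
matter, the numerical choices, and — importantly — where the mechanistic
model and the published dose-response narrative it was built to reproduce
genuinely part ways. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The physical model

### Geometry

Skin is idealised as a cylinder, 20 mm in diameter and 4 mm deep, with a
single blood vessel simplified to a coaxial cylinder whose top face sits at
the irradiated surface: diameter 1.0 mm for HPS (scar vessels are dilated),
0.6 mm for normal skin, height 2.0 mm. Every model element — beam, vessel,
domain — is rotationally symmetric about the beam axis, so the problem is
solved in axisymmetric (r, z) coordinates on a cell-centred grid; a full 3-D
solve would return the same fields at far higher cost. z = 0 is the surface
and increases downward.

### Laser heat source

A clinical dose triple (energy density q, pulse width τ, spot diameter ω₀)
is converted to pulse energy W = q·s over the spot area s = π(ω₀/2)², power
P = W/τ, and on-axis peak flux Φ₀ = 2P/(πw²) with beam radius w = ω₀/2. The
volumetric heat source is separable:

Q(r, z, t) = μₐ(1 − R) Φ₀ · G(r) · A(z) · E(t)

with radial Gaussian G = exp(−2r²/w²) (the 1/e² profile whose peak is
exactly Φ₀), axial Beer–Lambert attenuation A = exp(−μₜ z), μₜ = μₐ + μₛ,
and temporal Gaussian envelope E = exp(−4(t − τ)²/τ²) centred on the pulse
width. Two conventions deserve comment:

* **Units of q.** Device panels label the energy density J/cm³, but
  W = q·s is only dimensionally consistent when q is an areal density
  (J/cm²), which also matches typical PDL clinical fluences of 4–10 J/cm².
  The numeric values are used as printed in W = q·s and the label is
  carried verbatim in `dose_params` output.
* **Literal factor variants.** Source formulations circulating in the
  applied literature sometimes print a dimensionally irregular radial term
  (exp(−0.5 r²/ω₀)) and a double-attenuated axial term
  (exp(−μₛz − μₜz), which counts scattering twice). Both are available
  behind `radial_form = "literal"` / `axial_form = "literal"` so the
  discrepancy against the regular forms is measurable; the defaults are the
  regular forms.

Note a structural identity: because s and πw² are both proportional to
ω₀², the on-axis flux reduces to Φ₀ = 2q/τ — *independent of spot
diameter*. Its consequences are discussed below.

An energy audit (`deposited_energy()`) integrates Q over domain and pulse.
Only the absorbed share μₐ/μₜ of the attenuated light becomes heat, so the
absorbed energy is a few percent of (1 − R)W for these highly scattering
tissues; the test suite checks the audit against a brute-force quadrature.

### Bioheat transfer

Temperature obeys the Pennes equation
ρc ∂T/∂t = ∇·(k∇T) + ρ_b c_b w_b (T_art − T) + Q, with blood parameters
ρ_b = 1000 kg/m³, c_b = 4180 J/(kg·K), perfusion rate w_b = 6.4×10⁻³ s⁻¹
and arterial temperature 37 °C. The irradiated surface exchanges heat with
25 °C ambient air through a film coefficient h; the lateral and deep
boundaries are held at 37 °C; the vessel–tissue interface is internal (flux
continuity, no explicit condition).

The published optical table stops at optics and blood parameters, so the
tissue thermophysics must be closed from standard dermal values:
ρ = 1200 kg/m³, c = 3600 J/(kg·K), k = 0.5 W/(m·K), identical for scar and
normal skin, and h = 10 W/(m²·K) (natural convection). These four closure
values are deliberately exposed (`closure_defaults()`, the `[closure]`
config section) because every simulated temperature depends on them;
`generate_fixtures("perturbed_materials")` emits configurations with ±15 %
perturbations for sensitivity studies. Vessel cells take blood density and
specific heat with the tissue's optics and conductivity — the minimal
assumption consistent with a tissue-level optical table. The perfusion sink
acts everywhere.

### Thermal damage

Irreversible injury follows first-order Arrhenius kinetics,
Ω(t) = ∫ A exp(−Eₐ/(R_gas T)) dt, with A = 4.575×10⁷² s⁻¹ (dimension 1/s
assumed; none is printed in the source literature) and Eₐ = 4.71×10⁵ J/mol.
The factor is evaluated in log space so 10⁷² never overflows. Burn degrees:
first at Ω = 0.58, second at 1.0, third at 10⁴.

Two volume summaries are reported per region (scar tissue, whole domain):

* `damaged_volume_fraction()` — the fraction of region volume with
  Ω ≥ threshold (default 1.0, the conventional coagulation criterion);
* `expected_damage_fraction()` — the volume-weighted mean of
  θ = 1 − e^(−Ω), the fraction of native tissue constituents already
  denatured under first-order kinetics.

The second exists for a quantitative reason. At the temperatures these
doses actually reach (peaks ≈ 43–54 °C), Ω stays below ~10⁻⁵ everywhere:
Ω = 1 at 52 °C would take on the order of 10³ s, not the 1 s horizon. A
hard-thresholded damaged volume is therefore identically zero across the
entire dose grid and cannot rank doses, whereas a smoothly accumulating
"proportion of thermal damage" — exactly what published damage-versus-time
curves show — is the natural reading of θ. `select_optimal()` consequently
uses the expected fraction as its default objective
(`objective = "threshold_fraction"` restores the hard threshold). The
expected fraction includes a dose-independent physiological baseline
(Ω ≈ 2×10⁻⁷ per second at 37 °C, accrued everywhere); it cancels in
comparisons between doses.

## Numerics

* **Discretisation.** Symmetric finite volumes: face conductances
  G = k_f·A_face/d with harmonic-mean face conductivity; annular volumes
  2πr·Δr·Δz. Dirichlet boundaries act through half-cell conductances, the
  surface through the series resistance of half cell and film. The
  manufactured-solution test verifies second-order spatial convergence of
  this operator, Robin boundary included.
* **Time stepping.** Backward Euler (unconditionally stable; the matrix is
  SPD and is Cholesky-factorised once per distinct step size). Steps are
  τ/40 while the envelope is active (to 3τ), then grow geometrically
  (ratio 1.25, capped at 50 ms) to the 1 s horizon, which the grid hits
  exactly. A forward-Euler scheme is kept for verification and refuses to
  run when its stability bound is violated.
* **Source on the grid.** The separable factors are averaged exactly over
  each annulus and depth interval (error-function-free closed forms), so
  the discrete energy deposit matches the analytic integral at any
  resolution.
* **Damage accumulation.** Trapezoidal in time at every solver step, not
  at snapshot cadence, because Ω is dominated by the brief peak-temperature
  window.
* **Resolution.** The optical deposition layer is thin (1/μₜ ≈ 81 µm for
  scar), so accuracy is governed by Δz near the surface while the beam
  (w = 2.5–3.5 mm) needs only moderate Δr. Default grid: Δr = 0.2 mm,
  Δz = 0.025 mm (50 × 160 cells, ~4 s per 1-s simulation on one core); the
  acceptance script uses Δz = 0.0125 mm for its single runs (peak changes
  by ~0.3 °C between the two, ~0.1 °C on further halving) and the default
  grid for its 27-run factorial, whose selection verdict is identical at
  both resolutions. Tests use coarser grids where only orderings matter.
* **Probe convention.** "Center temperature" is read at the axis cell that
  is hottest at the end of the pulse phase (in practice the surface cell);
  the probe depth is reported alongside.
* **Degenerate inputs.** Zero-energy doses give a zero source; empty dose
  grids, unknown presets, missing closure fields and non-physiologic
  temperatures are rejected with specific errors; the solver aborts if the
  field leaves [T_ambient − 1, 120] °C.

## What the simulations show — and where they diverge from the published account

With the default closure, the model reproduces the published temperature
benchmarks well: scar peak ≈ 51.1–51.5 °C at q = 10, τ = 4 ms, ω₀ = 7 mm
(reported: 52 °C), normal skin ≈ 38.7 °C (reported: 38.5 °C), scar ≈ 39.1 °C
one second after the pulse (reported: 40 °C). Scar heats an order of
magnitude more than normal skin at every dose, and both peak temperature
and damage grow monotonically with q — the selective-photothermolysis
contrast the therapy relies on.

Two published dose-response trends, however, are *not* reproducible from
the model equations, and the package reports what the equations actually
imply rather than the narrative:

* **Spot diameter.** Since Φ₀ = 2q/τ is spot-independent and radial
  conduction over ≤1 s spreads ~0.7 mm ≪ w, the on-axis temperature is
  essentially identical across ω₀ ∈ {5, 6, 7} mm (the model resolves a
  microscopic *increase* with spot size, ~0.03 °C). The published claim
  that central temperature falls with increasing spot diameter would
  require the delivered energy not to scale with spot area — contradicting
  W = q·s. The damage trend (larger spot → larger damaged fraction) *is*
  reproduced: a wider spot heats proportionally more volume.
* **Pulse width.** At fixed q the pulse energy is fixed and a shorter
  pulse simply deposits it with less conductive spreading, so the
  temperature history at every point is hottest for τ = 0.5 ms, and the
  Arrhenius integral — a monotone functional of the history — is largest
  there too (the model reproduces τ = 4 ms > τ = 10 ms, but not
  τ = 4 ms > τ = 0.5 ms). The published account that a 0.5 ms pulse causes
  "essentially no temperature rise" is incompatible with energy
  conservation under the model's own source term; no consistent reading of
  the printed equations (fixed P, fixed Φ₀, top-hat envelope) recovers
  both halves of the published pulse-width ordering.

These divergences propagate into the constrained dose selection. Over the
full factorial grid the admissible-candidate maximiser is
(q = 10, τ = 10 ms, ω₀ = 7 mm) — a combination outside the published
one-factor-at-a-time sweeps, whose peak (≈ 49.9 °C, stable under grid
refinement) sits just below the 50 °C threshold — rather than the published
optimum (7.5, 4 ms, 7 mm). Restricting to the published one-factor design
still selects τ = 0.5 ms over τ = 4 ms. The corresponding acceptance checks
are deliberately left failing rather than tuned: the package's claim is
fidelity to the stated model, not to every stated outcome. The spot
component (7 mm) and the q-exclusion of 10 J/cm² at the reference pulse
width (peak 51–52 °C > 50 °C) are reproduced.

## What the synthetic fixtures do and do not emulate

Fixture generation (`generate_fixtures()`) covers three needs: the default
YAML configuration (the published parameter set verbatim plus the
documented closure); closure perturbations for sensitivity analysis; and
binary collagen masks with exact positive fractions for the histology
metric, including the published reference levels (84 % untreated scar,
56 % normal skin). The masks are uniform random pixel fields: they validate
the counting identity and its invariances, but carry none of the spatial
correlation of real stained sections, so passing them says nothing about
segmentation quality — segmentation is explicitly upstream of this package.
Simulation inputs are not synthetic data in any statistical sense: the
pipeline is deterministic, and the only randomness in the repository lives
in fixture generation under a recorded seed.

## Known limitations

* Single homogeneous tissue layer; no epidermis/dermis/fat stratification,
  no vascular network, no temperature dependence of optical or thermal
  properties (optics are held constant during the pulse by design).
* The Beer–Lambert axial profile ignores scattering-driven fluence
  broadening; a transport or diffusion treatment would deposit energy
  deeper and less steeply.
* Single pulse only — no repetition, scanning or multi-pass protocols.
* The thermophysical closure is external to the published parameter set;
  absolute temperatures (and hence constraint verdicts near 50 °C) inherit
  its uncertainty, which is why the perturbed-material fixtures exist.
* Damage constants are tissue-generic; CEM43-style alternatives are out of
  scope.
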