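# scartherm

Quantitative photothermal dosimetry for pulsed dye laser (PDL) treatment of
hypertrophic scar (HPS).

Clinical selection of PDL dose parameters for scar therapy is largely
empirical. `scartherm` implements a mechanistic simulation chain that turns a
clinical dose triple — energy density *q*, pulse width *τ*, spot diameter
*ω₀* — into tissue temperature histories and thermal-damage estimates for
scar and for normal skin, and applies a constrained dose-selection rule:
maximise scar damage subject to a peak tissue temperature threshold (50 °C,
the onset of protein coagulation). It is aimed at researchers in laser–tissue
interaction and treatment planning who want a transparent, scriptable
alternative to GUI finite-element tools.

## Model

Three coupled components, solved on an axisymmetric cylindrical skin domain
(20 mm diameter × 4 mm deep) with a coaxial blood-vessel cylinder (diameter
1.0 mm for scar, 0.6 mm for normal skin, height 2.0 mm):

1. **Pulsed Gaussian heat source.** A single pulse deposits

   Q(r, z, t) = μₐ (1 − R) Φ₀ · exp(−2r²/w²) · exp(−μₜ z) · exp(−4(t − τ)²/τ²),

   with Φ₀ = 2P/(πw²) the on-axis peak flux of a Gaussian beam of radius
   w = ω₀/2, P = W/τ, W = q·s, s = π(ω₀/2)² the spot area, and
   μₜ = μₐ + μₛ the total attenuation (Beer–Lambert). Scar absorbs far more
   than normal skin (μₐ = 5.574 vs 1.395 cm⁻¹; R = 0.2 vs 0.58) — the basis
   of selective photothermolysis.

2. **Pennes bioheat transfer.**

   ρc ∂T/∂t = ∇·(k∇T) + ρ_b c_b w_b (T_art − T) + Q,

   discretised by a symmetric finite-volume scheme in (r, z) with implicit
   (backward Euler) adaptive time stepping; convective surface boundary
   (h = 10 W m⁻² K⁻¹ to 25 °C ambient), remaining boundaries fixed at 37 °C.

3. **Arrhenius thermal damage.** Ω(t) = ∫ A exp(−Eₐ/(R_gas T)) dt with
   A = 4.575×10⁷² s⁻¹ and Eₐ = 4.71×10⁵ J/mol, accumulated trapezoidally at
   every solver step; burn degrees at Ω = 0.58 / 1.0 / 10⁴, plus two
   damaged-volume summaries (hard-thresholded and expected fraction
   1 − e^(−Ω)).

A small histology utility computes the collagen-fiber area percentage from
binary segmentation masks (collagen area / tissue area × 100).

## Worked example

```r
library(scartherm)

g <- build_domain("hps")                  # 50 x 160 cells, dr 0.2 / dz 0.025 mm
d <- dose_params(10, 4, 7)                # q = 10, tau = 4 ms, spot = 7 mm
d
#> <dose_params> q = 10 J/cm^3 (as printed), tau = 4 ms, spot = 7 mm
#>   s = 0.38485 cm^2, W = 3.8485 J, P = 962.11 W, Phi0 = 5000 W/cm^2

res <- solve_transient(g, d)              # ~5 s on one core
res
#> <bioheat_result>
#>   dose  : q = 10, tau = 4 ms, spot = 7 mm (preset 'hps')
#>   peak  : 51.10 C at t = 0.007 s (probe depth 0.0125 mm)
#>   damage: max Omega 8.79e-06; expected scar fraction 2.2e-07 at t = 1 s
```

The probe is the hottest cell on the beam axis: the scar surface reaches
~51 °C and relaxes to ~39 °C one second after the pulse. The same dose on
`build_domain("normal_skin")` peaks at only ~38.7 °C — the scar/normal
contrast that makes PDL therapy selective. `run_sweep()` +
`select_optimal()` then scan the dose grid and apply the 50 °C-constrained
maximisation; `summary()` on the sweep gives one row per candidate.

A command-line wrapper with `simulate`, `sweep`, `select`, `report`,
`collagen-fraction` and `fixtures` subcommands is installed at
`inst/cli/scartherm`.

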