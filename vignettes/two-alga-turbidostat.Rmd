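---
title: "Methods: light competition and gas-exchange control in a two-alga turbidostat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: light competition and gas-exchange control in a two-alga turbidostat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(algaq)
```

This vignette is the package's own account of the science it implements:
the stoichiometric conventions, the competition model and its equilibrium
geometry, the numerical choices, and what the synthetic-data tests do and
do not establish about real cultures.

## 1. Gas-exchange stoichiometry

### The residue convention

Biomass gross formulas give the average elemental composition per fixed
carbon count, e.g. C6.0H9.7O2.635N0.937 for chlorella and
C6.0H10.84O2.06N0.87 for spirulina. Because the nitrogen loop is treated
as open (N arrives as ammonium or urea and is not respired), the nitrogen
is notionally removed from the formula with 3 H per N (as ammonia), and
the oxygen with 2 H per O (as water). The remainder is a pure
carbon–hydrogen residue CₙHₘ:

* chlorella: m = 9.7 − 3(0.937) − 2(2.635) = 1.619 ≈ 1.6,
* spirulina: m = 10.84 − 3(0.87) − 2(2.06) = 4.11 exactly.

Ammonia-style N removal is the default and the only implemented mode:
removal as urea would also carry away carbon and is inconsistent with a
six-carbon residue.

`o2_per_co2()` converts a residue into the volume of O₂ released per
volume of CO₂ absorbed (volumes and moles are interchangeable for ideal
gases). The default **residue convention** is

O₂ : CO₂ = 1 + m / (2n),

which credits one O₂ per two residue hydrogens on top of the equimolar
carbohydrate exchange. It reproduces the tabulated values to every printed
digit (1 + 1.6/12 = 1.13̄; 1 + 4.11/12 = 1.3425). The fully
oxygen-balanced photosynthesis equation would instead give 1 + m/(4n);
since spirulina's 1.3425 matches the half-rule to four decimals, the
residue convention is unambiguously the one used in this line of work, and
the balanced variant is available behind `convention = "balanced"` for
sensitivity analysis. The discrepancy between the two conventions is a
genuine ambiguity of the residue formalism and is deliberately left
visible rather than hidden.

### Rounding path

Tabulated values round at each stage. `aq_report()` mirrors this: round
the residue hydrogen (1 digit for chlorella, 2 for spirulina), round the
volume ratio (2 and 4 digits), then report AQ as the reciprocal of the
*rounded* ratio, to 3 decimals. The path matters: 1/1.13 = 0.885, while
the unrounded 1/1.1349 = 0.881. The package computes full-precision values
everywhere else; `aq_report()` exists precisely to reproduce tables.

### Mixtures and the respiratory side

The mixture quotient is the mass-fraction superposition
`mixture_aq(f, aq1, aq2)` = f·AQ₁ + (1−f)·AQ₂ — a convex combination, so
any achievable mixture AQ lies in [0.745, 0.885] for the default pair, and
`fraction_for_aq()` inverts it exactly. On the consumer side,
`respiratory_quotient()` evaluates the complete-oxidation balance
RQ = c/(c + h/4 − o/2) for nitrogen-free substrates: 1.0 for
carbohydrates, 16/23 ≈ 0.696 for palmitic acid. Amino-acid oxidation is
excluded as a first approximation, so formulas with N are rejected rather
than silently mishandled.

## 2. The competition model

### Equations

State: biomass concentrations x₁ (chlorella), x₂ (spirulina) in g/L.

* Light uptake is Michaelis–Menten in the *internal* illumination E:
  μᵢ(E) = μ_max,i E/(Kᵢ + E).
* Self-shading: optical depth τ = s₁x₁ + s₂x₂ (sᵢ in L/g, path length
  absorbed into sᵢ). The exact depth average of a Beer–Lambert profile is
  E = E₀(1 − e^(−τ))/τ; at low optical density its first-order Taylor
  truncation E = E₀(1 − τ/2) is used as the default
  (`light_model = "linearized"`). The exact form is retained
  (`"beer_lambert"`) to quantify the linearization error, which is bounded
  by E₀τ²/6.
* Dynamics: dxᵢ/dt = xᵢ(μᵢ(E) − D). In chemostat mode D is fixed. In
  turbidostat mode the measured variable is the optical density at 680 nm,
  OD₆₈₀ = c₁x₁ + c₂x₂ (cᵢ in L/g), and D is the exact algebraic servo
  value — the OD-weighted mean growth rate — which makes d(OD₆₈₀)/dt = 0
  identically. Below the setpoint the pump is off (batch fill-up); an
  overfilled initial state is diluted down to the setpoint instantaneously
  at t = 0. No lagged (PID-style) controller is modelled.

Two unit conventions matter and are kept distinct: *shading per gram*
(sᵢ) drives the physics, *OD₆₈₀ per gram* (cᵢ) drives the measurement and
the servo. An "OD units" preset (cᵢ ≡ 1) collapses the two.

### Equilibrium geometry

A coexistence steady state needs μ₁(E*) = μ₂(E*) = D*, so E* is pinned at
the crossover E_c = (μ_max,2 K₁ − μ_max,1 K₂)/(μ_max,1 − μ_max,2) of the
two growth curves (spirulina superior below E_c, chlorella above). With
linearized light this fixes the optical depth τ* = 2(1 − E_c/E₀), and the
stationary biomasses solve the 2×2 linear system

s₁x₁ + s₂x₂ = 2(1 − E_c/E₀),  c₁x₁ + c₂x₂ = C.

`coexistence_composition()` performs this solve and reports infeasibility
(a negative biomass; the operating point lies outside the region) as a
flag rather than an error, because region scans need the signed solution.
The closed form is validated in the tests against an independent dynamic
oracle: its output is a zero of the right-hand side and the integrated
system converges to it.

Eliminating the biomasses gives the geometry. For species i alone,
1/E₀ = 1/E_c − (sᵢ/(2cᵢE_c))·C — a straight line in (1/E₀, C). For a
fixed biomass ratio x₁/x₂ = r, the same elimination gives slope
−(s₁r + s₂)/(2(c₁r + c₂)E_c). All these lines share the intercept 1/E_c
at C = 0: the pencil point, where both biomasses vanish and the gas ratio
is moot. Because AQ depends only on the mass fractions, each pencil line
is also an iso-AQ line.

### Which boundary is on top, and stability

On the setpoint manifold the composition obeys
dx₁/dt = x₁ c₂x₂ (μ₁(E) − μ₂(E))/C. Perturbing toward chlorella at fixed
OD changes the optical depth by (s₁ − s₂c₁/c₂) per unit x₁. Coexistence is
locally stable iff **the high-light specialist shades more per unit
OD₆₈₀** (s₁/c₁ > s₂/c₂): extra chlorella then darkens the culture, which
favours spirulina and pushes the composition back. This is exactly the
"chlorella shadows spirulina" mechanism that makes the mixed culture
viable. A corollary worth stating: with s₁/c₁ > s₂/c₂ the *chlorella*
monoculture line is the lower boundary in (1/E₀, C)-ordinate C. Accounts
that place spirulina on the bottom implicitly use the opposite ordering,
which in this model is the unstable configuration; the package encodes the
stable one in its defaults and leaves the ordering to the parameters. The
tests verify both signs numerically (`stability_probe()` fits the
exponential decay/growth rate of a composition disturbance).

### The segment-division rule

To realize a target ratio r = x₁/x₂ at a given E₀, take the vertical
segment between the two boundary values of C. The exact division point,
measured from the species-2 (r = 0) end, has odds r·s₁/s₂ — independent
of the OD coefficients. The naive rule "divide the segment in the ratio
r" is exact only for equal shading per gram (s₁ = s₂), e.g. in OD units
with equal shading per OD. `segment_division_point()` returns both the
exact setpoint and the naive one so the discrepancy factor s₁/s₂ can be
inspected; `design_operating_point()` chains
`fraction_for_aq()` → ratio → exact setpoint and verifies the round trip
through the linear solve.

## 3. Fitting

`fit_michaelis_menten()` offers the double-reciprocal (Lineweaver–Burk)
line of 1/μ on 1/E and a Levenberg–Marquardt nonlinear fit on the original
scale, initialized from the reciprocal estimate. Both are exact on
noiseless data; under additive noise the reciprocal route inflates the
weight of low-rate points (a known bias), which the tests demonstrate by
simulation. Ordinary (unweighted) least squares is the default throughout;
weights may be supplied but no heteroscedastic error model is fitted.

Two "straightening" transforms for operating-point data are provided.
`fit_log_boundary()` fits the empirical C = K·ln(E₀) − const; since the
true boundary C = A(1 − E_c/E₀) is concave in ln E₀, this fit carries a
systematic error — it overestimates C at low and high illumination and
underestimates it in between. `residual_sign_pattern()` encodes that
qualitative statement robustly as the signs of the mean residuals
(observed − fitted) of the lower, middle and upper illumination thirds:
(−, +, −). The contrast is sampled on a *geometric* E₀ grid (uniform in
ln E₀), the natural design when "low/average/high illumination" are
multiplicative regimes; on a linear grid the sparse low end can leave the
first third's mean dominated by mid-range points.
`reciprocal_transform()` maps the same data to (1/E₀, C), where model
points are exactly straight (residual RMS at machine precision) and the
C = 0 intercept estimates 1/E_c.

## 4. Synthetic data and the calibrated scenario

No kinetic or optical parameters are tabulated for the original cultures,
so the generators define the study conditions once:

| parameter | chlorella | spirulina | units | basis |
|---|---|---|---|---|
| μ_max | 2.0 | 1.2 | 1/d | typical dense-culture doubling times; chlorella faster at saturation |
| K_E | 60 | 15 | E₀ units (nominally W/m²) | spirulina saturates at low light → crossover E_c = 52.5, common μ = 0.9333/d |
| shade s | 2.5 | 0.8 | L/g | chlorella the stronger shader |
| OD₆₈₀ c | 2.0 | 2.5 | L/g | order of magnitude of algal OD per g/L |
| AQ | 0.885 | 0.745 | – | from the gross formulas (§1) |

The shade/OD pairs satisfy the stability condition s₁/c₁ > s₂/c₂ with a
composition relaxation time of ≈ 10 days at the default operating point —
a realistic equilibration scale for turbidostat experiments and short
enough that convergence studies are cheap. `default_scenario()` fixes
E₀ = 120 and calibrates the OD₆₈₀ setpoint (C = 1.3599) so the stationary
chlorella mass fraction is 0.6, hence mixture AQ = 0.829; the same
scenario ships as YAML/JSON under `inst/extdata/`.

`generate_monoculture_data()` adds i.i.d. Gaussian noise (σ = 0.05 /d by
default, ~3–5 % of the plateau rates) to μ(E) on a 10-point illumination
grid from 15 to 240, clipped at zero; `generate_steady_state_survey()`
tabulates classified outcomes and noisy observations over an operating
grid. All generators are pure functions of (arguments, seed) and restore
the caller's RNG state.

What the synthetic fixtures emulate — Michaelis–Menten light response with
additive noise, exact model steady states — and what they do not:
photoinhibition of spirulina at high light, metabolic self-inhibition at
high density, spectral niche separation, instrument-specific OD or
gas-analyzer error structure, and any departure of real growth kinetics
from Michaelis–Menten form. Passing tests therefore validate the
implementation and the internal consistency of the theory, not its
adequacy for any particular cultivator; the model itself should not be
extrapolated to high illumination and high density, where the neglected
effects are known to matter.

## 5. Numerical choices

* **Integration**: `deSolve::ode` (lsoda), default rtol 1e−8
  (simulation) / 1e−10 (steady-state search and probes), atol three
  decades tighter. The turbidostat switch (fill-up → servo) is a
  discontinuity in D; lsoda handles it, but cross-checks against
  fixed-step references start on the setpoint manifold where the
  right-hand side is smooth.
* **Steady-state search**: integrate in 50-day chunks until
  max |dx/dt| < 1e−10 g/L/d (cap 2000 d); a species below 1e−6 g/L is
  classed extinct. Outcome classification is tolerance-robust (checked
  over two decades of rtol).
* **Stability probe**: perturb x₁ by the requested relative magnitude,
  counter-adjust x₂ to stay on the setpoint; fit log|Δx₁| against time
  while the deviation stays within 5× its initial size (so unstable
  runs are fitted in their exponential phase, before saturation);
  R² < 0.98 flags a non-exponential transient. A zero-magnitude probe
  returns trivially with rate 0.
* **Degeneracies**: equal shade/OD ratios make the stationary solve
  singular (the two boundaries coincide) and raise an explicit error;
  identical growth curves, equal μ_max, and no positive crossover raise
  distinct errors from `crossover_illumination()`. τ ≥ 2 is rejected by
  the linearized light model (it would mean non-positive illumination);
  note τ* = 2(1 − E_c/E₀) < 2 at every equilibrium, so the bound binds
  only for transients or pathological states.
* **Extinction absorbing states**: the right-hand side clamps negative
  biomasses to zero, making xᵢ = 0 exactly absorbing without event
  handling.
* **Problem sizes**: test-suite simulation studies use 40–200 replicate
  fits, 10×10 equilibrium grids and ≤ 3000-day integrations — desk-scale
  choices that keep the full suite under a minute while leaving the
  statistical margins (e.g. the 5 % recovery check, passed at ~0.5 %
  observed bias) wide.

## 6. Known limitations

* The linearized light model is the design basis; results degrade as
  τ → 2 even though the equilibria remain formally inside the valid range.
* The turbidostat servo is ideal (instantaneous, noise-free); sensor lag
  and dilution-pump quantization are out of scope.
* The mixture-AQ superposition assumes each species holds a fixed
  composition and AQ across operating points; shifting AQ via nitrogen
  nutrition is explicitly not modelled.
* `fit_michaelis_menten()` reports asymptotic standard errors from the
  nonlinear fit only; the reciprocal route's errors are not propagated.
* Stability is assessed numerically (probe + sign analysis), not by a
  symbolic eigenvalue proof.
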