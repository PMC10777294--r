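# algaq

Design and analysis tools for a mixed continuous culture of two microalgae
— *Chlorella vulgaris* and *Spirulina platensis* — operated as the oxygen
generator of a closed life support system (LSS).

A human crew's respiratory quotient (CO₂ released : O₂ consumed) ranges
from about 0.7 on fat oxidation to 1.0 on carbohydrate, so the algal
compartment must offer a matching, *tunable* assimilation quotient
AQ = CO₂ absorbed : O₂ released. A chlorella monoculture provides
AQ = 0.885, a spirulina monoculture 0.745; a stably coexisting mixed
culture interpolates between the two through its composition. This package
implements the whole control chain:

1. **Stoichiometry.** From the elemental gross formulas of biomass
   (per 6 C), nitrogen is notionally removed as ammonia (3 H per N) and
   oxygen as water (2 H per O), leaving a CₙHₘ residue. The volume of O₂
   released per volume of CO₂ absorbed is 1 + m/(2n), and AQ is its
   reciprocal. The mixture value is the mass-fraction superposition
   AQ = f·AQ₁ + (1 − f)·AQ₂, invertible to find the composition for a
   target AQ.
2. **Competition model.** A turbidostat (dilution servo-controlled to hold
   optical density at 680 nm constant) with two species competing for
   light:

   dxᵢ/dt = xᵢ (μᵢ(E) − D),  μᵢ(E) = μ_max,i E / (K_i + E),
   E = E₀ (1 − τ/2),  τ = s₁x₁ + s₂x₂,

   where E is the depth-averaged internal illumination under linearized
   self-shading. Coexistence pins E at the crossover E_c of the two growth
   curves, yielding closed-form stationary compositions.
3. **Geometry.** In (1/E₀, C) coordinates — inverse illumination against
   the OD₆₈₀ setpoint — the monoculture boundaries of the coexistence
   region and every constant-ratio (hence constant-AQ) locus are straight
   lines through the single point (C = 0, 1/E₀ = 1/E_c), where both
   biomasses vanish. This makes operating-point design a ruler-and-pencil
   exercise, and the package contrasts it with the tempting but
   systematically biased empirical straightening C = K·ln(E₀) − const.
4. **Fitting & synthetic data.** Michaelis–Menten fits of monoculture
   light-response data (Levenberg–Marquardt, initialized from the
   double-reciprocal line), seeded generators for noisy monoculture and
   steady-state survey data, and a simulator for convergence and stability
   probing.

## Worked example

```r
library(algaq)

aq_report("C6.0H9.7O2.635N0.937", h_digits = 1, ratio_digits = 2)
#> $residue
#> <residue> C6 H1.6
#> $o2_per_co2
#> [1] 1.13
#> $aq
#> [1] 0.885
```

One absorbed litre of CO₂ releases 1.13 L of O₂ during chlorella biomass
synthesis, i.e. AQ = 0.885 (the spirulina formula gives 1.3425 L and
0.745).

```r
sc <- default_scenario()
sc
#> Calibrated two-alga turbidostat scenario
#> <cultivator> turbidostat, E0=120, OD680 setpoint C=1.35989, light=linearized
#> <equilibrium> x1=0.370879, x2=0.247253 g/L  (E*=52.5, D*=0.9333 /d)
#>   at E0=120, C=1.35989;  mixture AQ=0.829;  feasible: TRUE
```

The shipped scenario holds a 60:40 chlorella:spirulina culture (by mass),
so the mixture AQ is 0.6·0.885 + 0.4·0.745 = 0.829. Suppose the crew's
diet shifts and the LSS now needs AQ = 0.80 at the same lamp setting:

```r
dp <- design_operating_point(sc$model, aq_target = 0.80, e0 = 120)
dp$equilibrium
#> <equilibrium> x1=0.301095, x2=0.465328 g/L  (E*=52.5, D*=0.9333 /d)
#>   at E0=120, C=1.76551;  mixture AQ=0.8;  feasible: TRUE
```

Raising the OD₆₈₀ setpoint from 1.36 to 1.77 shifts the culture toward
spirulina and delivers the target quotient. The operating point is locally
stable — a 20 % composition disturbance decays exponentially:

```r
stability_probe(sc$model, sc$truth, magnitude = 0.2)[c("rate", "returned")]
#> $rate
#> [1] -0.1044    # 1/day; negative = stable
#> $returned
#> [1] TRUE
```

A thin command-line wrapper over the same functions ships in
`inst/cli/algaq` (subcommands `aq`, `mix`, `invert`, `fit`, `region`,
`design`, `simulate`, `synth`); see `?algaq_cli`.

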