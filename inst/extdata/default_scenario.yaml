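# calibrated two-alga turbidostat scenario (kinetic/optical values are
# package defaults, not measured parameters; AQ values from the biomass
# gross formulas)
species:
  - name: chlorella
    mu_max: 2.0
    k_e: 60.0
    shade: 2.5
    od680: 2.0
    aq: 0.885
  - name: spirulina
    mu_max: 1.2
    k_e: 15.0
    shade: 0.8
    od680: 2.5
    aq: 0.745
cultivator:
  e0: 120.0
  c_set: 1.35989010989010989
  mode: turbidostat
  light_model: linearized
seed: 0
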