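Package: algaq
Title: Gas-Exchange Stoichiometry and Light-Competition Modelling for
    Two-Alga Oxygen Generators
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and analysing a mixed continuous culture of
    two microalgae (Chlorella vulgaris and Spirulina platensis) used as the
    oxygen generator of a closed life support system.  Computes assimilation
    quotients from elemental gross formulas of biomass via a carbon-hydrogen
    residue convention, models light competition in a turbidostat with a
    two-species Michaelis-Menten system under linearized self-shading,
    derives the coexistence region and the pencil of constant-composition
    (constant assimilation quotient) lines in inverse-illumination
    coordinates, designs operating points for a target assimilation
    quotient, fits monoculture growth kinetics, and generates seeded
    synthetic data sets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
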