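# shared fixtures, built in code
chlorella_formula <- "C6.0H9.7O2.635N0.937"

list_residue <- function(n_c, m_h) {
  structure(list(n_c = n_c, m_h = m_h), class = "biomass_residue")
}
spirulina_formula <- "C6.0H10.84O2.06N0.87"

fix_scenario <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- default_scenario()
    memo
  }
})

fix_model <- function() fix_scenario()$model

# boundary points of the species-1 (chlorella) monoculture locus on a
# geometric illumination grid spanning low to high light
boundary_points <- function(model = fix_model(), species = 1, n = 20,
                            from = 60, to = 300) {
  b <- region_boundaries(model)
  e0 <- exp(seq(log(from), log(to), length.out = n))
  data.frame(e0 = e0, c = (1 / e0 - b$intercept[species]) / b$slope[species])
}
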