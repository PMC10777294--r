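test_that("crossover illumination is the closed-form curve intersection", {
  m <- fix_model()
  cr <- crossover_illumination(m)
  expect_equal(cr$e_c, 52.5)
  expect_equal(cr$mu_c, growth_rate(52.5, m$species[[1]]))
  expect_equal(growth_rate(cr$e_c, m$species[[1]]),
               growth_rate(cr$e_c, m$species[[2]]))
  # equal mu_max: curves only meet at saturation
  expect_error(crossover_illumination(alga_species("a", 2, 60, 1),
                                      alga_species("b", 2, 15, 1)),
               "equal mu_max")
  # identical parameters: degenerate
  expect_error(crossover_illumination(alga_species("a", 2, 60, 1),
                                      alga_species("b", 2, 60, 1)),
               "degenerate")
  # one species dominant at every light level: competitive exclusion
  expect_error(crossover_illumination(alga_species("a", 2, 15, 1),
                                      alga_species("b", 1.2, 60, 1)),
               "no coexistence")
})

test_that("stationary composition solves the turbidostat fixed point", {
  sc <- fix_scenario()
  eq <- sc$truth
  expect_true(eq$feasible)
  expect_equal(eq$x1 / eq$x2, 1.5, tolerance = 1e-12)   # 0.6 mass fraction
  expect_equal(eq$aq, 0.829, tolerance = 1e-12)
  expect_equal(eq$e_star, 52.5)
  expect_equal(eq$d_star, growth_rate(52.5, sc$model$species[[1]]))
  # oracle equivalence: the point is a zero of the dynamic rhs
  r <- model_rhs(eq$x1, eq$x2, sc$model)
  expect_lt(max(abs(r$dx)), 1e-9)
  # boundary query recovers a monoculture
  b <- region_boundaries(sc$model)
  e0 <- 150
  c_on_1 <- (1 / e0 - b$intercept[1]) / b$slope[1]
  eq1 <- coexistence_composition(sc$model, e0 = e0, c_set = c_on_1)
  expect_equal(eq1$x2, 0, tolerance = 1e-12)
  expect_true(eq1$feasible)
  # outside the region: infeasible with one negative biomass, not an error
  eq_out <- coexistence_composition(sc$model, e0 = e0, c_set = c_on_1 * 0.5)
  expect_false(eq_out$feasible)
  expect_true(xor(eq_out$x1 < 0, eq_out$x2 < 0))
  # degenerate geometry: shade/od ratios equal
  mdeg <- competition_model(alga_species("a", 2, 60, 1, od680 = 2),
                            alga_species("b", 1.2, 15, 0.5, od680 = 1))
  expect_error(coexistence_composition(mdeg, e0 = 150, c_set = 1),
               "degenerate geometry")
})

test_that("feasible equilibria satisfy the equal-growth fixed point on a grid", {
  m <- fix_model()
  for (e0 in c(70, 120, 200)) {
    sb <- algaq:::segment_bounds(m, e0)
    for (f in c(0.1, 0.5, 0.9)) {
      eq <- coexistence_composition(m, e0,
                                    sb$lower + f * (sb$upper - sb$lower))
      expect_true(eq$feasible)
      expect_lt(abs(growth_rate(eq$e_star, m$species[[1]]) - eq$d_star), 1e-9)
      expect_lt(abs(growth_rate(eq$e_star, m$species[[2]]) - eq$d_star), 1e-9)
      expect_gte(eq$aq, 0.745); expect_lte(eq$aq, 0.885)
    }
  }
})

test_that("boundary lines share the 1/E_c intercept and bound the region", {
  m <- fix_model()
  b <- region_boundaries(m)
  expect_equal(b$intercept, rep(1 / 52.5, 2))
  # points on each boundary yield the corresponding pure monoculture
  for (i in 1:2) {
    e0 <- 180
    cs <- (1 / e0 - b$intercept[i]) / b$slope[i]
    eq <- coexistence_composition(m, e0 = e0, c_set = cs)
    other <- if (i == 1) eq$x2 else eq$x1
    expect_equal(other, 0, tolerance = 1e-10)
  }
  # along either boundary C grows as 1/E0 falls (more light, more biomass)
  e0s <- seq(60, 400, length.out = 30)
  for (i in 1:2) {
    cs <- (1 / e0s - b$intercept[i]) / b$slope[i]
    expect_true(all(diff(cs) > 0))
  }
  # coincident lines when shade/od ratios are equal
  mdeg <- competition_model(alga_species("a", 2, 60, 1, od680 = 2),
                            alga_species("b", 1.2, 15, 0.5, od680 = 1))
  bdeg <- region_boundaries(mdeg)
  expect_equal(bdeg$slope[1], bdeg$slope[2])
})

test_that("iso-ratio lines form a pencil through the washout point", {
  m <- fix_model()
  b <- region_boundaries(m)
  # limits recover the two boundaries
  expect_equal(iso_ratio_line(m, 0)$slope, b$slope[2])
  expect_equal(iso_ratio_line(m, Inf)$slope, b$slope[1])
  slopes <- range(b$slope)
  for (r in c(0, 0.25, 1, 1.5, 4, Inf)) {
    l <- iso_ratio_line(m, r)
    expect_equal(l$intercept, 1 / 52.5, tolerance = 1e-12)
    expect_gte(l$slope, slopes[1]); expect_lte(l$slope, slopes[2])
  }
  # AQ is constant along a line: probe 5 points on the r = 1.5 line
  l <- iso_ratio_line(m, 1.5)
  for (cs in seq(0.4, 2, length.out = 5)) {
    e0 <- 1 / (l$intercept + l$slope * cs)
    eq <- coexistence_composition(m, e0 = e0, c_set = cs)
    expect_true(eq$feasible)
    expect_equal(eq$x1 / eq$x2, 1.5, tolerance = 1e-9)
    expect_equal(eq$aq, l$aq, tolerance = 1e-12)
  }
})

test_that("segment division yields the requested stationary ratio", {
  m <- fix_model()
  for (e0 in c(80, 120, 220)) {
    for (r in c(0, 0.5, 1.5, 4, Inf)) {
      seg <- segment_division_point(m, e0, r)
      eq <- coexistence_composition(m, e0 = e0, c_set = seg$c_set)
      expect_true(eq$feasible)
      if (r == 0) expect_equal(eq$x1, 0, tolerance = 1e-10)
      else if (is.infinite(r)) expect_equal(eq$x2, 0, tolerance = 1e-10)
      else expect_equal(eq$x1 / eq$x2, r, tolerance = 1e-9)
    }
  }
  # the naive equal-units division differs by the shading ratio factor
  s <- m$species
  r <- 2
  seg <- segment_division_point(m, 120, r)
  expect_equal(seg$division_odds / seg$naive_odds, s[[1]]$shade / s[[2]]$shade)
  # ... and coincides with the exact rule when shading per unit is equal
  mu <- competition_model(alga_species("a", 2, 60, 1, od680 = 1, aq = 0.885),
                          alga_species("b", 1.2, 15, 1, od680 = 2, aq = 0.745))
  segu <- segment_division_point(mu, 120, r)
  expect_equal(segu$c_set, segu$naive_c_set, tolerance = 1e-12)
  equ <- coexistence_composition(mu, e0 = 120, c_set = segu$naive_c_set)
  expect_equal(equ$x1 / equ$x2, r, tolerance = 1e-9)
  # below the crossover illumination there is no segment
  expect_error(segment_division_point(m, 40, 1), "no coexistence segment")
})

test_that("operating-point design hits the target assimilation quotient", {
  m <- fix_model()
  dp <- design_operating_point(m, 0.829, e0 = 120)
  expect_equal(dp$equilibrium$aq, 0.829, tolerance = 1e-9)
  expect_equal(dp$equilibrium$x1 / (dp$equilibrium$x1 + dp$equilibrium$x2),
               0.6, tolerance = 1e-9)
  # pure-species targets give monocultures on the boundaries
  dp1 <- design_operating_point(m, 0.885, e0 = 120)
  expect_equal(dp1$equilibrium$x2, 0, tolerance = 1e-10)
  dp2 <- design_operating_point(m, 0.745, e0 = 120)
  expect_equal(dp2$equilibrium$x1, 0, tolerance = 1e-10)
  expect_error(design_operating_point(m, 0.95, e0 = 120), "achievable range")
  expect_error(design_operating_point(m, 0.829, e0 = 30), "no coexistence")
})

test_that("chemostat monoculture closed form handles washout edges", {
  chl <- fix_model()$species[[1]]
  expect_true(monoculture_steady_state(chl, 100, d = 2.5)$washout)
  expect_true(monoculture_steady_state(chl, 100, d = 2.0)$washout)
  # marginal washout at the zero-density growth rate
  d_star <- chl$mu_max * 100 / (chl$k_e + 100)
  ms <- monoculture_steady_state(chl, 100, d = d_star)
  expect_equal(ms$x_star, 0)
  expect_equal(ms$e_star, 100)
  # interior case matches the closed form
  ms2 <- monoculture_steady_state(chl, 100, d = 0.5)
  e_star <- chl$k_e * 0.5 / (chl$mu_max - 0.5)
  expect_equal(ms2$e_star, e_star)
  expect_equal(ms2$x_star, 2 * (1 - e_star / 100) / chl$shade)
})
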