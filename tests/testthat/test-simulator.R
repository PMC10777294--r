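test_that("an equilibrium initial state stays put", {
  sc <- fix_scenario()
  tr <- simulate(sc$model, init = c(x1 = sc$truth$x1, x2 = sc$truth$x2),
                 t_end = 100, tol = 1e-10)
  expect_lt(max(abs(tr$x1 - sc$truth$x1)), 1e-6)
  expect_lt(max(abs(tr$x2 - sc$truth$x2)), 1e-6)
  expect_true(all(diff(tr$t) > 0))
})

test_that("turbidostat trajectories conserve OD680 at the setpoint", {
  sc <- fix_scenario()
  cset <- sc$model$cultivator$c_set
  # several compositions, all placed on the setpoint manifold
  for (f in c(0.2, 0.5, 0.8)) {
    x1 <- f * cset / sc$model$species[[1]]$od680
    x2 <- (1 - f) * cset / sc$model$species[[2]]$od680
    tr <- simulate(sc$model, init = c(x1 = x1, x2 = x2), t_end = 60,
                   tol = 1e-10)
    expect_lt(max(abs(tr$od680 - cset)) / cset, 1e-6)
    expect_true(all(tr$x1 > -1e-12 & tr$x2 > -1e-12))
  }
})

test_that("an overfilled start is diluted to the setpoint, then conserved", {
  sc <- fix_scenario()
  cset <- sc$model$cultivator$c_set
  tr <- simulate(sc$model, init = c(x1 = 2, x2 = 2), t_end = 20, tol = 1e-10)
  expect_lt(max(abs(tr$od680 - cset)) / cset, 1e-6)
})

test_that("adaptive result matches a step-halved fixed-step reference", {
  sc <- fix_scenario()
  # start on the OD setpoint manifold so the servo is engaged throughout
  # (the fixed-step reference has no event handling for the fill-up switch)
  cset <- sc$model$cultivator$c_set
  init <- c(x1 = 0.55 * cset / sc$model$species[[1]]$od680,
            x2 = 0.45 * cset / sc$model$species[[2]]$od680)
  tr <- simulate(sc$model, init = init, t_end = 30, n_out = 31, tol = 1e-10)
  rk_fixed <- function(h) {
    y <- init; out <- matrix(NA_real_, 31, 2); out[1, ] <- y
    f <- function(y) model_rhs(y[1], y[2], sc$model)$dx
    steps_per_out <- round(1 / h)
    for (i in 2:31) {
      for (s in seq_len(steps_per_out)) {
        k1 <- f(y); k2 <- f(y + h / 2 * k1)
        k3 <- f(y + h / 2 * k2); k4 <- f(y + h * k3)
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      out[i, ] <- y
    }
    out
  }
  a <- rk_fixed(0.02)
  b <- rk_fixed(0.01)
  # the reference is itself converged (halving the step changes nothing)
  expect_lt(max(abs(a - b)), 1e-6)
  expect_lt(max(abs(cbind(tr$x1, tr$x2) - b)), 1e-4)
})

test_that("steady-state search reproduces the algebraic equilibrium", {
  sc <- fix_scenario()
  fs <- find_steady_state(sc$model, init = c(x1 = 0.05, x2 = 0.05))
  expect_equal(fs$outcome, "coexistence")
  expect_true(fs$converged)
  expect_lt(abs(fs$x1 - sc$truth$x1), 1e-6)
  expect_lt(abs(fs$x2 - sc$truth$x2), 1e-6)
  expect_equal(fs$d, sc$truth$d_star, tolerance = 1e-6)
})

test_that("outcome classification covers dominance, washout, and tolerance", {
  sc <- fix_scenario()
  s <- sc$model$species
  # operating point in the species-1 dominance zone (below its boundary)
  b <- region_boundaries(sc$model)
  e0 <- 150
  c1_line <- (1 / e0 - b$intercept[1]) / b$slope[1]
  m1 <- competition_model(s[[1]], s[[2]],
                          cultivator(e0 = e0, c_set = 0.5 * c1_line))
  f1 <- find_steady_state(m1, init = c(x1 = 0.02, x2 = 0.02), t_max = 1500)
  expect_equal(f1$outcome, "monoculture-1")
  # insufficient light at fixed dilution: both species wash out
  cfg <- cultivator(e0 = 40, d = growth_rate(52.5, s[[1]]), mode = "chemostat")
  mw <- competition_model(s[[1]], s[[2]], cfg)
  fw <- find_steady_state(mw, init = c(x1 = 0.1, x2 = 0.1), t_max = 600)
  expect_equal(fw$outcome, "washout")
  # classification is robust to integrator tolerance over two decades
  f_loose <- find_steady_state(m1, init = c(x1 = 0.02, x2 = 0.02),
                               t_max = 1500, tol = 1e-8)
  expect_equal(f_loose$outcome, f1$outcome)
})

test_that("the default coexistence equilibrium is locally stable", {
  sc <- fix_scenario()
  pr <- stability_probe(sc$model, sc$truth, magnitude = 0.2)
  expect_lt(pr$rate, 0)
  expect_true(pr$returned)
  expect_true(pr$exponential)
  # zero perturbation returns trivially
  pr0 <- stability_probe(sc$model, sc$truth, magnitude = 0)
  expect_true(pr0$returned)
})

test_that("inverting the shading/OD ratios destabilizes coexistence", {
  sc <- fix_scenario()
  s <- sc$model$species
  # swap the shade coefficients: now the low-light species shades more
  # per unit OD680, so composition disturbances are self-amplifying
  a <- alga_species("a", s[[1]]$mu_max, s[[1]]$k_e, shade = 0.8,
                    od680 = s[[1]]$od680, aq = s[[1]]$aq)
  b <- alga_species("b", s[[2]]$mu_max, s[[2]]$k_e, shade = 2.5,
                    od680 = s[[2]]$od680, aq = s[[2]]$aq)
  pre <- competition_model(a, b)
  seg <- segment_division_point(pre, 120, r = 1.5)
  m <- competition_model(a, b, cultivator(e0 = 120, c_set = seg$c_set))
  eq <- coexistence_composition(m)
  expect_true(eq$feasible)
  pr <- stability_probe(m, eq, magnitude = 0.05, t_end = 40)
  expect_gt(pr$rate, 0)
  expect_false(pr$returned)
})

test_that("chemostat monoculture trajectories reach the closed form", {
  s <- fix_model()$species
  cfg <- cultivator(e0 = 100, d = 0.5, mode = "chemostat")
  m <- competition_model(s[[1]], s[[2]], cfg)
  ms <- monoculture_steady_state(s[[1]], 100, 0.5)
  fs <- find_steady_state(m, init = c(x1 = 0.05, x2 = 0), t_max = 1000)
  expect_equal(fs$outcome, "monoculture-1")
  expect_lt(abs(fs$x1 - ms$x_star) / ms$x_star, 1e-4)
})
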