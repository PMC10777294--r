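#' Generate synthetic monoculture growth measurements
#'
#' Emulates a monoculture light-response experiment: specific growth rates
#' on an illumination grid following the species' Michaelis-Menten curve
#' with additive Gaussian noise, clipped at zero.  Deterministic given
#' `(arguments, seed)`.
#'
#' @param sp An [alga_species()].
#' @param e_grid Illumination levels (default: 10 levels from 15 to 240,
#'   spanning well below and above typical half-saturation values).
#' @param sigma Noise standard deviation on the rate (1/day; default 0.05).
#' @param seed Integer seed.
#' @return Data frame with columns `illumination` and `growth_rate`.
#' @export
generate_monoculture_data <- function(sp,
                                      e_grid = seq(15, 240, length.out = 10),
                                      sigma = 0.05, seed = 0) {
  stopifnot(length(e_grid) >= 1L, all(e_grid > 0), sigma >= 0)
  mu <- growth_rate(e_grid, sp)
  if (sigma > 0) {
    mu <- withr_seed(seed, mu + stats::rnorm(length(mu), 0, sigma))
    mu <- pmax(mu, 0)
  }
  data.frame(illumination = e_grid, growth_rate = mu)
}

# evaluate expr-with-RNG under a local seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' The calibrated default two-species scenario
#'
#' A ready-made chlorella + spirulina turbidostat scenario.  The
#' assimilation quotients (0.885 and 0.745) come from the biomass gross
#' formulas via [aq_report()]; the kinetic and optical parameters are
#' package defaults chosen to satisfy the qualitative constraints of the
#' system (spirulina superior at low light, chlorella at high light, and
#' chlorella shading more per unit OD680 so that coexistence is stable) --
#' they are not measured values.  The OD680 setpoint is calibrated so that
#' the stationary chlorella mass fraction is 0.6, hence mixture AQ
#' = 0.6*0.885 + 0.4*0.745 = 0.829.
#'
#' @param e0 Incident illumination of the scenario (default 120).
#' @param seed Seed recorded in the fixture (default 0).
#' @return List of class `scenario_fixture`: `model` (a
#'   [competition_model()] with the calibrated cultivator attached), `truth`
#'   (the stationary [coexistence_composition()]), and `seed`.
#' @examples
#' sc <- default_scenario()
#' sc$truth$aq   # 0.829
#' @export
default_scenario <- function(e0 = 120, seed = 0) {
  chl <- alga_species("chlorella", mu_max = 2.0, k_e = 60,
                      shade = 2.5, od680 = 2.0,
                      aq = aq_report("C6.0H9.7O2.635N0.937",
                                     h_digits = 1, ratio_digits = 2)$aq)
  spi <- alga_species("spirulina", mu_max = 1.2, k_e = 15,
                      shade = 0.8, od680 = 2.5,
                      aq = aq_report("C6.0H10.84O2.06N0.87",
                                     h_digits = 2, ratio_digits = 4)$aq)
  pre <- competition_model(chl, spi)
  f1 <- fraction_for_aq(0.829, chl$aq, spi$aq)        # 0.6 chlorella
  seg <- segment_division_point(pre, e0, r = f1 / (1 - f1))
  cfg <- cultivator(e0 = e0, c_set = seg$c_set, mode = "turbidostat",
                    light_model = "linearized")
  model <- competition_model(chl, spi, cfg)
  truth <- coexistence_composition(model)
  if (!isTRUE(truth$feasible))
    stop("scenario calibration failed: infeasible equilibrium", call. = FALSE)
  structure(list(model = model, truth = truth, seed = seed),
            class = "scenario_fixture")
}

#' @export
print.scenario_fixture <- function(x, ...) {
  cat("Calibrated two-alga turbidostat scenario\n")
  print(x$model$cultivator)
  print(x$truth)
  invisible(x)
}

#' Survey steady states over an operating-point grid
#'
#' For every (E0, C) grid point, computes the stationary outcome of the
#' turbidostat model and (optionally noisy) observations of the biomasses
#' and the mixture assimilation quotient -- a stand-in for a steady-state
#' survey experiment.  Monoculture outcomes report the surviving species'
#' biomass C/od680 and its pure AQ; points at or below the crossover
#' illumination are labelled by the low-light species' monoculture.
#'
#' @param model A [competition_model()].
#' @param e0_grid,c_grid Positive grids of incident illumination and OD680
#'   setpoints.
#' @param noise Gaussian noise sd added to biomasses and AQ (clipped at 0).
#' @param seed Integer seed.
#' @return Data frame with columns `e0`, `c`, `outcome`, `x1`, `x2`, `aq`.
#' @export
generate_steady_state_survey <- function(model, e0_grid, c_grid, noise = 0,
                                         seed = 0) {
  stopifnot(all(e0_grid > 0), all(c_grid > 0), noise >= 0)
  grid <- expand.grid(e0 = e0_grid, c = c_grid, KEEP.OUT.ATTRS = FALSE)
  cr <- crossover_illumination(model)
  sp <- model$species
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    e0 <- grid$e0[i]; cs <- grid$c[i]
    if (e0 <= cr$e_c) {          # internal light always below crossover
      x <- c(0, cs / sp[[2]]$od680)
      outcome <- "monoculture-2"
    } else {
      eq <- coexistence_composition(model, e0 = e0, c_set = cs)
      if (eq$feasible && min(eq$x1, eq$x2) > 1e-9 * (eq$x1 + eq$x2)) {
        x <- c(eq$x1, eq$x2); outcome <- "coexistence"
      } else if (eq$feasible && eq$x1 >= eq$x2) {
        x <- c(cs / sp[[1]]$od680, 0); outcome <- "monoculture-1"
      } else if (eq$feasible) {
        x <- c(0, cs / sp[[2]]$od680); outcome <- "monoculture-2"
      } else if (eq$x2 < 0) {
        x <- c(cs / sp[[1]]$od680, 0); outcome <- "monoculture-1"
      } else {
        x <- c(0, cs / sp[[2]]$od680); outcome <- "monoculture-2"
      }
    }
    tot <- sum(x)
    aq <- if (tot > 0) mixture_aq(x[1] / tot, sp[[1]]$aq, sp[[2]]$aq)
          else NA_real_
    data.frame(e0 = e0, c = cs, outcome = outcome,
               x1 = x[1], x2 = x[2], aq = aq, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (noise > 0) {
    out[, c("x1", "x2", "aq")] <- withr_seed(seed, {
      m <- as.matrix(out[, c("x1", "x2", "aq")])
      pmax(m + stats::rnorm(length(m), 0, noise), 0)
    })
  }
  out
}
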