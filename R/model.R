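#' Define an algal species for the competition model
#'
#' Bundles the kinetic, optical and gas-exchange parameters of one species.
#' Growth is light-limited Michaelis-Menten: mu(E) = mu_max * E / (K_E + E).
#' `shade` is the optical-depth contribution per unit biomass concentration
#' (path length included), `od680` the contribution to the measured optical
#' density at 680 nm per unit biomass.
#'
#' @param name Species label.
#' @param mu_max Maximal specific growth rate (1/day, > 0).
#' @param k_e Half-saturation illumination (same units as E0, > 0).
#' @param shade Optical depth per g/L of biomass (L/g, >= 0).
#' @param od680 OD680 per g/L of biomass (L/g, > 0).
#' @param aq Assimilation quotient of the pure culture (CO2 : O2).
#' @return Object of class `alga_species`.
#' @examples
#' alga_species("chlorella", mu_max = 2, k_e = 60, shade = 2.5,
#'              od680 = 2, aq = 0.885)
#' @export
alga_species <- function(name, mu_max, k_e, shade, od680 = 1, aq = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  num1 <- function(x, what, min, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(what, " must be a finite number", call. = FALSE)
    if (if (strict) x <= min else x < min)
      stop(what, " must be ", if (strict) "> " else ">= ", min, call. = FALSE)
    as.numeric(x)
  }
  structure(list(name = name,
                 mu_max = num1(mu_max, "mu_max", 0),
                 k_e = num1(k_e, "k_e", 0),
                 shade = num1(shade, "shade", 0, strict = FALSE),
                 od680 = num1(od680, "od680", 0),
                 aq = if (is.na(aq)) NA_real_ else as.numeric(aq)),
            class = "alga_species")
}

#' @export
print.alga_species <- function(x, ...) {
  cat(sprintf("<alga> %s: mu_max=%g /d, K_E=%g, shade=%g L/g, od680=%g L/g, AQ=%g\n",
              x$name, x$mu_max, x$k_e, x$shade, x$od680, x$aq))
  invisible(x)
}

#' Cultivator settings
#'
#' @param e0 Incident illumination E0 (> 0; units arbitrary but consistent
#'   with `k_e`, conventionally W/m2).
#' @param c_set OD680 setpoint for turbidostat mode (> 0).
#' @param d Fixed dilution rate for chemostat mode (1/day, >= 0).
#' @param mode `"turbidostat"` (dilution servo-controlled so OD680 stays
#'   constant) or `"chemostat"` (fixed dilution).
#' @param light_model `"linearized"` (E = E0 (1 - tau/2), the low-density
#'   Taylor truncation) or `"beer_lambert"` (exact depth average).
#' @return Object of class `cultivator`.
#' @export
cultivator <- function(e0, c_set = NULL, d = NULL,
                       mode = c("turbidostat", "chemostat"),
                       light_model = c("linearized", "beer_lambert")) {
  mode <- match.arg(mode)
  light_model <- match.arg(light_model)
  if (!is.numeric(e0) || length(e0) != 1L || !is.finite(e0) || e0 <= 0)
    stop("e0 must be a positive number", call. = FALSE)
  if (mode == "turbidostat") {
    if (is.null(c_set) || !is.finite(c_set) || c_set <= 0)
      stop("turbidostat mode requires a positive OD680 setpoint `c_set`",
           call. = FALSE)
    d <- NA_real_
  } else {
    if (is.null(d) || !is.finite(d) || d < 0)
      stop("chemostat mode requires a dilution rate `d` >= 0", call. = FALSE)
    if (is.null(c_set)) c_set <- NA_real_
  }
  structure(list(e0 = as.numeric(e0), c_set = as.numeric(c_set),
                 d = as.numeric(d), mode = mode, light_model = light_model),
            class = "cultivator")
}

#' @export
print.cultivator <- function(x, ...) {
  cat(sprintf("<cultivator> %s, E0=%g, %s, light=%s\n", x$mode, x$e0,
              if (x$mode == "turbidostat") sprintf("OD680 setpoint C=%g", x$c_set)
              else sprintf("D=%g /d", x$d),
              x$light_model))
  invisible(x)
}

#' Two-species light-competition model
#'
#' Couples two [alga_species()] competing for light in a flow cultivator.
#' The state is the biomass pair (x1, x2) in g/L; both species see the same
#' depth-averaged internal illumination E, reduced below the incident E0 by
#' self-shading, and grow at mu_i(E) while being diluted at rate D:
#' dx_i/dt = x_i (mu_i(E) - D).  In turbidostat mode D is the algebraic
#' dilution that holds OD680 exactly constant.
#'
#' @param sp1,sp2 [alga_species()] objects (conventionally species 1 is the
#'   high-light specialist).
#' @param cultivator A [cultivator()]; may be `NULL` for purely geometric
#'   analyses and attached later.
#' @return Object of class `competition_model`.
#' @seealso [default_scenario()] for a ready calibrated instance,
#'   [coexistence_composition()], [simulate.competition_model()].
#' @export
competition_model <- function(sp1, sp2, cultivator = NULL) {
  stopifnot(inherits(sp1, "alga_species"), inherits(sp2, "alga_species"))
  if (!is.null(cultivator) && !inherits(cultivator, "cultivator"))
    stop("`cultivator` must be created with cultivator()", call. = FALSE)
  structure(list(species = list(sp1, sp2), cultivator = cultivator),
            class = "competition_model")
}

#' @export
print.competition_model <- function(x, ...) {
  cat("Two-species light-competition model\n")
  print(x$species[[1]]); print(x$species[[2]])
  if (!is.null(x$cultivator)) print(x$cultivator)
  cr <- tryCatch(crossover_illumination(x), error = function(e) NULL)
  if (!is.null(cr))
    cat(sprintf("growth-curve crossover: E_c = %g (common mu = %.4g /d)\n",
                cr$e_c, cr$mu_c))
  invisible(x)
}

#' @export
summary.competition_model <- function(object, ...) {
  print(object)
  cr <- tryCatch(crossover_illumination(object), error = function(e) NULL)
  if (!is.null(cr)) {
    b <- region_boundaries(object)
    cat("coexistence boundaries in (1/E0, C):\n")
    print(as.data.frame(b), row.names = FALSE)
    s <- vapply(object$species, function(z) z$shade / z$od680, numeric(1))
    cat(sprintf("shade per OD680: %.4g vs %.4g -> coexistence %s\n",
                s[1], s[2],
                if (s[1] > s[2]) "stable (species 1 shades more per OD)"
                else "unstable"))
  }
  invisible(object)
}

#' Michaelis-Menten specific growth rate
#'
#' @param e Illumination (>= 0), vectorized.
#' @param sp An [alga_species()].
#' @return Specific growth rate mu_max * e / (k_e + e) in 1/day.
#' @export
growth_rate <- function(e, sp) {
  if (any(!is.finite(e)) || any(e < 0))
    stop("illumination must be finite and >= 0", call. = FALSE)
  sp$mu_max * e / (sp$k_e + e)
}

#' Optical depth of the culture
#'
#' tau = shade1 * x1 + shade2 * x2, the (dimensionless) optical depth of the
#' light path through the suspension.
#'
#' @param x1,x2 Biomass concentrations (g/L), vectorized.
#' @param model A [competition_model()].
#' @return Optical depth tau >= 0.
#' @export
optical_depth <- function(x1, x2, model) {
  model$species[[1]]$shade * x1 + model$species[[2]]$shade * x2
}

#' Measured optical density at 680 nm
#'
#' @inheritParams optical_depth
#' @return OD680 = od680_1 * x1 + od680_2 * x2.
#' @export
od680 <- function(x1, x2, model) {
  model$species[[1]]$od680 * x1 + model$species[[2]]$od680 * x2
}

#' Depth-averaged illumination, exact Beer-Lambert form
#'
#' Averaging E0 exp(-z) over optical depth z in \[0, tau\] gives
#' E = E0 (1 - exp(-tau)) / tau, continuously extended to E0 at tau = 0.
#'
#' @param e0 Incident illumination (> 0).
#' @param tau Optical depth (>= 0), vectorized.
#' @return Average internal illumination in (0, E0].
#' @export
avg_illumination_exact <- function(e0, tau) {
  if (any(e0 <= 0)) stop("e0 must be positive", call. = FALSE)
  if (any(tau < 0)) stop("tau must be >= 0", call. = FALSE)
  out <- ifelse(tau > 0, e0 * (-expm1(-tau)) / tau, e0)
  as.numeric(out)
}

#' Depth-averaged illumination, linearized low-density form
#'
#' First-order Taylor truncation of the exact depth average:
#' E = E0 (1 - tau/2).  Valid for low optical density; tau >= 2 would give
#' non-positive illumination and is rejected.
#'
#' @inheritParams avg_illumination_exact
#' @return E0 * (1 - tau/2).
#' @export
avg_illumination_linear <- function(e0, tau) {
  if (any(e0 <= 0)) stop("e0 must be positive", call. = FALSE)
  if (any(tau < 0)) stop("tau must be >= 0", call. = FALSE)
  if (any(tau >= 2))
    stop("linearized light model out of range: tau >= 2 (use beer_lambert)",
         call. = FALSE)
  e0 * (1 - tau / 2)
}

avg_illumination <- function(e0, tau, light_model = "linearized") {
  if (light_model == "linearized") avg_illumination_linear(e0, tau)
  else avg_illumination_exact(e0, tau)
}

#' Turbidostat dilution rate
#'
#' The dilution that holds OD680 exactly constant is the OD-weighted mean of
#' the two specific growth rates:
#' D = (od1 x1 mu1(E) + od2 x2 mu2(E)) / (od1 x1 + od2 x2).
#'
#' @inheritParams optical_depth
#' @param e Internal illumination at which the growth rates are evaluated.
#' @return Dilution rate (1/day).
#' @export
turbidostat_dilution <- function(x1, x2, e, model) {
  sp <- model$species
  w1 <- sp[[1]]$od680 * x1
  w2 <- sp[[2]]$od680 * x2
  if (w1 + w2 <= 0)
    stop("empty cultivator: OD680 is zero, turbidostat dilution undefined",
         call. = FALSE)
  (w1 * growth_rate(e, sp[[1]]) + w2 * growth_rate(e, sp[[2]])) / (w1 + w2)
}

#' Right-hand side of the competition model
#'
#' Evaluates dx_i/dt = x_i (mu_i(E) - D) with E from the configured light
#' model and D either fixed (chemostat) or the turbidostat servo dilution:
#' zero while the culture is still filling up (OD680 below the setpoint,
#' batch growth) and the exact OD-conserving algebraic dilution of
#' [turbidostat_dilution()] once the setpoint is reached.  States with
#' x_i = 0 are absorbing.
#'
#' @inheritParams optical_depth
#' @param model A [competition_model()] with a cultivator attached (or pass
#'   `config`).
#' @param config Optional [cultivator()] overriding `model$cultivator`.
#' @return List with `dx` (length-2 derivative), `e` (internal illumination)
#'   and `d` (dilution rate).
#' @export
model_rhs <- function(x1, x2, model, config = NULL) {
  cfg <- if (is.null(config)) model$cultivator else config
  if (is.null(cfg)) stop("no cultivator configuration attached", call. = FALSE)
  x1 <- max(x1, 0); x2 <- max(x2, 0)
  sp <- model$species
  tau <- optical_depth(x1, x2, model)
  e <- avg_illumination(cfg$e0, tau, cfg$light_model)
  d <- if (cfg$mode == "chemostat") {
    cfg$d
  } else if (x1 + x2 > 0) {
    if (od680(x1, x2, model) < cfg$c_set * (1 - 1e-12)) 0  # batch fill-up
    else turbidostat_dilution(x1, x2, e, model)
  } else 0
  list(dx = c(x1 * (growth_rate(e, sp[[1]]) - d),
              x2 * (growth_rate(e, sp[[2]]) - d)),
       e = e, d = d)
}
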