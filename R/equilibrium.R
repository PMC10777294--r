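#' Crossover illumination of the two growth curves
#'
#' The two Michaelis-Menten curves mu_i(E) = mu_max_i E / (K_i + E) intersect
#' at E_c = (mu_max2 K1 - mu_max1 K2) / (mu_max1 - mu_max2).  E_c is the
#' internal illumination of every coexistence equilibrium: both species can
#' only grow at the common dilution rate when they grow equally fast.
#'
#' @param model A [competition_model()] (or pass two species via `sp2`).
#' @param sp2 Optional second species if `model` is an [alga_species()].
#' @return List with `e_c` (crossover illumination) and `mu_c` (the common
#'   growth rate there, which is the coexistence dilution rate).
#' @export
crossover_illumination <- function(model, sp2 = NULL) {
  if (inherits(model, "competition_model")) {
    s1 <- model$species[[1]]; s2 <- model$species[[2]]
  } else {
    s1 <- model; s2 <- sp2
  }
  if (s1$mu_max == s2$mu_max && s1$k_e == s2$k_e)
    stop("degenerate: identical growth curves cross everywhere", call. = FALSE)
  if (s1$mu_max == s2$mu_max)
    stop("no finite crossover: equal mu_max, curves only meet at saturation",
         call. = FALSE)
  e_c <- (s2$mu_max * s1$k_e - s1$mu_max * s2$k_e) / (s1$mu_max - s2$mu_max)
  if (!is.finite(e_c) || e_c <= 0)
    stop(paste0("no coexistence: growth curves do not cross at positive ",
                "illumination (one species dominates at all light levels)"),
         call. = FALSE)
  list(e_c = e_c, mu_c = growth_rate(e_c, s1))
}

#' Stationary composition at an operating point
#'
#' At a coexistence steady state the internal illumination must equal the
#' crossover E_c, so the optical depth is pinned at tau* = 2 (1 - E_c/E0)
#' (linearized light model), while the OD680 servo pins
#' od1 x1 + od2 x2 = C.  The stationary biomasses solve this 2x2 linear
#' system.  Infeasible solutions (a negative biomass, i.e. the operating
#' point lies outside the coexistence region) are returned with
#' `feasible = FALSE` rather than raised, so region scans can use them.
#'
#' @param model A [competition_model()].
#' @param e0 Incident illumination (default: the attached cultivator's).
#' @param c_set OD680 setpoint (default: the attached cultivator's).
#' @return Object of class `equilibrium_point`: `x1`, `x2` (g/L), `e_star`
#'   (= E_c), `d_star` (= common mu at E_c), `aq` (mass-fraction mixture
#'   assimilation quotient), `feasible`, plus the `e0`, `c_set` queried.
#' @export
coexistence_composition <- function(model, e0 = NULL, c_set = NULL) {
  cfg <- model$cultivator
  if (is.null(e0)) e0 <- cfg$e0
  if (is.null(c_set)) c_set <- cfg$c_set
  if (!is.finite(e0) || e0 <= 0) stop("e0 must be positive", call. = FALSE)
  if (!is.finite(c_set) || c_set <= 0)
    stop("c_set must be positive", call. = FALSE)
  s1 <- model$species[[1]]; s2 <- model$species[[2]]
  cr <- crossover_illumination(model)
  A <- rbind(c(s1$shade, s2$shade), c(s1$od680, s2$od680))
  if (abs(det(A)) < 1e-14 * max(abs(A)) ^ 2)
    stop(paste0("degenerate geometry: equal shade/od680 ratio for both ",
                "species, stationary composition is not unique"),
         call. = FALSE)
  b <- c(2 * (1 - cr$e_c / e0), c_set)
  x <- solve(A, b)
  feasible <- all(x >= -1e-12)
  total <- x[1] + x[2]
  aq <- if (feasible && total > 0)
    mixture_aq(min(max(x[1] / total, 0), 1), s1$aq, s2$aq) else NA_real_
  structure(list(x1 = x[1], x2 = x[2], e_star = cr$e_c, d_star = cr$mu_c,
                 aq = aq, feasible = feasible, e0 = e0, c_set = c_set),
            class = "equilibrium_point")
}

#' @export
print.equilibrium_point <- function(x, ...) {
  cat(sprintf("<equilibrium> x1=%.6g, x2=%.6g g/L  (E*=%g, D*=%.4g /d)\n",
              x$x1, x$x2, x$e_star, x$d_star))
  cat(sprintf("  at E0=%g, C=%g;  mixture AQ=%.4g;  feasible: %s\n",
              x$e0, x$c_set, x$aq, x$feasible))
  invisible(x)
}

#' Coexistence-region boundary lines in (1/E0, C) coordinates
#'
#' The region of stable coexistence in the (E0, C) operating plane is bounded
#' by the two monoculture loci.  Setting the other species to zero in the
#' stationary system gives, for species i,
#' 1/E0 = 1/E_c - (shade_i / (2 od_i E_c)) C:
#' straight lines in (1/E0, C) that share the intercept 1/E_c at C = 0 (the
#' washout pencil point, where x1 = x2 = 0).
#'
#' @param model A [competition_model()].
#' @return Object of class `boundary_lines`: a data.frame with one row per
#'   species (`species`, `slope`, `intercept`), attribute `e_c`.
#' @export
region_boundaries <- function(model) {
  cr <- crossover_illumination(model)
  sp <- model$species
  out <- data.frame(
    species = vapply(sp, `[[`, character(1), "name"),
    slope = vapply(sp, function(s) -s$shade / (2 * s$od680 * cr$e_c),
                   numeric(1)),
    intercept = rep(1 / cr$e_c, 2),
    stringsAsFactors = FALSE)
  structure(out, e_c = cr$e_c, class = c("boundary_lines", "data.frame"))
}

#' Iso-ratio (iso-AQ) line in (1/E0, C) coordinates
#'
#' All operating points whose stationary composition has a fixed biomass
#' ratio x1/x2 = r lie on a straight line through the common pencil point
#' (C = 0, 1/E0 = 1/E_c):
#' 1/E0 = 1/E_c - (shade1 r + shade2) / (2 (od1 r + od2) E_c) * C.
#' Because the mixture assimilation quotient depends only on the mass
#' fractions, AQ is constant along each such line; r = 0 and r = Inf recover
#' the two monoculture boundaries.
#'
#' @param model A [competition_model()].
#' @param r Biomass ratio x1/x2, in \[0, Inf\].
#' @return List with `r`, `slope`, `intercept` (= 1/E_c) and the constant
#'   `aq` along the line.
#' @export
iso_ratio_line <- function(model, r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0)
    stop("r must be a single ratio >= 0 (Inf allowed)", call. = FALSE)
  cr <- crossover_illumination(model)
  s1 <- model$species[[1]]; s2 <- model$species[[2]]
  if (is.infinite(r)) {
    slope <- -s1$shade / (2 * s1$od680 * cr$e_c)
    f1 <- 1
  } else {
    slope <- -(s1$shade * r + s2$shade) / (2 * (s1$od680 * r + s2$od680) * cr$e_c)
    f1 <- r / (1 + r)
  }
  list(r = r, slope = slope, intercept = 1 / cr$e_c,
       aq = mixture_aq(f1, s1$aq, s2$aq))
}

segment_bounds <- function(model, e0) {
  cr <- crossover_illumination(model)
  if (e0 <= cr$e_c)
    stop(sprintf(paste0("E0 = %g is at or below the crossover illumination ",
                        "E_c = %g: no coexistence segment"), e0, cr$e_c),
         call. = FALSE)
  a <- 2 * (1 - cr$e_c / e0)        # stationary optical depth tau*
  sp <- model$species
  c_mono <- vapply(sp, function(s) a * s$od680 / s$shade, numeric(1))
  list(a = a, c1 = c_mono[1], c2 = c_mono[2],
       lower = min(c_mono), upper = max(c_mono))
}

#' OD setpoint dividing the boundary segment for a target composition
#'
#' At a given illumination E0, the vertical segment between the two
#' monoculture boundary values of C contains all coexistence setpoints.  The
#' setpoint whose stationary biomass ratio is x1/x2 = r is
#' C = tau* (od1 r + od2) / (shade1 r + shade2) with tau* = 2 (1 - E_c/E0).
#' Measured from the species-2 (r = 0) boundary this divides the segment
#' with odds r * shade1/shade2; the naive rule "divide the segment in the
#' ratio r" is exact only when the two species have equal shading per unit
#' biomass, e.g. in an OD-units convention with equal shading per OD.  Both
#' the exact setpoint and the naive one are returned for comparison.
#'
#' @param model A [competition_model()].
#' @param e0 Incident illumination; must exceed the crossover E_c.
#' @param r Target biomass ratio x1/x2 (>= 0, Inf allowed).
#' @return List with `c_set` (exact setpoint), `c_mono1`/`c_mono2` (segment
#'   ends, species-1 and species-2 monoculture), `division_odds` (exact odds
#'   from the species-2 end), `naive_c_set` (segment divided in odds r) and
#'   `naive_odds` (= r).
#' @export
segment_division_point <- function(model, e0, r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0)
    stop("r must be a single ratio >= 0 (Inf allowed)", call. = FALSE)
  sb <- segment_bounds(model, e0)
  s1 <- model$species[[1]]; s2 <- model$species[[2]]
  if (is.infinite(r)) {
    c_exact <- sb$c1
    odds <- Inf
  } else {
    c_exact <- sb$a * (s1$od680 * r + s2$od680) / (s1$shade * r + s2$shade)
    odds <- r * s1$shade / s2$shade
  }
  naive <- if (is.infinite(r)) sb$c1 else sb$c2 + r / (1 + r) * (sb$c1 - sb$c2)
  list(c_set = c_exact, c_mono1 = sb$c1, c_mono2 = sb$c2,
       division_odds = odds, naive_c_set = naive, naive_odds = r)
}

#' Design an operating point for a target assimilation quotient
#'
#' Chains the composition-to-AQ control logic: the target AQ fixes the mass
#' fraction of species 1 ([fraction_for_aq()]), hence the biomass ratio r,
#' hence (at the chosen E0) the OD680 setpoint on the iso-ratio line
#' ([segment_division_point()]); the stationary composition there is returned
#' for verification.
#'
#' @param model A [competition_model()] with species AQ values set.
#' @param aq_target Desired mixture assimilation quotient; must lie between
#'   the two pure-culture values.
#' @param e0 Incident illumination (must exceed E_c).
#' @return List with `c_set` and the corresponding `equilibrium`
#'   ([coexistence_composition()] output whose `aq` equals `aq_target`).
#' @export
design_operating_point <- function(model, aq_target, e0) {
  s1 <- model$species[[1]]; s2 <- model$species[[2]]
  f1 <- fraction_for_aq(aq_target, s1$aq, s2$aq)
  r <- if (f1 >= 1) Inf else f1 / (1 - f1)
  seg <- segment_division_point(model, e0, r)
  eq <- coexistence_composition(model, e0 = e0, c_set = seg$c_set)
  list(c_set = seg$c_set, equilibrium = eq)
}

#' Monoculture steady state in a chemostat
#'
#' A single species at fixed dilution d settles where mu(E*) = d, i.e.
#' E* = K_E d / (mu_max - d), and the biomass adjusts the self-shading so
#' that the linearized internal illumination equals E*:
#' x* = 2 (1 - E*/E0) / shade.  If d >= mu_max, or the required E* is not
#' below E0 (insufficient light), the culture washes out (x* = 0) -- a
#' result, not an error.
#'
#' @param sp An [alga_species()].
#' @param e0 Incident illumination (> 0).
#' @param d Dilution rate (1/day, >= 0).
#' @return List with `x_star` (g/L), `e_star`, and `washout` flag.
#' @export
monoculture_steady_state <- function(sp, e0, d) {
  stopifnot(e0 > 0, d >= 0)
  if (d == 0)
    return(list(x_star = 2 / sp$shade, e_star = 0, washout = FALSE))
  if (d >= sp$mu_max)
    return(list(x_star = 0, e_star = NA_real_, washout = TRUE))
  e_star <- sp$k_e * d / (sp$mu_max - d)
  if (e_star >= e0)
    return(list(x_star = 0, e_star = e_star, washout = TRUE))
  list(x_star = 2 * (1 - e_star / e0) / sp$shade, e_star = e_star,
       washout = FALSE)
}
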