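#' Integrate the competition model
#'
#' Adaptive (lsoda) integration of the two-species system.  Biomasses are
#' clamped at zero inside the right-hand side (x_i = 0 is absorbing).  In
#' turbidostat mode the pump is off while the culture is below the OD680
#' setpoint (batch fill-up); once the setpoint is reached the algebraic
#' servo dilution holds OD680 constant up to integrator tolerance.  An
#' initial state above the setpoint is diluted down to it instantaneously
#' at t = 0 (perfect control), preserving the composition.
#'
#' @param object A [competition_model()] with a cultivator attached.
#' @param nsim,seed Accepted for compatibility with the [stats::simulate()]
#'   generic; the model is deterministic, so they are ignored.
#' @param init Named numeric vector `c(x1 = , x2 = )`, initial biomasses
#'   (g/L).
#' @param t_end Final time (days).
#' @param n_out Number of equally spaced output times.
#' @param tol Relative integration tolerance (absolute tolerance is
#'   `tol * 1e-3`).
#' @param ... Passed on to [deSolve::ode()].
#' @return Object of class `trajectory`: a data.frame with columns `t`,
#'   `x1`, `x2`, `od680`, `e` (internal illumination) and `d` (dilution).
#' @examples
#' sc <- default_scenario()
#' tr <- simulate(sc$model, init = c(x1 = 0.2, x2 = 0.3), t_end = 50)
#' tail(tr, 1)
#' @export
simulate.competition_model <- function(object, nsim = 1, seed = NULL,
                                       init, t_end = 200, n_out = 401,
                                       tol = 1e-8, ...) {
  if (is.null(object$cultivator))
    stop("attach a cultivator() to the model before simulating", call. = FALSE)
  stopifnot(is.numeric(init), length(init) == 2L, all(init >= 0),
            t_end > 0, tol > 0)
  cfg <- object$cultivator
  if (cfg$mode == "turbidostat") {
    od0 <- od680(init[1], init[2], object)
    if (od0 > cfg$c_set) init <- init * cfg$c_set / od0
  }
  times <- seq(0, t_end, length.out = n_out)
  rhs_fun <- function(t, y, p) list(model_rhs(y[1], y[2], object)$dx)
  out <- deSolve::ode(y = c(x1 = unname(init[1]), x2 = unname(init[2])),
                      times = times, func = rhs_fun, parms = NULL,
                      rtol = tol, atol = tol * 1e-3, ...)
  if (attr(out, "istate")[1] < 0)
    warning("integration stopped early; returning the valid part")
  out <- as.data.frame(out)
  names(out)[1] <- "t"
  out$x1 <- pmax(out$x1, 0)
  out$x2 <- pmax(out$x2, 0)
  aux <- t(vapply(seq_len(nrow(out)), function(i) {
    r <- model_rhs(out$x1[i], out$x2[i], object)
    c(r$e, r$d)
  }, numeric(2)))
  out$od680 <- od680(out$x1, out$x2, object)
  out$e <- aux[, 1]
  out$d <- aux[, 2]
  structure(out, model = object, class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points over %g days\n", nrow(x),
              x$t[nrow(x)] - x$t[1]))
  print.data.frame(utils::head(as.data.frame(x), 4))
  cat("  ...\n")
  print.data.frame(utils::tail(as.data.frame(x), 2))
  invisible(x)
}

#' Integrate until a steady state and classify the outcome
#'
#' Runs the model in chunks until the right-hand-side norm falls below
#' `residual_tol`, then classifies the end state as `"coexistence"`,
#' `"monoculture-1"`, `"monoculture-2"` or `"washout"` using an extinction
#' threshold of `extinct` g/L.
#'
#' @param model A [competition_model()] with cultivator.
#' @param init Initial biomasses `c(x1 = , x2 = )`; the default starts both
#'   species at 0.05 g/L.
#' @param t_max Maximum integration time (days).
#' @param residual_tol Convergence threshold on `max(|dx/dt|)` (g/L/day).
#' @param extinct Biomass below which a species is classed extinct (g/L).
#' @param tol Integrator relative tolerance.
#' @return List with `outcome`, `x1`, `x2`, `e`, `d`, `t` (time reached),
#'   `converged`, and `residual`.
#' @export
find_steady_state <- function(model, init = c(x1 = 0.05, x2 = 0.05),
                              t_max = 2000, residual_tol = 1e-10,
                              extinct = 1e-6, tol = 1e-10) {
  state <- c(x1 = unname(init[1]), x2 = unname(init[2]))
  t <- 0
  chunk <- 50
  converged <- FALSE
  repeat {
    tr <- simulate(model, init = state, t_end = chunk, n_out = 11, tol = tol)
    n <- nrow(tr)
    state <- c(x1 = tr$x1[n], x2 = tr$x2[n])
    t <- t + chunk
    res <- max(abs(model_rhs(state[1], state[2], model)$dx))
    if (res < residual_tol) { converged <- TRUE; break }
    if (t >= t_max) break
  }
  r <- model_rhs(state[1], state[2], model)
  alive <- state > extinct
  outcome <- if (all(alive)) "coexistence"
             else if (alive[1]) "monoculture-1"
             else if (alive[2]) "monoculture-2"
             else "washout"
  list(outcome = outcome, x1 = unname(state[1]), x2 = unname(state[2]),
       e = r$e, d = r$d, t = t, converged = converged, residual = res)
}

#' Probe local stability of a coexistence equilibrium
#'
#' Perturbs the composition at fixed OD680 (x1 scaled by 1 + `magnitude`,
#' x2 adjusted so the optical density setpoint is unchanged), integrates,
#' and fits an exponential to the decay (or growth) of the composition
#' deviation.  A negative leading rate means the equilibrium is locally
#' stable -- disturbances of the species ratio die out and the mixed culture
#' returns to its set composition.
#'
#' @param model A [competition_model()] (turbidostat cultivator attached).
#' @param eq An [coexistence_composition()] equilibrium (feasible).
#' @param magnitude Relative composition perturbation (default 0.2 = 20%).
#' @param t_end Probe duration (days).
#' @param tol Integrator tolerance.
#' @return List with `rate` (leading exponential rate, 1/day; negative =
#'   stable), `returned` (deviation shrank below 5% of its initial value),
#'   and `exponential` (TRUE when the log-linear fit explains the transient,
#'   R^2 > 0.98; FALSE flags a non-exponential transient).
#' @export
stability_probe <- function(model, eq, magnitude = 0.2, t_end = 120,
                            tol = 1e-10) {
  if (!isTRUE(eq$feasible)) stop("equilibrium is not feasible", call. = FALSE)
  s1 <- model$species[[1]]; s2 <- model$species[[2]]
  if (magnitude == 0)
    return(list(rate = 0, returned = TRUE, exponential = TRUE))
  x1p <- eq$x1 * (1 + magnitude)
  x2p <- (eq$c_set - s1$od680 * x1p) / s2$od680
  if (x2p < 0)
    stop("perturbation magnitude pushes species 2 below zero at fixed OD",
         call. = FALSE)
  cfg <- cultivator(e0 = eq$e0, c_set = eq$c_set, mode = "turbidostat",
                    light_model = model$cultivator$light_model %||% "linearized")
  m <- competition_model(s1, s2, cfg)
  tr <- simulate(m, init = c(x1 = x1p, x2 = x2p), t_end = t_end,
                 n_out = 241, tol = tol)
  dev <- tr$x1 - eq$x1
  d0 <- abs(dev[1])
  # fit only while the deviation is in the local regime and above noise
  keep <- abs(dev) > 1e-12 & abs(dev) < 5 * d0
  keep[1] <- TRUE
  run <- cumsum(!keep) == 0          # leading run of usable points
  if (sum(run) < 5)
    return(list(rate = NA_real_, returned = FALSE, exponential = FALSE))
  fit <- stats::lm(log(abs(dev[run])) ~ tr$t[run])
  r2 <- summary(fit)$r.squared
  list(rate = unname(stats::coef(fit)[2]),
       returned = abs(dev[length(dev)]) < 0.05 * d0,
       exponential = is.finite(r2) && r2 > 0.98)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
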