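#' Plot the coexistence region and iso-ratio pencil
#'
#' Draws the two monoculture boundary lines and a pencil of iso-ratio
#' (constant assimilation quotient) lines, either in the transformed
#' (1/E0, C) coordinates where all loci are exactly straight, or back in
#' the operating (E0, C) plane.
#'
#' @param x A [competition_model()].
#' @param coords `"reciprocal"` for (1/E0 vs C, straight lines) or
#'   `"direct"` for (E0 vs C).
#' @param ratios Iso-ratio values x1/x2 to draw.
#' @param c_max Largest OD680 setpoint shown.
#' @param ... Further arguments to [graphics::plot()].
#' @return The model, invisibly.
#' @export
plot.competition_model <- function(x, coords = c("reciprocal", "direct"),
                                   ratios = c(0.25, 1, 4), c_max = NULL, ...) {
  coords <- match.arg(coords)
  b <- region_boundaries(x)
  e_c <- attr(b, "e_c")
  if (is.null(c_max)) {
    # OD reachable at 4x the crossover illumination on the shallower boundary
    c_max <- max(-b$intercept / b$slope * 0.75)
  }
  cs <- seq(0, c_max, length.out = 100)
  lines_r <- lapply(ratios, function(r) iso_ratio_line(x, r))
  if (coords == "reciprocal") {
    graphics::plot(NA, xlim = c(0, c_max), ylim = c(0, 1 / e_c * 1.05),
                   xlab = "OD680 setpoint C", ylab = "1 / E0",
                   main = "Coexistence region and iso-AQ pencil", ...)
    for (i in 1:2)
      graphics::lines(cs, b$intercept[i] + b$slope[i] * cs, lwd = 2, col = i + 1)
    for (l in lines_r)
      graphics::lines(cs, l$intercept + l$slope * cs, lty = 3)
    graphics::points(0, 1 / e_c, pch = 19)
    graphics::legend("topright", bty = "n",
                     legend = c(b$species, sprintf("x1/x2 = %g", ratios)),
                     col = c(2, 3, rep(1, length(ratios))),
                     lty = c(1, 1, rep(3, length(ratios))))
  } else {
    inv <- function(l) ifelse(l$intercept + l$slope * cs > 0,
                              1 / (l$intercept + l$slope * cs), NA)
    graphics::plot(NA, xlim = c(e_c, 4 * e_c), ylim = c(0, c_max),
                   xlab = "incident illumination E0", ylab = "OD680 setpoint C",
                   main = "Coexistence region", ...)
    for (i in 1:2) {
      e0v <- ifelse(b$intercept[i] + b$slope[i] * cs > 0,
                    1 / (b$intercept[i] + b$slope[i] * cs), NA)
      graphics::lines(e0v, cs, lwd = 2, col = i + 1)
    }
    for (l in lines_r) graphics::lines(inv(l), cs, lty = 3)
  }
  invisible(x)
}

#' Plot a simulated trajectory
#'
#' @param x A `trajectory` from [simulate.competition_model()].
#' @param ... Further arguments to [graphics::matplot()].
#' @return The trajectory, invisibly.
#' @export
plot.trajectory <- function(x, ...) {
  graphics::matplot(x$t, cbind(x$x1, x$x2, x$od680), type = "l",
                    lty = c(1, 1, 2), col = c(2, 3, 1),
                    xlab = "time (d)", ylab = "biomass (g/L) / OD680", ...)
  graphics::legend("right", bty = "n", lty = c(1, 1, 2), col = c(2, 3, 1),
                   legend = c("x1", "x2", "OD680"))
  invisible(x)
}
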