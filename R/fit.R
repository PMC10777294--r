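#' Fit Michaelis-Menten light-limited growth kinetics
#'
#' Fits mu(E) = mu_max E / (K_E + E) to monoculture growth-rate
#' measurements.  `method = "nonlinear"` performs Levenberg-Marquardt least
#' squares on the original scale, initialized from the double-reciprocal
#' estimate; `method = "reciprocal"` is the classical Lineweaver-Burk route,
#' an ordinary least-squares line of 1/mu on 1/E (mu_max = 1/intercept,
#' K_E = slope/intercept).  The reciprocal route is exact on noiseless data
#' but amplifies the influence of low-rate points under noise, which is why
#' it serves here as the initializer rather than the estimator of record.
#'
#' @param formula A two-sided formula `rate ~ illumination` naming columns
#'   of `data`.
#' @param data Data frame of measurements.
#' @param method `"nonlinear"` (default) or `"reciprocal"`.
#' @param weights Optional per-point weights (default: unweighted).
#' @return Object of class `mm_fit` with the usual accessor methods
#'   ([coef()], [vcov()], [predict()], [fitted()], [residuals()],
#'   [summary()], [plot()]).
#' @examples
#' chl <- alga_species("chlorella", 2, 60, 2.5, 2, 0.885)
#' d <- generate_monoculture_data(chl, sigma = 0, seed = 1)
#' coef(fit_michaelis_menten(growth_rate ~ illumination, d))
#' @export
fit_michaelis_menten <- function(formula, data,
                                 method = c("nonlinear", "reciprocal"),
                                 weights = NULL) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data)
  mu <- stats::model.response(mf)
  if (ncol(mf) != 2L)
    stop("formula must be of the form rate ~ illumination", call. = FALSE)
  e <- mf[[2L]]
  if (any(e <= 0)) stop("illumination values must be positive", call. = FALSE)
  w <- if (is.null(weights)) rep(1, length(mu)) else weights
  if (length(unique(e)) < 2L)
    stop("need measurements at >= 2 distinct illumination levels",
         call. = FALSE)

  recip <- function(e, mu, w) {
    pos <- mu > 0
    if (!all(pos)) {
      warning(sum(!pos), " non-positive rate(s) dropped for the reciprocal fit")
      e <- e[pos]; mu <- mu[pos]; w <- w[pos]
    }
    if (length(unique(e)) < 2L)
      stop("need >= 2 distinct illumination levels with positive rates",
           call. = FALSE)
    lf <- stats::lm(I(1 / mu) ~ I(1 / e), weights = w)
    b <- stats::coef(lf)
    if (!is.finite(b[1]) || b[1] <= 0)
      stop("infeasible reciprocal fit: non-positive intercept (1/mu_max)",
           call. = FALSE)
    c(mu_max = unname(1 / b[1]), k_e = unname(b[2] / b[1]))
  }

  start <- recip(e, mu, w)
  if (method == "reciprocal") {
    cf <- start
    fitted <- cf[1] * e / (cf[2] + e)
    obj <- list(coefficients = cf, se = c(mu_max = NA_real_, k_e = NA_real_),
                vcov = matrix(NA_real_, 2, 2,
                              dimnames = list(names(cf), names(cf))))
  } else {
    if (length(unique(e)) < 3L)
      stop("nonlinear fit needs >= 3 distinct illumination levels",
           call. = FALSE)
    df <- data.frame(mu = mu, e = e)
    nfit <- minpack.lm::nlsLM(mu ~ mu_max * e / (k_e + e), data = df,
                              start = as.list(start), weights = w,
                              lower = c(1e-12, 1e-12),
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(nfit)
    fitted <- as.numeric(stats::fitted(nfit))
    sm <- summary(nfit)
    obj <- list(coefficients = cf, se = sm$coefficients[, "Std. Error"],
                vcov = stats::vcov(nfit), nls = nfit)
  }
  obj$method <- method
  obj$data <- data.frame(e = e, mu = mu, weight = w)
  obj$fitted.values <- fitted
  obj$residuals <- mu - fitted
  obj$call <- match.call()
  class(obj) <- "mm_fit"
  obj
}

#' @export
coef.mm_fit <- function(object, ...) object$coefficients

#' @export
vcov.mm_fit <- function(object, ...) object$vcov

#' @export
fitted.mm_fit <- function(object, ...) object$fitted.values

#' @export
residuals.mm_fit <- function(object, ...) object$residuals

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  e <- if (is.null(newdata)) object$data$e
       else if (is.data.frame(newdata)) newdata[[1L]]
       else newdata
  cf <- object$coefficients
  cf[["mu_max"]] * e / (cf[["k_e"]] + e)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten growth fit (%s least squares)\n", x$method))
  cat(sprintf("  mu_max = %.6g /d,  K_E = %.6g  (n = %d)\n",
              x$coefficients[["mu_max"]], x$coefficients[["k_e"]],
              nrow(x$data)))
  invisible(x)
}

#' @export
summary.mm_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  res <- object$residuals
  out <- list(method = object$method, coefficients = tab,
              rms = sqrt(mean(res ^ 2)), n = nrow(object$data))
  class(out) <- "summary.mm_fit"
  out
}

#' @export
print.summary.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten growth fit (%s), n = %d, residual RMS = %.4g\n",
              x$method, x$n, x$rms))
  stats::printCoefmat(x$coefficients, na.print = "-")
  invisible(x)
}

#' @export
plot.mm_fit <- function(x, ...) {
  d <- x$data
  eg <- seq(min(d$e) * 0.5, max(d$e) * 1.1, length.out = 200)
  graphics::plot(d$e, d$mu, xlab = "illumination E",
                 ylab = "specific growth rate (1/d)",
                 main = sprintf("Michaelis-Menten fit (%s)", x$method), ...)
  graphics::lines(eg, predict(x, eg))
  invisible(x)
}

line_fit <- function(k_coef, const, residuals, rms, type, extra = list()) {
  structure(c(list(k_coef = k_coef, const = const, residuals = residuals,
                   rms = rms, type = type), extra),
            class = "line_fit")
}

#' @export
print.line_fit <- function(x, ...) {
  cat(sprintf("<line fit, %s> K = %.6g, const = %.6g, residual RMS = %.4g\n",
              x$type, x$k_coef, x$const, x$rms))
  invisible(x)
}

#' Empirical logarithmic straightening of a region boundary
#'
#' Least-squares fit of the form C(E0) = K ln(E0) - const to boundary
#' points.  This transform looks straight by eye but carries a systematic
#' error against the model's true boundary C = A (1 - E_c/E0), which is
#' concave in ln(E0): the fit underestimates C at intermediate illumination
#' and overestimates it at the low and high ends.
#'
#' @param e0 Incident illuminations (> 0).
#' @param c OD680 boundary values.
#' @return A `line_fit` with `k_coef` (K), `const`, `residuals`
#'   (observed - fitted, ordered as the input) and `rms`.
#' @seealso [reciprocal_transform()] for the exact straightening,
#'   [residual_sign_pattern()].
#' @export
fit_log_boundary <- function(e0, c) {
  if (any(e0 <= 0)) stop("e0 must be positive", call. = FALSE)
  if (length(unique(e0)) < 2L)
    stop("need >= 2 distinct e0 values", call. = FALSE)
  f <- stats::lm(c ~ log(e0))
  b <- stats::coef(f)
  res <- as.numeric(stats::residuals(f))
  line_fit(k_coef = unname(b[2]), const = unname(-b[1]),
           residuals = res, rms = sqrt(mean(res ^ 2)), type = "log",
           extra = list(e0 = e0, c = c))
}

#' Exact reciprocal straightening of operating-point data
#'
#' Maps points to (1/E0, C) and fits the line 1/E0 = intercept + slope * C.
#' On data generated by the model this transform is exactly straight, and
#' the intercept at C = 0 is 1/E_c, the common pencil point.
#'
#' @inheritParams fit_log_boundary
#' @return A `line_fit` (type `"reciprocal"`) whose `k_coef` is the slope,
#'   `const` the intercept (an estimate of 1/E_c), with residuals in 1/E0
#'   units; also carries `points`, the transformed data.frame.
#' @export
reciprocal_transform <- function(e0, c) {
  if (any(e0 <= 0)) stop("e0 must be positive", call. = FALSE)
  pts <- data.frame(inv_e0 = 1 / e0, c = c)
  f <- stats::lm(inv_e0 ~ c, data = pts)
  b <- stats::coef(f)
  res <- as.numeric(stats::residuals(f))
  line_fit(k_coef = unname(b[2]), const = unname(b[1]),
           residuals = res, rms = sqrt(mean(res ^ 2)), type = "reciprocal",
           extra = list(points = pts))
}

#' Sign pattern of thirds of the residuals
#'
#' Orders the residuals of a `line_fit` by illumination, splits them into
#' first/middle/last thirds and returns the sign of each third's mean
#' residual -- a robust encoding of a systematic low/mid/high lack of fit.
#'
#' @param fit A `line_fit` from [fit_log_boundary()].
#' @return Integer vector of length 3 with values in {-1, 0, 1}.
#' @export
residual_sign_pattern <- function(fit) {
  stopifnot(inherits(fit, "line_fit"))
  if (is.null(fit$e0)) stop("fit carries no e0 ordering", call. = FALSE)
  res <- fit$residuals[order(fit$e0)]
  idx <- cut(seq_along(res), 3, labels = FALSE)
  as.integer(sign(vapply(split(res, idx), mean, numeric(1))))
}
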