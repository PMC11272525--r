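#' Weibull survival curve
#'
#' Constructs a Weibull survival curve in the rate parameterisation
#' \eqn{S(t) = \exp(-\lambda t^\gamma)}, the form in which scale (\eqn{\lambda})
#' and shape (\eqn{\gamma}) parameters are conventionally reported when
#' extrapolating digitized Kaplan-Meier curves in health-economic models.
#' Time is measured in months throughout the package.
#'
#' Note this differs from [stats::dweibull()]'s parameterisation
#' \eqn{S(t) = \exp(-(t/b)^a)}; the correspondence is \eqn{a = \gamma},
#' \eqn{b = \lambda^{-1/\gamma}}.
#'
#' @param scale Positive rate-scale parameter \eqn{\lambda} (units
#'   month^-gamma).
#' @param shape Positive shape parameter \eqn{\gamma}; values above 1 give an
#'   increasing hazard.
#' @return An object of class `weibull_curve`.
#' @examples
#' pfs <- weibull_curve(scale = 0.04, shape = 1.28)
#' weibull_survival(pfs, 12)
#' @export
weibull_curve <- function(scale, shape) {
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale),
            is.numeric(shape), length(shape) == 1L, is.finite(shape))
  if (scale <= 0) stop("weibull_curve: `scale` must be > 0", call. = FALSE)
  if (shape <= 0) stop("weibull_curve: `shape` must be > 0", call. = FALSE)
  structure(list(scale = as.numeric(scale), shape = as.numeric(shape)),
            class = "weibull_curve")
}

#' @export
print.weibull_curve <- function(x, ...) {
  cat(sprintf("Weibull curve S(t) = exp(-%g * t^%g)  [t in months]\n",
              x$scale, x$shape))
  invisible(x)
}

#' Weibull survival probability
#'
#' Evaluates \eqn{S(t) = \exp(-\lambda t^\gamma)} at one or more times.
#'
#' @param curve A [weibull_curve()].
#' @param t Non-negative time(s) in months.
#' @return Survival probabilities in (0, 1]; vectorised over `t`.
#' @export
weibull_survival <- function(curve, t) {
  stopifnot(inherits(curve, "weibull_curve"), is.numeric(t))
  if (any(t < 0)) stop("weibull_survival: `t` must be >= 0", call. = FALSE)
  exp(-curve$scale * t^curve$shape)
}

#' Weibull hazard function
#'
#' \eqn{h(t) = \lambda \gamma t^{\gamma - 1}}.
#'
#' @inheritParams weibull_survival
#' @return Hazard rates per month.
#' @export
weibull_hazard <- function(curve, t) {
  stopifnot(inherits(curve, "weibull_curve"), is.numeric(t))
  if (any(t < 0)) stop("weibull_hazard: `t` must be >= 0", call. = FALSE)
  curve$scale * curve$shape * t^(curve$shape - 1)
}

#' Adjust a Weibull curve by a hazard ratio
#'
#' Derives a comparator arm's curve from the reference arm's curve under
#' proportional hazards: the shape is unchanged and the scale is multiplied
#' by a factor `k`, so that \eqn{S_{adj}(t) = S(t)^k}.
#'
#' The `direction` flag resolves which factor is applied when `hr` is
#' reported as reference-versus-comparator (here camrelizumab-versus-
#' sintilimab). With `"divide"` (the default) the comparator hazard is the
#' reference hazard divided by the HR, so an HR below 1 (reference superior)
#' yields a comparator curve that is *worse* than the reference. With
#' `"multiply"` the scale is multiplied by the HR literally.
#'
#' @param curve Reference-arm [weibull_curve()].
#' @param hr Positive hazard ratio.
#' @param direction `"divide"` (comparator hazard = reference hazard / HR,
#'   default) or `"multiply"` (literal scale product).
#' @return The adjusted `weibull_curve`.
#' @examples
#' ctc_pfs <- weibull_curve(0.04, 1.28)
#' sgp_pfs <- adjust_curve_by_hr(ctc_pfs, hr = 0.75)        # worse PFS
#' lit     <- adjust_curve_by_hr(ctc_pfs, 0.75, "multiply") # literal product
#' @export
adjust_curve_by_hr <- function(curve, hr, direction = c("divide", "multiply")) {
  stopifnot(inherits(curve, "weibull_curve"), is.numeric(hr), length(hr) == 1L)
  if (!is.finite(hr) || hr <= 0) {
    stop("adjust_curve_by_hr: `hr` must be a positive finite number",
         call. = FALSE)
  }
  direction <- match.arg(direction)
  k <- if (direction == "divide") 1 / hr else hr
  weibull_curve(scale = curve$scale * k, shape = curve$shape)
}

#' Restricted mean survival time
#'
#' Area under the survival curve from 0 to `horizon` (months), by adaptive
#' quadrature. As the horizon grows this approaches the Weibull mean
#' \eqn{\Gamma(1 + 1/\gamma)\,\lambda^{-1/\gamma}}.
#'
#' @inheritParams weibull_survival
#' @param horizon Non-negative upper limit in months.
#' @return Restricted mean survival in months.
#' @export
restricted_mean <- function(curve, horizon) {
  stopifnot(inherits(curve, "weibull_curve"),
            is.numeric(horizon), length(horizon) == 1L)
  if (!is.finite(horizon) || horizon < 0) {
    stop("restricted_mean: `horizon` must be finite and >= 0", call. = FALSE)
  }
  if (horizon == 0) return(0)
  # beyond S(t) = 1e-16 the integrand underflows and can defeat adaptive
  # quadrature on very long horizons; the truncated tail is < 1e-16 * t
  t_cap <- (-log(1e-16) / curve$scale)^(1 / curve$shape)
  stats::integrate(function(t) weibull_survival(curve, t),
                   lower = 0, upper = min(horizon, t_cap),
                   rel.tol = 1e-10, subdivisions = 500L)$value
}

#' Mean of a Weibull survival distribution
#'
#' Closed form \eqn{\Gamma(1 + 1/\gamma)\,\lambda^{-1/\gamma}}, in months.
#' Used as the infinite-horizon limit of [restricted_mean()].
#'
#' @inheritParams weibull_survival
#' @return Mean survival time in months.
#' @export
weibull_mean <- function(curve) {
  gamma(1 + 1 / curve$shape) * curve$scale^(-1 / curve$shape)
}
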