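#' Maximum-likelihood Weibull fit to right-censored data
#'
#' Maximises the right-censored Weibull log-likelihood
#' \deqn{\ell(\lambda,\gamma) = \sum_{events}\log(\lambda\gamma t^{\gamma-1})
#'   - \sum_{all} \lambda t^{\gamma}}
#' over \eqn{(\log\lambda, \log\gamma)} with BFGS from the fixed starting
#' point \eqn{\gamma = 1}, \eqn{\lambda = \#events / \sum t} (the exponential
#' MLE), so fits are deterministic. AIC and BIC are reported for comparison
#' with alternative parametric families.
#'
#' @param ipd A [pseudo_ipd()] with at least 2 records and at least 1 event.
#' @return A `fit_report` list: `curve` ([weibull_curve()]), `loglik`,
#'   `aic`, `bic`, `n_params` (2), `n_obs`, `convergence` (0 = converged).
#' @examples
#' ipd <- simulate_ipd(weibull_curve(0.04, 1.28), n = 500, seed = 1)
#' fit_weibull_mle(ipd)
#' @export
fit_weibull_mle <- function(ipd) {
  stopifnot(inherits(ipd, "pseudo_ipd"))
  if (nrow(ipd) < 2L) {
    stop("fit_weibull_mle: need at least 2 records", call. = FALSE)
  }
  n_events <- sum(ipd$event)
  if (n_events < 1) {
    stop("fit_weibull_mle: no events; parameters are not identifiable",
         call. = FALSE)
  }
  t <- pmax(ipd$time, .Machine$double.eps)  # guard log(0) for exact zeros
  ev <- ipd$event == 1
  negll <- function(par) {
    lam <- exp(par[1]); gam <- exp(par[2])
    -(sum(log(lam * gam) + (gam - 1) * log(t[ev])) - lam * sum(t^gam))
  }
  start <- c(log(n_events / sum(t)), 0)
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 500L))
  if (opt$convergence != 0) {
    stop("fit_weibull_mle: optimizer did not converge (code ",
         opt$convergence, ")", call. = FALSE)
  }
  ll <- -opt$value
  k <- 2L
  n <- nrow(ipd)
  structure(list(curve = weibull_curve(exp(opt$par[1]), exp(opt$par[2])),
                 loglik = ll,
                 aic = 2 * k - 2 * ll,
                 bic = k * log(n) - 2 * ll,
                 n_params = k,
                 n_obs = n,
                 convergence = opt$convergence),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf(
    "Weibull MLE: scale %.6g, shape %.6g (n = %d, logLik %.4f, AIC %.2f, BIC %.2f)\n",
    x$curve$scale, x$curve$shape, x$n_obs, x$loglik, x$aic, x$bic))
  invisible(x)
}

#' Export a fit report as a flat one-row data frame
#'
#' @param x A `fit_report`.
#' @return A one-row `data.frame` (scale, shape, loglik, aic, bic, n_params,
#'   n_obs), suitable for `write.csv`.
#' @export
fit_report_row <- function(x) {
  stopifnot(inherits(x, "fit_report"))
  data.frame(scale = x$curve$scale, shape = x$curve$shape,
             loglik = x$loglik, aic = x$aic, bic = x$bic,
             n_params = x$n_params, n_obs = x$n_obs)
}

#' Fit a Weibull curve to digitized Kaplan-Meier coordinates
#'
#' Ordinary least squares on the complementary-log-log scale: for the
#' Weibull law \eqn{\log(-\log S(t)) = \log\lambda + \gamma \log t}, so a
#' line through the transformed digitized points gives shape as the slope
#' and log-scale as the intercept. Points with survival exactly 0 or 1
#' (including the mandatory anchor at t = 0) carry no information on this
#' scale and are excluded.
#'
#' @param points A [km_points()] object with at least 3 usable points
#'   (0 < survival < 1).
#' @return A [weibull_curve()].
#' @examples
#' pts <- generate_km_points(weibull_curve(0.04, 1.28), grid = 0:24)
#' fit_weibull_to_km_points(pts)
#' @export
fit_weibull_to_km_points <- function(points) {
  stopifnot(inherits(points, "km_points"))
  use <- points$survival > 0 & points$survival < 1 & points$time > 0
  if (sum(use) < 3L) {
    stop("fit_weibull_to_km_points: fewer than 3 usable points ",
         "(0 < survival < 1)", call. = FALSE)
  }
  x <- log(points$time[use])
  y <- log(-log(points$survival[use]))
  fit <- stats::lm.fit(cbind(1, x), y)
  weibull_curve(scale = exp(fit$coefficients[[1]]),
                shape = fit$coefficients[[2]])
}
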