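#' Enumerate the tunable parameters of a configuration
#'
#' Walks the configuration and returns one row per parameter that the
#' sensitivity analyses vary: the pooled hazard ratios, the discount rate,
#' per-cycle drug prices, adverse-event management costs, incidences and
#' disutilities, and the state utilities. Each row carries the config path
#' its value lives at (see [config_get()]), its baseline and one-way
#' bounds, the probabilistic distribution family and a role tag.
#'
#' Families follow standard practice for such models: beta for
#' probabilities and utilities, gamma for costs and disutilities, and
#' normal for hazard ratios — applied on the log-HR scale by default
#' (`settings/hr_sampling: lognormal`) because published HR intervals are
#' asymmetric around the point estimate; `natural` switches to a normal on
#' the HR scale truncated at zero. A parameter whose baseline and bounds
#' are all zero (an event absent from one arm) is marked `fixed` and never
#' sampled. The discount rate is varied in the one-way analysis only.
#'
#' @param config An `analysis_config`.
#' @return A `data.frame`: `name`, `path`, `baseline`, `low`, `high`,
#'   `family` (`beta|gamma|normal|fixed`), `role`.
#' @export
enumerate_parameters <- function(config) {
  rows <- list()
  add <- function(name, path, family, role, block = NULL,
                  baseline = NULL, low = NULL, high = NULL) {
    if (!is.null(block)) {
      baseline <- block$baseline; low <- block$low; high <- block$high
    }
    if (family == "beta" && baseline == 0 && low == 0 && high == 0) {
      family <- "fixed"
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, path = path, baseline = baseline, low = low,
      high = high, family = family, role = role)
  }
  for (ep in c("pfs", "os")) {
    add(paste0("hr_", ep), sprintf("hazard_ratios/%s/baseline", ep),
        "normal", "hr", block = config$hazard_ratios[[ep]])
  }
  add("discount_rate", "settings/annual_discount", "fixed", "discount",
      baseline = config$settings$annual_discount,
      low = config$discount_range$low, high = config$discount_range$high)
  for (d in names(config$drug_costs)) {
    add(paste0("cost_", d), sprintf("drug_costs/%s/baseline", d),
        "gamma", "cost", block = config$drug_costs[[d]])
  }
  for (ae in config$adverse_events) {
    add(paste0("cost_ae_", ae$name),
        sprintf("adverse_events/%s/cost/baseline", ae$name),
        "gamma", "cost", block = ae$cost)
    add(paste0("disutility_", ae$name),
        sprintf("adverse_events/%s/disutility/baseline", ae$name),
        "gamma", "disutility", block = ae$disutility)
    for (arm in names(ae$incidence)) {
      add(sprintf("incidence_%s_%s", ae$name, arm),
          sprintf("adverse_events/%s/incidence/%s/baseline", ae$name, arm),
          "beta", "probability", block = ae$incidence[[arm]])
    }
  }
  add("utility_pfs", "utilities/pfs/baseline", "beta", "utility",
      block = config$utilities$pfs)
  add("utility_pd", "utilities/pd/baseline", "beta", "utility",
      block = config$utilities$pd)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Method-of-moments distribution parameters for one sampled quantity
#'
#' Given a parameter's mean and standard error, returns the distribution
#' parameters matching those first two moments: beta
#' \eqn{\alpha = m(m(1-m)/s^2 - 1)}, \eqn{\beta = (1-m)(m(1-m)/s^2 - 1)};
#' gamma shape \eqn{m^2/s^2}, rate \eqn{m/s^2}; normal \eqn{(m, s)}. When
#' no explicit `se` is supplied it is derived from the one-way bounds as
#' `(high - low) / (2 * 1.959964)`, treating the range as a 95 percent
#' interval. A zero standard error (or a `fixed` family) degenerates to a
#' point mass.
#'
#' @param spec A one-row slice of [enumerate_parameters()] output, or any
#'   list with `baseline`, `low`, `high`, `family` (and optionally `se`).
#' @return A `list(family, mean, se, ...)` with family-specific parameter
#'   fields (`alpha`/`beta`, `shape`/`rate`, or `sd`).
#' @examples
#' method_of_moments(list(baseline = 0.5, low = 0.304, high = 0.696,
#'                        family = "beta", se = 0.1))
#' @export
method_of_moments <- function(spec) {
  m <- spec$baseline
  s <- if (!is.null(spec$se) && !is.na(spec$se)) {
    spec$se
  } else {
    (spec$high - spec$low) / (2 * stats::qnorm(0.975))
  }
  fam <- spec$family
  if (fam == "fixed" || s == 0) {
    return(list(family = "fixed", mean = m, se = 0))
  }
  if (fam == "beta") {
    if (m <= 0 || m >= 1) {
      stop("method_of_moments: beta requires mean in (0, 1), got ", m,
           call. = FALSE)
    }
    if (s^2 >= m * (1 - m)) {
      stop("method_of_moments: infeasible beta moments (s^2 >= m(1-m))",
           call. = FALSE)
    }
    nu <- m * (1 - m) / s^2 - 1
    return(list(family = "beta", mean = m, se = s,
                alpha = m * nu, beta = (1 - m) * nu))
  }
  if (fam == "gamma") {
    if (m <= 0) {
      stop("method_of_moments: gamma requires mean > 0, got ", m,
           call. = FALSE)
    }
    return(list(family = "gamma", mean = m, se = s,
                shape = m^2 / s^2, rate = m / s^2))
  }
  if (fam == "normal") {
    return(list(family = "normal", mean = m, se = s, sd = s))
  }
  stop("method_of_moments: unknown family '", fam, "'", call. = FALSE)
}

#' Draw from a method-of-moments distribution
#'
#' @param mom Output of [method_of_moments()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`. Uses the current RNG stream.
#' @export
sample_parameter <- function(mom, n = 1L) {
  switch(mom$family,
         fixed = rep(mom$mean, n),
         beta = stats::rbeta(n, mom$alpha, mom$beta),
         gamma = stats::rgamma(n, shape = mom$shape, rate = mom$rate),
         normal = stats::rnorm(n, mom$mean, mom$sd),
         stop("sample_parameter: unknown family '", mom$family, "'",
              call. = FALSE))
}

# hazard ratios get their own sampler: by default normal on the log scale
# with SE from the log-CI width (published HR intervals are asymmetric);
# optionally a natural-scale normal truncated at zero.
hr_sampler <- function(block, mode = c("lognormal", "natural")) {
  mode <- match.arg(mode)
  if (mode == "lognormal") {
    mu <- log(block$baseline)
    sdlog <- (log(block$high) - log(block$low)) / (2 * stats::qnorm(0.975))
    function(n) stats::rlnorm(n, mu, sdlog)
  } else {
    s <- (block$high - block$low) / (2 * stats::qnorm(0.975))
    function(n) {
      x <- stats::rnorm(n, block$baseline, s)
      while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad),
                                                        block$baseline, s)
      x
    }
  }
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Sets each parameter in turn to its low and then its high bound, reruns
#' the full base case with everything else untouched, and records the ICER
#' per QALY at each bound. Entries are sorted by bar width (absolute ICER
#' swing), the ordering of a tornado diagram.
#'
#' @param config An `analysis_config`.
#' @param parameters Parameter table as from [enumerate_parameters()];
#'   default all of it. A `name` not resolvable in the config errors.
#' @return A `data.frame` of class `tornado`: `parameter`, `icer_low`,
#'   `icer_high`, `width`, plus the baseline ICER as attribute
#'   `"icer_base"`.
#' @export
one_way_dsa <- function(config, parameters = enumerate_parameters(config)) {
  stopifnot(inherits(config, "analysis_config"))
  base_icer <- run_base_case(config)$incremental$icer_qaly
  icer_at <- function(path, value) {
    run_base_case(config_set(config, path, value))$incremental$icer_qaly
  }
  out <- do.call(rbind, lapply(seq_len(nrow(parameters)), function(i) {
    p <- parameters[i, ]
    lo <- icer_at(p$path, p$low)
    hi <- icer_at(p$path, p$high)
    data.frame(parameter = p$name, icer_low = lo, icer_high = hi,
               width = abs(hi - lo))
  }))
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "icer_base") <- base_icer
  class(out) <- c("tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo resampling of every non-fixed parameter from its
#' method-of-moments distribution (hazard ratios per the configured
#' sampling mode), with both arms re-evaluated under each shared draw. The
#' summary reports the means of the incremental quantities and the
#' probabilistic ICER as the ratio of means — the mean of per-draw ratios
#' is unstable when the QALY difference changes sign and is returned only
#' as a diagnostic.
#'
#' @param config An `analysis_config`.
#' @param n_draws Number of Monte-Carlo replications (default 5000).
#' @param seed Integer seed; identical `(config, n_draws, seed)` give
#'   identical draws. The caller's RNG state is preserved.
#' @param parameters Optional parameter table in the format of
#'   [enumerate_parameters()] (its default), e.g. with distribution
#'   families overridden; rows with role `discount` or family `fixed` are
#'   never sampled.
#' @return A `psa_result` list: `samples` (`data.frame` with `draw`,
#'   `delta_cost`, `delta_qaly`), `summary` (`mean_delta_cost`,
#'   `mean_delta_qaly`, `mean_delta_ly`, `icer` = ratio of means,
#'   `mean_ratio_diagnostic`), `n_draws`, `seed`.
#' @export
run_psa <- function(config, n_draws = 5000L, seed = 1L, parameters = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (n_draws < 1) stop("run_psa: `n_draws` must be >= 1", call. = FALSE)
  params <- if (is.null(parameters)) enumerate_parameters(config) else parameters
  params <- params[params$role != "discount", , drop = FALSE]
  hr_mode <- config$settings$hr_sampling %||% "lognormal"
  samplers <- lapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    if (p$role == "hr" && p$family != "fixed") {
      hr_sampler(list(baseline = p$baseline, low = p$low, high = p$high),
                 hr_mode)
    } else {
      mom <- method_of_moments(p)
      function(n) sample_parameter(mom, n)
    }
  })
  local_seed(seed)
  draws <- vapply(samplers, function(s) s(n_draws), numeric(n_draws))
  if (n_draws == 1L) draws <- matrix(draws, nrow = 1L)
  colnames(draws) <- params$name
  res <- matrix(NA_real_, n_draws, 3,
                dimnames = list(NULL, c("delta_cost", "delta_qaly",
                                        "delta_ly")))
  cfg_i <- config
  for (i in seq_len(n_draws)) {
    cfg_i <- config
    for (j in seq_len(nrow(params))) {
      cfg_i <- config_set(cfg_i, params$path[j], draws[i, j])
    }
    bc <- run_base_case(cfg_i)
    res[i, ] <- c(bc$incremental$delta_cost, bc$incremental$delta_qaly,
                  bc$incremental$delta_ly)
  }
  samples <- data.frame(draw = seq_len(n_draws), res)
  summary <- list(
    mean_delta_cost = mean(samples$delta_cost),
    mean_delta_qaly = mean(samples$delta_qaly),
    mean_delta_ly = mean(samples$delta_ly),
    icer = mean(samples$delta_cost) / mean(samples$delta_qaly),
    mean_ratio_diagnostic = mean(samples$delta_cost / samples$delta_qaly))
  structure(list(samples = samples, summary = summary,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("PSA (%d draws, seed %d)\n", x$n_draws, x$seed))
  cat(sprintf("  mean dCost $%.2f, mean dQALY %.4f, ICER (ratio of means) $%.2f/QALY\n",
              s$mean_delta_cost, s$mean_delta_qaly, s$icer))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold w, the probability that the
#' reference strategy is cost-effective is the fraction of draws with
#' positive net monetary benefit, `w * dQALY - dCost > 0`; the comparator
#' receives the complement (ties count for the comparator, so the two
#' curves sum to one at every threshold).
#'
#' @param samples The `samples` data frame of a [run_psa()] result (or the
#'   `psa_result` itself).
#' @param wtp_grid Thresholds in USD per QALY; the default grid, 0 to
#'   50,000 by 500, contains both GDP-based thresholds exactly.
#' @return A `data.frame`: `wtp`, `p_reference`, `p_comparator`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 50000, by = 500)) {
  if (inherits(samples, "psa_result")) samples <- samples$samples
  if (!is.data.frame(samples) || nrow(samples) == 0L ||
      !all(c("delta_cost", "delta_qaly") %in% names(samples))) {
    stop("ceac: `samples` must be a non-empty PSA sample table",
         call. = FALSE)
  }
  if (length(wtp_grid) == 0L) {
    stop("ceac: `wtp_grid` must be non-empty", call. = FALSE)
  }
  p_ref <- vapply(wtp_grid, function(w) {
    mean(w * samples$delta_qaly - samples$delta_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, p_reference = p_ref, p_comparator = 1 - p_ref)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
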