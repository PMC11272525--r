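#' Simulate pseudo individual-patient data from a Weibull curve
#'
#' Draws event times from \eqn{S(t) = \exp(-\lambda t^\gamma)} by inverse
#' transform, applies independent exponential censoring at rate
#' `censor_hazard` (per month) and an administrative cutoff at
#' `admin_cutoff` months, and records the earlier of the three as the
#' observation time. This emulates the follow-up process behind a trial's
#' Kaplan-Meier curve so that curve-fitting code can be tested against a
#' known generating law.
#'
#' @param curve Generating [weibull_curve()].
#' @param n Number of patients (>= 1).
#' @param censor_hazard Exponential censoring rate per month (>= 0; 0
#'   disables random censoring).
#' @param admin_cutoff Administrative censoring time in months (> 0; `Inf`
#'   disables it).
#' @param seed Integer seed; identical arguments give identical output. The
#'   caller's RNG state is left untouched.
#' @return A [pseudo_ipd()].
#' @examples
#' ipd <- simulate_ipd(weibull_curve(0.04, 1.28), n = 100,
#'                     censor_hazard = 0.02, admin_cutoff = 30, seed = 1)
#' mean(ipd$event)
#' @export
simulate_ipd <- function(curve, n, censor_hazard = 0, admin_cutoff = Inf,
                         seed = 1L) {
  stopifnot(inherits(curve, "weibull_curve"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("simulate_ipd: `n` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(censor_hazard) || censor_hazard < 0) {
    stop("simulate_ipd: `censor_hazard` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(admin_cutoff) || admin_cutoff <= 0) {
    stop("simulate_ipd: `admin_cutoff` must be > 0", call. = FALSE)
  }
  local_seed(seed)
  # inverse transform: t = (-log U / lambda)^(1/gamma)
  u <- stats::runif(n)
  t_event <- (-log(u) / curve$scale)^(1 / curve$shape)
  t_cens <- if (censor_hazard > 0) {
    stats::rexp(n, rate = censor_hazard)
  } else {
    rep(Inf, n)
  }
  obs <- pmin(t_event, t_cens, admin_cutoff)
  event <- as.numeric(t_event <= pmin(t_cens, admin_cutoff))
  pseudo_ipd(time = obs, event = event)
}

#' Noiseless digitized curve coordinates from a Weibull law
#'
#' Evaluates the curve on a time grid, producing the idealised output of a
#' figure-digitization step (no reading error).
#'
#' @param curve A [weibull_curve()].
#' @param grid Ascending times in months, starting at 0. Default: monthly
#'   from 0 to 36, a typical published KM axis.
#' @return A [km_points()] object.
#' @export
generate_km_points <- function(curve, grid = 0:36) {
  stopifnot(inherits(curve, "weibull_curve"), is.numeric(grid))
  if (length(grid) < 1L || grid[1] != 0 || any(diff(grid) <= 0)) {
    stop("generate_km_points: `grid` must be sorted ascending and start at 0",
         call. = FALSE)
  }
  km_points(time = grid, survival = weibull_survival(curve, grid))
}

#' Trial-level log hazard-ratio table
#'
#' One row per pairwise comparison reported by a trial: the two treatment
#' labels, the estimated log hazard ratio of `arm_a` versus `arm_b`, its
#' standard error, and the endpoint (`"PFS"` or `"OS"`). The rows of each
#' endpoint must form a connected treatment network.
#'
#' @param trial Character trial identifiers.
#' @param arm_a,arm_b Treatment labels.
#' @param loghr Log hazard ratios (arm_a vs arm_b).
#' @param se Positive standard errors of `loghr`.
#' @param endpoint `"PFS"` or `"OS"` per row.
#' @return A `data.frame` of class `trial_hr_table`.
#' @export
trial_hr_table <- function(trial, arm_a, arm_b, loghr, se,
                           endpoint = "PFS") {
  d <- data.frame(trial = as.character(trial),
                  arm_a = as.character(arm_a),
                  arm_b = as.character(arm_b),
                  loghr = as.numeric(loghr),
                  se = as.numeric(se),
                  endpoint = as.character(endpoint))
  if (nrow(d) < 1L) stop("trial_hr_table: empty table", call. = FALSE)
  if (any(!is.finite(d$se)) || any(d$se <= 0)) {
    stop("trial_hr_table: standard errors must be > 0", call. = FALSE)
  }
  if (any(d$arm_a == d$arm_b)) {
    stop("trial_hr_table: self-comparisons are not allowed", call. = FALSE)
  }
  if (!all(d$endpoint %in% c("PFS", "OS"))) {
    stop("trial_hr_table: endpoint must be 'PFS' or 'OS'", call. = FALSE)
  }
  structure(d, class = c("trial_hr_table", "data.frame"))
}

#' Generate a synthetic trial-level hazard-ratio table
#'
#' Takes a set of network edges with true log hazard ratios and standard
#' errors, checks the network is connected, and returns a
#' [trial_hr_table()] whose per-row estimates are the true values plus
#' independent normal noise with the stated standard errors. The ground
#' truth being known, the network meta-analysis engine can be validated
#' against it.
#'
#' @param edges A `data.frame` with columns `trial`, `arm_a`, `arm_b`,
#'   `true_loghr`, `se`, and optionally `endpoint` (default `"PFS"`).
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @return A [trial_hr_table()].
#' @examples
#' chain <- data.frame(trial = c("T1", "T2", "T3"),
#'                     arm_a = c("CTC", "TC", "GP"),
#'                     arm_b = c("TC", "GP", "SGP"),
#'                     true_loghr = c(-0.3, 0.1, 0.1),
#'                     se = c(0.1, 0.1, 0.1))
#' generate_trial_table(chain, seed = 1)
#' @export
generate_trial_table <- function(edges, seed = 1L) {
  req <- c("trial", "arm_a", "arm_b", "true_loghr", "se")
  if (!is.data.frame(edges) || !all(req %in% names(edges))) {
    stop("generate_trial_table: `edges` needs columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(edges$se <= 0)) {
    stop("generate_trial_table: standard errors must be > 0", call. = FALSE)
  }
  if (!network_connected(edges$arm_a, edges$arm_b)) {
    stop("generate_trial_table: treatment network is not connected",
         call. = FALSE)
  }
  endpoint <- if ("endpoint" %in% names(edges)) edges$endpoint else "PFS"
  local_seed(seed)
  est <- edges$true_loghr + stats::rnorm(nrow(edges), sd = edges$se)
  trial_hr_table(trial = edges$trial, arm_a = edges$arm_a,
                 arm_b = edges$arm_b, loghr = est, se = edges$se,
                 endpoint = endpoint)
}

#' @rdname ipd_io
#' @export
write_trial_table <- function(x, path) {
  stopifnot(inherits(x, "trial_hr_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname ipd_io
#' @export
read_trial_table <- function(path) {
  d <- utils::read.csv(path)
  trial_hr_table(d$trial, d$arm_a, d$arm_b, d$loghr, d$se, d$endpoint)
}

# breadth-first search over the undirected edge list
network_connected <- function(arm_a, arm_b) {
  nodes <- unique(c(arm_a, arm_b))
  if (length(nodes) <= 1L) return(TRUE)
  seen <- nodes[1]
  frontier <- nodes[1]
  while (length(frontier) > 0L) {
    nxt <- unique(c(arm_b[arm_a %in% frontier], arm_a[arm_b %in% frontier]))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  length(seen) == length(nodes)
}

# run expr-free seeded draws without clobbering the caller's RNG stream
local_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  parent <- parent.frame()
  if (is.null(old)) {
    do.call(on.exit,
            list(quote(rm(".Random.seed", envir = globalenv())), add = TRUE),
            envir = parent)
  } else {
    do.call(on.exit,
            list(bquote(assign(".Random.seed", .(old), envir = globalenv())),
                 add = TRUE),
            envir = parent)
  }
  set.seed(as.integer(seed))
  invisible(NULL)
}
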