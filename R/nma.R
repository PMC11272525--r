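#' Fixed-effect network meta-analysis of log hazard ratios
#'
#' Pools trial-level log hazard ratios over a connected treatment network
#' by inverse-variance weighted least squares on the edge-incidence matrix
#' (the graph-theoretical formulation: the normal equations involve the
#' weighted graph Laplacian, solved here with the reference treatment's
#' column removed). For a path-shaped network this reduces exactly to the
#' Bucher chain: log effects add along the path and variances add.
#'
#' @param table A [trial_hr_table()] (single endpoint; filter first if the
#'   table mixes PFS and OS rows).
#' @param reference Treatment label to express all contrasts against.
#' @return A `data.frame` with one row per non-reference treatment:
#'   `treatment`, `loghr` (the pooled log hazard ratio of the *reference
#'   versus* that treatment — the direction in which a reference-vs-
#'   comparator HR enters the economic model), `se`, `hr`, `ci_low`,
#'   `ci_high` (95\%).
#' @examples
#' tab <- trial_hr_table(trial = c("T1", "T2", "T3"),
#'                       arm_a = c("CTC", "TC", "GP"),
#'                       arm_b = c("TC", "GP", "SGP"),
#'                       loghr = c(-0.3, 0.1, 0.1),
#'                       se = c(0.1, 0.1, 0.1))
#' pool_network(tab, reference = "CTC")
#' @export
pool_network <- function(table, reference) {
  stopifnot(inherits(table, "trial_hr_table"))
  if (length(unique(table$endpoint)) > 1L) {
    stop("pool_network: table mixes endpoints; pool one endpoint at a time",
         call. = FALSE)
  }
  trts <- sort(unique(c(table$arm_a, table$arm_b)))
  if (!reference %in% trts) {
    stop("pool_network: reference '", reference, "' not in the network",
         call. = FALSE)
  }
  if (!network_connected(table$arm_a, table$arm_b)) {
    stop("pool_network: treatment network is not connected", call. = FALSE)
  }
  # incidence matrix: row e has +1 at arm_a, -1 at arm_b
  m <- nrow(table)
  X <- matrix(0, m, length(trts), dimnames = list(NULL, trts))
  X[cbind(seq_len(m), match(table$arm_a, trts))] <- 1
  X[cbind(seq_len(m), match(table$arm_b, trts))] <- -1
  X <- X[, trts != reference, drop = FALSE]
  w <- 1 / table$se^2
  XtWX <- crossprod(X, w * X)
  beta <- solve(XtWX, crossprod(X, w * table$loghr))
  covb <- solve(XtWX)
  # beta holds treatment-vs-reference effects; report reference-vs-treatment
  out <- data.frame(treatment = colnames(X),
                    loghr = -as.numeric(beta),
                    se = sqrt(diag(covb)))
  z <- stats::qnorm(0.975)
  out$hr <- exp(out$loghr)
  out$ci_low <- exp(out$loghr - z * out$se)
  out$ci_high <- exp(out$loghr + z * out$se)
  rownames(out) <- NULL
  out
}

#' Summarise a pooled log hazard ratio as an HR with confidence interval
#'
#' @param loghr Log hazard ratio.
#' @param se Positive standard error of `loghr`.
#' @param level Confidence level in (0, 1); default 0.95.
#' @param endpoint Optional endpoint tag (`"PFS"` or `"OS"`).
#' @return A `hazard_ratio_estimate` list: `hr`, `ci_low`, `ci_high`,
#'   `se_log`, `level`, `endpoint`.
#' @examples
#' summarize_hr(log(0.75), se = 0.115)
#' @export
summarize_hr <- function(loghr, se, level = 0.95, endpoint = NA_character_) {
  stopifnot(is.numeric(loghr), length(loghr) == 1L)
  if (!is.numeric(se) || length(se) != 1L || se <= 0) {
    stop("summarize_hr: `se` must be > 0", call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("summarize_hr: `level` must lie in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(hr = exp(loghr),
                 ci_low = exp(loghr - z * se),
                 ci_high = exp(loghr + z * se),
                 se_log = se,
                 level = level,
                 endpoint = endpoint),
            class = "hazard_ratio_estimate")
}

#' Reconstruct a hazard-ratio estimate from published point and interval
#'
#' The log-scale standard error is recovered from the interval width:
#' `se = (log(ci_high) - log(ci_low)) / (2 z)`.
#'
#' @param hr Point estimate (> 0).
#' @param ci_low,ci_high Confidence bounds (> 0), `ci_low <= hr <= ci_high`.
#' @inheritParams summarize_hr
#' @return A `hazard_ratio_estimate`.
#' @export
hazard_ratio_estimate <- function(hr, ci_low, ci_high, level = 0.95,
                                  endpoint = NA_character_) {
  stopifnot(hr > 0, ci_low > 0, ci_high > 0)
  if (ci_low > hr || hr > ci_high) {
    stop("hazard_ratio_estimate: require ci_low <= hr <= ci_high",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- (log(ci_high) - log(ci_low)) / (2 * z)
  structure(list(hr = hr, ci_low = ci_low, ci_high = ci_high,
                 se_log = se, level = level, endpoint = endpoint),
            class = "hazard_ratio_estimate")
}

#' @export
print.hazard_ratio_estimate <- function(x, ...) {
  cat(sprintf("HR %.3f (%.0f%% CI %.3f-%.3f)%s\n", x$hr, 100 * x$level,
              x$ci_low, x$ci_high,
              if (is.na(x$endpoint)) "" else paste0(" [", x$endpoint, "]")))
  invisible(x)
}
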