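#' Load and validate an analysis configuration
#'
#' The configuration is a nested YAML document holding every model input:
#' global settings, reference-arm Weibull curves, pooled hazard ratios,
#' per-cycle drug prices, adverse-event incidences/costs/disutilities,
#' state utilities and strategy drug schedules. The packaged default
#' (`system.file("extdata", "default_config.yaml", package = "psmcea")`)
#' is the single source of the base-case parameter values; the engine
#' modules contain none of them.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `analysis_config` (nested named list).
#' @seealso [default_config()], [validate_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("load_config: file not found: ", path, call. = FALSE)
  }
  config <- yaml::read_yaml(path)
  validate_config(config)
}

#' @rdname load_config
#' @export
default_config <- function() {
  load_config(system.file("extdata", "default_config.yaml",
                          package = "psmcea", mustWork = TRUE))
}

#' Write a configuration back to YAML
#'
#' @param config An `analysis_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a configuration
#'
#' Checks presence and typing of every required field and the cross-field
#' invariants (two strategies, resolvable drug references, probabilities in
#' range). Violations raise an error naming the offending field path; a
#' baseline lying outside its stated low/high range (which occurs verbatim
#' in published parameter tables) is reported as a warning, not an error.
#'
#' @param config A nested list as produced by [load_config()].
#' @return The config, classed `analysis_config`, invisibly valid.
#' @export
validate_config <- function(config) {
  fail <- function(path, msg) {
    stop("config validation: ", paste(path, collapse = "/"), ": ", msg,
         call. = FALSE)
  }
  need <- function(path) {
    x <- config
    for (k in path) {
      if (is.list(x) && is.null(names(x)) && is.character(k)) {
        idx <- which(vapply(x, function(e) identical(e$name, k), logical(1)))
        if (length(idx) != 1L) fail(path, "missing")
        x <- x[[idx]]
      } else if (is.null(x <- x[[k]])) {
        fail(path, "missing")
      }
    }
    x
  }
  num <- function(path, lo = -Inf, hi = Inf) {
    x <- need(path)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      fail(path, "must be a single finite number")
    }
    if (x < lo || x > hi) {
      fail(path, sprintf("must lie in [%g, %g], got %g", lo, hi, x))
    }
    x
  }
  range_block <- function(path, lo = -Inf, hi = Inf) {
    b <- num(c(path, "baseline"), lo, hi)
    l <- num(c(path, "low"), lo, hi)
    h <- num(c(path, "high"), lo, hi)
    if (l > h) fail(path, "low bound exceeds high bound")
    if (b < l || b > h) {
      warning("config: ", paste(path, collapse = "/"),
              sprintf(": baseline %g outside [%g, %g] (kept as given)",
                      b, l, h), call. = FALSE)
    }
    invisible(NULL)
  }

  num(c("metadata", "cny_per_usd"), lo = 0)
  ref <- need(c("metadata", "reference_arm"))
  cmp <- need(c("metadata", "comparator_arm"))

  num(c("settings", "cycle_length_days"), lo = 1e-9)
  num(c("settings", "n_cycles"), lo = 1)
  num(c("settings", "annual_discount"), lo = 0, hi = 1 - 1e-12)
  if (num(c("settings", "wtp_low"), lo = 0) >
      num(c("settings", "wtp_high"), lo = 0)) {
    fail(c("settings", "wtp_low"), "exceeds wtp_high")
  }
  for (ep in c("pfs", "os")) {
    num(c("survival", ep, "scale"), lo = 1e-12)
    num(c("survival", ep, "shape"), lo = 1e-12)
    range_block(c("hazard_ratios", ep), lo = 1e-12)
  }
  num(c("discount_range", "low"), lo = 0, hi = 1)
  num(c("discount_range", "high"), lo = 0, hi = 1)

  drugs <- need("drug_costs")
  for (d in names(drugs)) range_block(c("drug_costs", d), lo = 0)

  aes <- need("adverse_events")
  arms <- c(ref, cmp)
  for (i in seq_along(aes)) {
    ae <- aes[[i]]
    if (is.null(ae$name)) fail(c("adverse_events", i), "missing name")
    range_block(c("adverse_events", ae$name, "cost"), lo = 0)
    range_block(c("adverse_events", ae$name, "disutility"), lo = 0, hi = 1)
    for (arm in arms) {
      range_block(c("adverse_events", ae$name, "incidence", arm),
                  lo = 0, hi = 1)
    }
  }
  range_block(c("utilities", "pfs"), lo = 0, hi = 1)
  range_block(c("utilities", "pd"), lo = 0, hi = 1)

  strategies <- need("strategies")
  if (!setequal(names(strategies), arms)) {
    fail("strategies", paste0("must define exactly the arms ",
                              paste(arms, collapse = " and ")))
  }
  for (arm in arms) {
    ind <- need(c("strategies", arm, "induction_drugs"))
    for (d in c(unlist(ind), need(c("strategies", arm, "maintenance_drug")))) {
      if (is.null(drugs[[d]])) {
        fail(c("strategies", arm), paste0("unknown drug '", d, "'"))
      }
    }
    num(c("strategies", arm, "maintenance_cap_months"), lo = 1e-9)
    num(c("strategies", arm, "n_induction_cycles"), lo = 1)
  }
  structure(config, class = c("analysis_config", "list"))
}

#' Get or set a configuration value by path
#'
#' Paths are slash-separated keys into the nested configuration, e.g.
#' `"drug_costs/paclitaxel/baseline"` or
#' `"adverse_events/rccep/incidence/CTC/baseline"`. Within the
#' `adverse_events` list, the second component matches the entry's `name`
#' field. These paths are how the sensitivity-analysis machinery addresses
#' every tunable parameter.
#'
#' @param config An `analysis_config`.
#' @param path Slash-separated path string.
#' @param value Replacement value (for `config_set`).
#' @return `config_get`: the value; `config_set`: the modified config.
#' @export
config_get <- function(config, path) {
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  x <- config
  for (j in seq_along(keys)) {
    k <- keys[j]
    if (is.list(x) && is.null(names(x)) && !grepl("^[0-9]+$", k)) {
      idx <- which(vapply(x, function(e) identical(e$name, k), logical(1)))
      if (length(idx) != 1L) {
        stop("config path not found: ", path, call. = FALSE)
      }
      x <- x[[idx]]
    } else {
      if (is.null(x[[k]])) stop("config path not found: ", path, call. = FALSE)
      x <- x[[k]]
    }
  }
  x
}

#' @rdname config_get
#' @export
config_set <- function(config, path, value) {
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  set_rec <- function(x, keys) {
    k <- keys[1]
    if (is.list(x) && is.null(names(x)) && !grepl("^[0-9]+$", k)) {
      idx <- which(vapply(x, function(e) identical(e$name, k), logical(1)))
      if (length(idx) != 1L) {
        stop("config path not found: ", path, call. = FALSE)
      }
      k <- idx
    } else if (is.null(x[[k]])) {
      stop("config path not found: ", path, call. = FALSE)
    }
    if (length(keys) == 1L) {
      x[[k]] <- value
    } else {
      x[[k]] <- set_rec(x[[k]], keys[-1])
    }
    x
  }
  out <- set_rec(unclass(config), keys)
  structure(out, class = c("analysis_config", "list"))
}

# ---- config -> model objects -------------------------------------------

config_settings <- function(config) {
  s <- config$settings
  model_settings(cycle_length_days = s$cycle_length_days,
                 n_cycles = s$n_cycles,
                 annual_discount = s$annual_discount,
                 wtp_low = s$wtp_low, wtp_high = s$wtp_high,
                 cycle_eval = s$cycle_eval,
                 ae_cost_timing = s$ae_cost_timing,
                 ae_disutility_timing = s$ae_disutility_timing,
                 hr_direction = s$hr_direction)
}

config_strategy <- function(config, arm) {
  sc <- config$strategies[[arm]]
  drugs <- config$drug_costs
  induction <- data.frame(
    drug = unlist(sc$induction_drugs),
    cost_per_cycle = vapply(sc$induction_drugs,
                            function(d) drugs[[d]]$baseline, numeric(1)))
  aes <- config$adverse_events
  ae_tab <- data.frame(
    name = vapply(aes, `[[`, character(1), "name"),
    incidence = vapply(aes, function(a) a$incidence[[arm]]$baseline,
                       numeric(1)),
    cost = vapply(aes, function(a) a$cost$baseline, numeric(1)),
    disutility = vapply(aes, function(a) a$disutility$baseline, numeric(1)))
  strategy_spec(name = arm,
                induction = induction,
                maintenance_drug = sc$maintenance_drug,
                maintenance_cost = drugs[[sc$maintenance_drug]]$baseline,
                maintenance_cap_months = sc$maintenance_cap_months,
                n_induction_cycles = sc$n_induction_cycles,
                adverse_events = ae_tab,
                utility_pfs = config$utilities$pfs$baseline,
                utility_pd = config$utilities$pd$baseline)
}

config_curves <- function(config) {
  ref_pfs <- weibull_curve(config$survival$pfs$scale,
                           config$survival$pfs$shape)
  ref_os <- weibull_curve(config$survival$os$scale, config$survival$os$shape)
  dir <- config$settings$hr_direction
  list(reference = list(pfs = ref_pfs, os = ref_os),
       comparator = list(
         pfs = adjust_curve_by_hr(ref_pfs,
                                  config$hazard_ratios$pfs$baseline, dir),
         os = adjust_curve_by_hr(ref_os,
                                 config$hazard_ratios$os$baseline, dir)))
}

#' Run the deterministic base case from a configuration
#'
#' Builds both arms' curves (comparator via hazard-ratio adjustment),
#' traces, and accruals, and computes the incremental comparison of the
#' reference arm versus the comparator.
#'
#' @param config An `analysis_config`; default the packaged configuration.
#' @return A `base_case` list: `reference` and `comparator` `ce_result`s
#'   (named by arm), `incremental` ([compute_icer()] of reference vs
#'   comparator), `traces`, `settings`.
#' @examples
#' \donttest{
#' bc <- run_base_case(default_config())
#' bc$incremental
#' }
#' @export
run_base_case <- function(config = default_config()) {
  stopifnot(inherits(config, "analysis_config"))
  settings <- config_settings(config)
  curves <- config_curves(config)
  ref <- config$metadata$reference_arm
  cmp <- config$metadata$comparator_arm
  tr_ref <- build_trace(curves$reference$pfs, curves$reference$os, settings)
  tr_cmp <- build_trace(curves$comparator$pfs, curves$comparator$os, settings)
  res_ref <- evaluate_strategy(tr_ref, config_strategy(config, ref), settings)
  res_cmp <- evaluate_strategy(tr_cmp, config_strategy(config, cmp), settings)
  structure(list(reference = res_ref, comparator = res_cmp,
                 incremental = compute_icer(res_ref, res_cmp),
                 traces = stats::setNames(list(tr_ref, tr_cmp),
                                          c(ref, cmp)),
                 settings = settings),
            class = "base_case")
}

#' @export
print.base_case <- function(x, ...) {
  print(x$reference)
  print(x$comparator)
  print(x$incremental)
  invisible(x)
}
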