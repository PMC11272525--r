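#' Partitioned survival model settings
#'
#' Global settings of the three-state model. The default time structure is
#' 173 cycles of 21 days (about 10 years), outcomes and costs discounted at
#' 5 percent per year, with willingness-to-pay thresholds of 1x and 3x
#' China's 2022 GDP per capita in US dollars.
#'
#' @param cycle_length_days Cycle length in days (> 0); default 21 (one
#'   chemotherapy administration interval).
#' @param n_cycles Number of model cycles (>= 1); default 173.
#' @param annual_discount Annual discount rate in \[0, 1); default 0.05.
#' @param wtp_low,wtp_high Willingness-to-pay thresholds in USD per QALY;
#'   defaults 12734 and 38202.
#' @param cycle_eval `"midpoint"` (state membership evaluated at cycle
#'   midpoints, i.e. half-cycle correction; default) or `"start"`.
#' @param ae_cost_timing `"per_cycle"` (adverse-event management costs
#'   accrue as an incidence-weighted amount every cycle over progression-free
#'   occupancy; default) or `"one_off"` (a single incidence-weighted cost at
#'   model entry).
#' @param ae_disutility_timing `"induction"` (incidence-weighted
#'   adverse-event disutility decrements the progression-free utility
#'   during induction cycles only, the window in which the cytotoxic
#'   components are given; default) or `"per_cycle"` (decrement applied
#'   throughout PFS occupancy). The induction default keeps the effective
#'   progression-free utility above the progressed-disease utility in both
#'   arms; a lifetime decrement can invert that ordering when the AE
#'   burden is heavy.
#' @param hr_direction `"divide"` or `"multiply"`, passed to
#'   [adjust_curve_by_hr()] when comparator curves are derived.
#' @param days_per_month Calendar conversion; default 365.25 / 12.
#' @return A `model_settings` list (with derived fields `cycle_months` and
#'   `cycle_years`).
#' @export
model_settings <- function(cycle_length_days = 21,
                           n_cycles = 173L,
                           annual_discount = 0.05,
                           wtp_low = 12734,
                           wtp_high = 38202,
                           cycle_eval = c("midpoint", "start"),
                           ae_cost_timing = c("per_cycle", "one_off"),
                           ae_disutility_timing = c("induction", "per_cycle"),
                           hr_direction = c("divide", "multiply"),
                           days_per_month = 365.25 / 12) {
  if (cycle_length_days <= 0) {
    stop("model_settings: `cycle_length_days` must be > 0", call. = FALSE)
  }
  if (n_cycles < 1 || n_cycles != round(n_cycles)) {
    stop("model_settings: `n_cycles` must be a positive integer",
         call. = FALSE)
  }
  if (annual_discount < 0 || annual_discount >= 1) {
    stop("model_settings: `annual_discount` must lie in [0, 1)",
         call. = FALSE)
  }
  if (wtp_low > wtp_high) {
    stop("model_settings: `wtp_low` must be <= `wtp_high`", call. = FALSE)
  }
  cycle_months <- cycle_length_days / days_per_month
  structure(list(cycle_length_days = cycle_length_days,
                 n_cycles = as.integer(n_cycles),
                 annual_discount = annual_discount,
                 wtp_low = wtp_low, wtp_high = wtp_high,
                 cycle_eval = match.arg(cycle_eval),
                 ae_cost_timing = match.arg(ae_cost_timing),
                 ae_disutility_timing = match.arg(ae_disutility_timing),
                 hr_direction = match.arg(hr_direction),
                 days_per_month = days_per_month,
                 cycle_months = cycle_months,
                 cycle_years = cycle_months / 12),
            class = "model_settings")
}

#' Treatment strategy specification
#'
#' One arm's drug schedule, adverse-event profile and utility inputs.
#' Induction components are given every cycle for `n_induction_cycles`
#' cycles; afterwards progression-free patients receive the maintenance
#' component until the PD-1 inhibitor cap (months from treatment start) is
#' reached. All treatment stops on progression.
#'
#' @param name Strategy label.
#' @param induction `data.frame` with columns `drug`, `cost_per_cycle`
#'   (USD; all components administered each induction cycle).
#' @param maintenance_drug,maintenance_cost Maintenance monotherapy label
#'   and per-cycle USD cost.
#' @param maintenance_cap_months Months of PD-1 therapy allowed from
#'   treatment start (> 0); default 24.
#' @param n_induction_cycles Number of induction cycles; default 6.
#' @param adverse_events `data.frame` with columns `name`, `incidence`
#'   (probability), `cost` (USD per managed episode), `disutility`
#'   (utility decrement >= 0). May have zero rows.
#' @param utility_pfs,utility_pd State utilities in \[0, 1\].
#' @return A `strategy_spec` list.
#' @export
strategy_spec <- function(name, induction, maintenance_drug,
                          maintenance_cost, maintenance_cap_months = 24,
                          n_induction_cycles = 6L,
                          adverse_events = data.frame(name = character(),
                                                      incidence = numeric(),
                                                      cost = numeric(),
                                                      disutility = numeric()),
                          utility_pfs, utility_pd) {
  stopifnot(is.data.frame(induction),
            all(c("drug", "cost_per_cycle") %in% names(induction)),
            is.data.frame(adverse_events),
            all(c("name", "incidence", "cost", "disutility") %in%
                  names(adverse_events)))
  if (any(induction$cost_per_cycle < 0) || maintenance_cost < 0 ||
      any(adverse_events$cost < 0)) {
    stop("strategy_spec: costs must be >= 0", call. = FALSE)
  }
  if (any(adverse_events$incidence < 0 | adverse_events$incidence > 1)) {
    stop("strategy_spec: incidences must lie in [0, 1]", call. = FALSE)
  }
  if (any(adverse_events$disutility < 0)) {
    stop("strategy_spec: disutilities must be >= 0", call. = FALSE)
  }
  if (utility_pfs < 0 || utility_pfs > 1 || utility_pd < 0 || utility_pd > 1) {
    stop("strategy_spec: utilities must lie in [0, 1]", call. = FALSE)
  }
  if (maintenance_cap_months <= 0) {
    stop("strategy_spec: `maintenance_cap_months` must be > 0", call. = FALSE)
  }
  structure(list(name = name,
                 induction = induction,
                 maintenance_drug = maintenance_drug,
                 maintenance_cost = maintenance_cost,
                 maintenance_cap_months = maintenance_cap_months,
                 n_induction_cycles = as.integer(n_induction_cycles),
                 adverse_events = adverse_events,
                 utility_pfs = utility_pfs,
                 utility_pd = utility_pd),
            class = "strategy_spec")
}

#' Build the partitioned survival trace
#'
#' Partitions the cohort at each cycle's evaluation time t into the three
#' states directly from the two survival curves:
#' progression-free = min(S_pfs(t), S_os(t)) (the minimum guards against
#' curve crossing under extrapolation), dead = 1 - S_os(t), and progressed
#' disease = the remainder. The discount weight at t is
#' (1 + r)^(-t in years).
#'
#' @param pfs_curve,os_curve [weibull_curve()] objects for progression-free
#'   and overall survival (months).
#' @param settings A [model_settings()].
#' @return A `data.frame` of class `survival_trace` with columns `cycle`,
#'   `time` (months at the evaluation point), `pfs`, `pd`, `dead`,
#'   `discount`.
#' @examples
#' tr <- build_trace(weibull_curve(0.04, 1.28), weibull_curve(0.01, 1.53),
#'                   model_settings())
#' head(tr)
#' @export
build_trace <- function(pfs_curve, os_curve, settings = model_settings()) {
  stopifnot(inherits(pfs_curve, "weibull_curve"),
            inherits(os_curve, "weibull_curve"),
            inherits(settings, "model_settings"))
  i <- seq_len(settings$n_cycles)
  offset <- if (settings$cycle_eval == "midpoint") 0.5 else 1
  t <- (i - offset) * settings$cycle_months
  s_pfs <- weibull_survival(pfs_curve, t)
  s_os <- weibull_survival(os_curve, t)
  pfs <- pmin(s_pfs, s_os)
  dead <- 1 - s_os
  pd <- pmax(s_os - pfs, 0)
  structure(data.frame(cycle = i, time = t, pfs = pfs, pd = pd, dead = dead,
                       discount = (1 + settings$annual_discount)^(-t / 12)),
            class = c("survival_trace", "data.frame"))
}

#' Accrue discounted life-years and QALYs over a trace
#'
#' Each cycle contributes occupancy x cycle length (years) x discount
#' weight. Progression-free occupancy is valued at the PFS utility minus
#' the incidence-weighted adverse-event disutility burden (applied per
#' cycle or during induction only, per the settings); progressed occupancy
#' is valued at the PD utility.
#'
#' @param trace A [build_trace()] result.
#' @param strategy A [strategy_spec()].
#' @param settings A [model_settings()].
#' @return A list: `ly`, `pf_ly`, `pd_ly` (years), `qaly`, `pfs_qaly`,
#'   `pd_qaly`.
#' @export
accrue_outcomes <- function(trace, strategy, settings = model_settings()) {
  stopifnot(inherits(trace, "survival_trace"),
            inherits(strategy, "strategy_spec"),
            inherits(settings, "model_settings"))
  cyl <- settings$cycle_years
  w <- trace$discount
  pf_ly <- sum(trace$pfs * cyl * w)
  pd_ly <- sum(trace$pd * cyl * w)
  ae <- strategy$adverse_events
  dis_burden <- sum(ae$incidence * ae$disutility)
  dis <- rep(dis_burden, nrow(trace))
  if (settings$ae_disutility_timing == "induction") {
    dis[trace$cycle > strategy$n_induction_cycles] <- 0
  }
  u_pfs_eff <- pmax(strategy$utility_pfs - dis, 0)
  pfs_qaly <- sum(trace$pfs * u_pfs_eff * cyl * w)
  pd_qaly <- sum(trace$pd * strategy$utility_pd * cyl * w)
  list(ly = pf_ly + pd_ly, pf_ly = pf_ly, pd_ly = pd_ly,
       qaly = pfs_qaly + pd_qaly, pfs_qaly = pfs_qaly, pd_qaly = pd_qaly)
}

#' Accrue discounted costs over a trace
#'
#' Drug costs: the summed induction component prices accrue on
#' progression-free occupancy during induction cycles; the maintenance
#' price accrues on progression-free occupancy in later cycles whose start
#' lies before the PD-1 cap (months from treatment start). No drug cost
#' accrues on progressed occupancy (treatment stops at progression) and the
#' progressed state itself carries no cost (best supportive care).
#' Adverse-event management costs accrue as the incidence-weighted sum per
#' cycle over progression-free occupancy, or once at entry, per the
#' settings. All increments are discounted.
#'
#' @inheritParams accrue_outcomes
#' @return A list: `total_cost`, `drug_cost`, `ae_cost` (USD).
#' @export
accrue_costs <- function(trace, strategy, settings = model_settings()) {
  stopifnot(inherits(trace, "survival_trace"),
            inherits(strategy, "strategy_spec"),
            inherits(settings, "model_settings"))
  w <- trace$discount
  induction_cost <- sum(strategy$induction$cost_per_cycle)
  is_induction <- trace$cycle <= strategy$n_induction_cycles
  cycle_start <- (trace$cycle - 1) * settings$cycle_months
  in_cap <- cycle_start < strategy$maintenance_cap_months
  is_maint <- !is_induction & in_cap
  drug_cost <- sum(induction_cost * trace$pfs[is_induction] * w[is_induction]) +
    sum(strategy$maintenance_cost * trace$pfs[is_maint] * w[is_maint])
  ae <- strategy$adverse_events
  ae_burden <- sum(ae$incidence * ae$cost)
  ae_cost <- if (settings$ae_cost_timing == "per_cycle") {
    sum(ae_burden * trace$pfs * w)
  } else {
    ae_burden  # single undiscounted hit at model entry (t = 0)
  }
  list(total_cost = drug_cost + ae_cost, drug_cost = drug_cost,
       ae_cost = ae_cost)
}

#' Evaluate one strategy: trace plus all accruals
#'
#' @inheritParams accrue_outcomes
#' @return A `ce_result` list combining [accrue_outcomes()] and
#'   [accrue_costs()] with the strategy name.
#' @export
evaluate_strategy <- function(trace, strategy, settings = model_settings()) {
  out <- c(list(strategy = strategy$name),
           accrue_outcomes(trace, strategy, settings),
           accrue_costs(trace, strategy, settings))
  structure(out, class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("Strategy %s\n", x$strategy))
  cat(sprintf("  LYs   %.4f (PF %.4f + PD %.4f)\n", x$ly, x$pf_ly, x$pd_ly))
  cat(sprintf("  QALYs %.4f (PFS %.4f + PD %.4f)\n",
              x$qaly, x$pfs_qaly, x$pd_qaly))
  cat(sprintf("  Costs $%.2f (drug $%.2f + AE $%.2f)\n",
              x$total_cost, x$drug_cost, x$ae_cost))
  invisible(x)
}

#' Convert cost-effectiveness results to a data frame
#'
#' @param results A `ce_result` or list of them.
#' @return One row per strategy.
#' @export
ce_result_table <- function(results) {
  if (inherits(results, "ce_result")) results <- list(results)
  do.call(rbind, lapply(results, function(x) {
    data.frame(strategy = x$strategy, ly = x$ly, pf_ly = x$pf_ly,
               pd_ly = x$pd_ly, qaly = x$qaly, pfs_qaly = x$pfs_qaly,
               pd_qaly = x$pd_qaly, total_cost = x$total_cost,
               drug_cost = x$drug_cost, ae_cost = x$ae_cost)
  }))
}

#' Incremental cost-effectiveness of strategy `a` versus `b`
#'
#' Differences are `a` minus `b`. The ICER is reported per QALY and per
#' life-year at full precision; when `a` is cheaper and more effective it
#' is classified `"dominant"` (no meaningful ratio), `"dominated"` in the
#' reverse case, and `"icer"` otherwise. A zero QALY difference flags the
#' ICER as undefined rather than erroring.
#'
#' @param a,b `ce_result` objects.
#' @return An `incremental_result` list: `delta_cost`, `delta_qaly`,
#'   `delta_ly`, `icer_qaly`, `icer_ly`, `classification`
#'   (`"icer" | "dominant" | "dominated" | "undefined"`).
#' @export
compute_icer <- function(a, b) {
  stopifnot(inherits(a, "ce_result"), inherits(b, "ce_result"))
  dc <- a$total_cost - b$total_cost
  dq <- a$qaly - b$qaly
  dl <- a$ly - b$ly
  classification <- if (dq == 0) {
    "undefined"
  } else if (dc < 0 && dq > 0) {
    "dominant"
  } else if (dc > 0 && dq < 0) {
    "dominated"
  } else {
    "icer"
  }
  structure(list(comparison = paste(a$strategy, "vs", b$strategy),
                 delta_cost = dc, delta_qaly = dq, delta_ly = dl,
                 icer_qaly = if (dq != 0) dc / dq else NA_real_,
                 icer_ly = if (dl != 0) dc / dl else NA_real_,
                 classification = classification),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("%s: dCost $%.2f, dQALY %.4f, dLY %.4f\n",
              x$comparison, x$delta_cost, x$delta_qaly, x$delta_ly))
  if (x$classification == "icer") {
    cat(sprintf("  ICER $%.2f/QALY, $%.2f/LY\n", x$icer_qaly, x$icer_ly))
  } else {
    cat(sprintf("  %s\n", x$classification))
  }
  invisible(x)
}
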