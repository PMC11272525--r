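# Independently coded reference implementations used as oracles.
# These deliberately avoid the package's vectorised code paths: the accrual
# oracle is a plain per-cycle loop over scalars, the NMA oracle is the
# Bucher closed form.

# default config, loaded once; the RCCEP disutility row legitimately warns
base_config <- suppressWarnings(psmcea::default_config())

# single-loop accrual under the same conventions as the engine
oracle_evaluate <- function(config, arm) {
  s <- config$settings
  cm <- s$cycle_length_days / (365.25 / 12)
  surv <- function(sc, sh, t) exp(-sc * t^sh)
  pl <- config$survival$pfs$scale; pg <- config$survival$pfs$shape
  ol <- config$survival$os$scale;  og <- config$survival$os$shape
  if (identical(arm, config$metadata$comparator_arm)) {
    kp <- config$hazard_ratios$pfs$baseline
    ko <- config$hazard_ratios$os$baseline
    if (identical(s$hr_direction, "divide")) { kp <- 1 / kp; ko <- 1 / ko }
    pl <- pl * kp; ol <- ol * ko
  }
  st <- config$strategies[[arm]]
  ind_cost <- 0
  for (d in st$induction_drugs) {
    ind_cost <- ind_cost + config$drug_costs[[d]]$baseline
  }
  m_cost <- config$drug_costs[[st$maintenance_drug]]$baseline
  ae_c <- 0; ae_d <- 0
  for (ae in config$adverse_events) {
    inc <- ae$incidence[[arm]]$baseline
    ae_c <- ae_c + inc * ae$cost$baseline
    ae_d <- ae_d + inc * ae$disutility$baseline
  }
  u_pfs <- config$utilities$pfs$baseline
  u_pd <- config$utilities$pd$baseline
  acc <- c(pf_ly = 0, pd_ly = 0, pfs_qaly = 0, pd_qaly = 0,
           drug_cost = 0, ae_cost = 0)
  for (i in seq_len(s$n_cycles)) {
    t <- (i - if (identical(s$cycle_eval, "midpoint")) 0.5 else 1) * cm
    sp <- surv(pl, pg, t); so <- surv(ol, og, t)
    pfs <- min(sp, so); pd <- max(so - pfs, 0)
    w <- (1 + s$annual_discount)^(-t / 12)
    cyl <- cm / 12
    acc["pf_ly"] <- acc["pf_ly"] + pfs * cyl * w
    acc["pd_ly"] <- acc["pd_ly"] + pd * cyl * w
    dis <- if (identical(s$ae_disutility_timing, "per_cycle") ||
               i <= st$n_induction_cycles) ae_d else 0
    acc["pfs_qaly"] <- acc["pfs_qaly"] + pfs * max(u_pfs - dis, 0) * cyl * w
    acc["pd_qaly"] <- acc["pd_qaly"] + pd * u_pd * cyl * w
    if (i <= st$n_induction_cycles) {
      acc["drug_cost"] <- acc["drug_cost"] + ind_cost * pfs * w
    } else if ((i - 1) * cm < st$maintenance_cap_months) {
      acc["drug_cost"] <- acc["drug_cost"] + m_cost * pfs * w
    }
    if (identical(s$ae_cost_timing, "per_cycle")) {
      acc["ae_cost"] <- acc["ae_cost"] + ae_c * pfs * w
    }
  }
  if (identical(s$ae_cost_timing, "one_off")) acc["ae_cost"] <- ae_c
  c(acc,
    ly = unname(acc["pf_ly"] + acc["pd_ly"]),
    qaly = unname(acc["pfs_qaly"] + acc["pd_qaly"]),
    total_cost = unname(acc["drug_cost"] + acc["ae_cost"]))
}

# Bucher chain: log effects and variances add along a path
oracle_bucher_chain <- function(loghrs, ses) {
  c(loghr = sum(loghrs), se = sqrt(sum(ses^2)))
}

# three-trial path network CTC - TC - GP - SGP
make_chain_edges <- function(loghrs = c(-0.3, 0.1, 0.1),
                             ses = c(0.1, 0.1, 0.1)) {
  data.frame(trial = c("T1", "T2", "T3"),
             arm_a = c("CTC", "TC", "GP"),
             arm_b = c("TC", "GP", "SGP"),
             true_loghr = loghrs, se = ses)
}

# a hand-built trace with occupancy pinned to given vectors (discount = 1)
pinned_trace <- function(pfs, pd = rep(0, length(pfs)), cycle_years) {
  n <- length(pfs)
  structure(data.frame(cycle = seq_len(n),
                       time = (seq_len(n) - 0.5) * cycle_years * 12,
                       pfs = pfs, pd = pd, dead = 1 - pfs - pd,
                       discount = rep(1, n)),
            class = c("survival_trace", "data.frame"))
}
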