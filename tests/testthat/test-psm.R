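monthly <- model_settings(cycle_length_days = 365.25 / 12, n_cycles = 120,
                          cycle_eval = "start")

mk_res <- function(cost, qaly, ly, name = "X") {
  structure(list(strategy = name, ly = ly, qaly = qaly, total_cost = cost),
            class = "ce_result")
}

no_ae <- data.frame(name = character(), incidence = numeric(),
                    cost = numeric(), disutility = numeric())

test_that("trace starts at full progression-free occupancy", {
  tr <- build_trace(weibull_curve(0.04, 1.28), weibull_curve(0.01, 1.53),
                    monthly)
  expect_equal(tr$time[1], 0)
  expect_equal(unlist(tr[1, c("pfs", "pd", "dead")]),
               c(pfs = 1, pd = 0, dead = 0))
  expect_equal(tr$discount[1], 1)
})

test_that("identical PFS and OS curves leave nobody in progressed disease", {
  cv <- weibull_curve(0.04, 1.28)
  tr <- build_trace(cv, cv, monthly)
  expect_true(all(tr$pd == 0))
  expect_equal(tr$pfs + tr$dead, rep(1, nrow(tr)), tolerance = 1e-14)
})

test_that("progressed occupancy is the gap between the two curves", {
  pfs <- weibull_curve(0.04, 1.28); os <- weibull_curve(0.01, 1.53)
  tr <- build_trace(pfs, os, monthly)
  # cycle 13 of the start-convention monthly grid falls exactly at t = 12
  row <- tr[tr$cycle == 13, ]
  expect_equal(row$time, 12)
  expect_equal(row$pd, weibull_survival(os, 12) - weibull_survival(pfs, 12),
               tolerance = 1e-12)
  # conservation and monotone structure
  expect_equal(tr$pfs + tr$pd + tr$dead, rep(1, nrow(tr)), tolerance = 1e-12)
  expect_true(all(diff(tr$pfs) <= 0))
  expect_true(all(diff(tr$pfs + tr$pd) <= 0))
  expect_true(all(diff(tr$discount) <= 0) && all(tr$discount > 0))
})

test_that("undiscounted unit-utility QALYs equal life-years exactly", {
  st <- strategy_spec("plain",
                      induction = data.frame(drug = "d", cost_per_cycle = 0),
                      maintenance_drug = "d", maintenance_cost = 0,
                      adverse_events = no_ae, utility_pfs = 1, utility_pd = 1)
  s0 <- model_settings(annual_discount = 0, n_cycles = 150)
  tr <- build_trace(weibull_curve(0.04, 1.28), weibull_curve(0.01, 1.53), s0)
  out <- accrue_outcomes(tr, st, s0)
  expect_equal(out$qaly, out$ly, tolerance = 1e-14)
  expect_equal(out$pf_ly + out$pd_ly, out$ly, tolerance = 1e-14)
})

test_that("a rectangular year of survival accrues by the rectangle rule", {
  weekly <- model_settings(cycle_length_days = 365.25 / 52, n_cycles = 60,
                           annual_discount = 0)
  st <- strategy_spec("rect",
                      induction = data.frame(drug = "d", cost_per_cycle = 0),
                      maintenance_drug = "d", maintenance_cost = 0,
                      adverse_events = no_ae,
                      utility_pfs = 0.75, utility_pd = 0.59)
  tr <- pinned_trace(pfs = c(rep(1, 52), rep(0, 8)),
                     cycle_years = weekly$cycle_years)
  out <- accrue_outcomes(tr, st, weekly)
  expect_equal(out$ly, 1.0, tolerance = 1e-12)
  expect_equal(out$qaly, 0.75, tolerance = 1e-12)
})

test_that("induction pricing follows the per-cycle component sum", {
  cfg <- base_config
  prices <- vapply(c("camrelizumab", "paclitaxel", "carboplatin"),
                   function(d) config_get(cfg, paste0("drug_costs/", d,
                                                      "/baseline")),
                   numeric(1))
  st <- strategy_spec("CTC-induction",
                      induction = data.frame(drug = names(prices),
                                             cost_per_cycle = unname(prices)),
                      maintenance_drug = "camrelizumab",
                      maintenance_cost = prices[["camrelizumab"]],
                      adverse_events = no_ae,
                      utility_pfs = 0.75, utility_pd = 0.59)
  s6 <- model_settings(annual_discount = 0, n_cycles = 6)
  tr <- pinned_trace(pfs = rep(1, 6), cycle_years = s6$cycle_years)
  costs <- accrue_costs(tr, st, s6)
  expect_equal(costs$drug_cost, 6 * sum(prices), tolerance = 1e-9)
  expect_equal(costs$drug_cost, 8189.82, tolerance = 1e-9)
  expect_equal(costs$ae_cost, 0)
})

test_that("zero prices accrue zero cost", {
  st <- strategy_spec("free",
                      induction = data.frame(drug = "d", cost_per_cycle = 0),
                      maintenance_drug = "d", maintenance_cost = 0,
                      adverse_events = no_ae, utility_pfs = 1, utility_pd = 1)
  tr <- build_trace(weibull_curve(0.04, 1.28), weibull_curve(0.01, 1.53),
                    monthly)
  expect_equal(accrue_costs(tr, st, monthly)$total_cost, 0)
})

test_that("maintenance stops at the PD-1 cap and on progression", {
  # flat survival, no discounting: drug cost counts cycles directly
  s0 <- model_settings(annual_discount = 0, n_cycles = 60)
  st <- strategy_spec("cap",
                      induction = data.frame(drug = "pd1", cost_per_cycle = 100),
                      maintenance_drug = "pd1", maintenance_cost = 100,
                      maintenance_cap_months = 24,
                      adverse_events = no_ae, utility_pfs = 1, utility_pd = 1)
  tr <- pinned_trace(pfs = rep(1, 60), cycle_years = s0$cycle_years)
  n_on_treatment <- sum((seq_len(60) - 1) * s0$cycle_months < 24)
  expect_equal(accrue_costs(tr, st, s0)$drug_cost, 100 * n_on_treatment)
  # occupancy weighting: halving PFS halves the bill
  tr_half <- pinned_trace(pfs = rep(0.5, 60), pd = rep(0.25, 60),
                          cycle_years = s0$cycle_years)
  expect_equal(accrue_costs(tr_half, st, s0)$drug_cost,
               50 * n_on_treatment)
})

test_that("one-off adverse-event costing charges the burden once", {
  s1 <- model_settings(annual_discount = 0, n_cycles = 40,
                       ae_cost_timing = "one_off")
  ae <- data.frame(name = "x", incidence = 0.4, cost = 1000, disutility = 0.1)
  st <- strategy_spec("oneoff",
                      induction = data.frame(drug = "d", cost_per_cycle = 0),
                      maintenance_drug = "d", maintenance_cost = 0,
                      adverse_events = ae, utility_pfs = 0.75,
                      utility_pd = 0.59)
  tr <- pinned_trace(pfs = rep(1, 40), cycle_years = s1$cycle_years)
  expect_equal(accrue_costs(tr, st, s1)$ae_cost, 400)
  s2 <- model_settings(annual_discount = 0, n_cycles = 40,
                       ae_cost_timing = "per_cycle")
  expect_equal(accrue_costs(tr, st, s2)$ae_cost, 400 * 40)
})

test_that("per-cycle disutility mode decrements PFS utility for life", {
  ae <- data.frame(name = "x", incidence = 0.5, cost = 0, disutility = 0.2)
  st <- strategy_spec("dis",
                      induction = data.frame(drug = "d", cost_per_cycle = 0),
                      maintenance_drug = "d", maintenance_cost = 0,
                      n_induction_cycles = 6,
                      adverse_events = ae, utility_pfs = 0.75,
                      utility_pd = 0.59)
  s0 <- model_settings(annual_discount = 0, n_cycles = 10,
                       ae_disutility_timing = "per_cycle")
  s1 <- model_settings(annual_discount = 0, n_cycles = 10,
                       ae_disutility_timing = "induction")
  tr <- pinned_trace(pfs = rep(1, 10), cycle_years = s0$cycle_years)
  cyl <- s0$cycle_years
  expect_equal(accrue_outcomes(tr, st, s0)$qaly, 10 * (0.75 - 0.1) * cyl,
               tolerance = 1e-12)
  expect_equal(accrue_outcomes(tr, st, s1)$qaly,
               (6 * (0.75 - 0.1) + 4 * 0.75) * cyl, tolerance = 1e-12)
})

test_that("totals are non-decreasing in the model horizon", {
  cfg <- base_config
  totals <- vapply(c(60, 120, 173), function(n) {
    bc <- run_base_case(config_set(cfg, "settings/n_cycles", n))
    c(bc$reference$ly, bc$reference$qaly, bc$reference$total_cost)
  }, numeric(3))
  expect_true(all(diff(t(totals)) >= 0))
})

test_that("QALYs never exceed life-years when utilities are below one", {
  cfg <- base_config
  for (u in list(c(0.75, 0.59), c(1, 1), c(0.3, 0.9))) {
    c2 <- config_set(cfg, "utilities/pfs/baseline", u[1])
    c2 <- config_set(c2, "utilities/pd/baseline", u[2])
    bc <- run_base_case(c2)
    expect_lte(bc$reference$qaly, bc$reference$ly + 1e-12)
    expect_lte(bc$comparator$qaly, bc$comparator$ly + 1e-12)
  }
})

test_that("incremental classification follows the dominance rules", {
  expect_equal(compute_icer(mk_res(200, 2, 2), mk_res(100, 1, 1))$icer_qaly,
               100)
  dom <- compute_icer(mk_res(99, 1.1, 1.1), mk_res(100, 1, 1))
  expect_identical(dom$classification, "dominant")
  rev <- compute_icer(mk_res(101, 0.9, 0.9), mk_res(100, 1, 1))
  expect_identical(rev$classification, "dominated")
  und <- compute_icer(mk_res(101, 1, 1), mk_res(100, 1, 1))
  expect_identical(und$classification, "undefined")
  expect_true(is.na(und$icer_qaly))
})
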