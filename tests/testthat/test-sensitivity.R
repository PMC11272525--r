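test_that("method of moments reproduces hand-computed distribution parameters", {
  mm <- method_of_moments(list(baseline = 0.5, low = NA, high = NA,
                               family = "beta", se = 0.1))
  expect_equal(mm$alpha, 12)
  expect_equal(mm$beta, 12)
  # SE derived from a printed range: (high - low) / (2 * 1.959964)
  mm2 <- method_of_moments(list(baseline = 0.75, low = 0.6, high = 0.94,
                                family = "normal"))
  expect_equal(mm2$sd, (0.94 - 0.6) / (2 * qnorm(0.975)), tolerance = 1e-9)
  gm <- method_of_moments(list(baseline = 382.86, low = 306.29,
                               high = 459.43, family = "gamma"))
  expect_equal(gm$shape / gm$rate, 382.86, tolerance = 1e-9)
  expect_equal(sqrt(gm$shape) / gm$rate, gm$se, tolerance = 1e-9)
})

test_that("degenerate moments collapse to a point mass in every family", {
  for (fam in c("beta", "gamma", "normal")) {
    mm <- method_of_moments(list(baseline = 0.6, low = 0.6, high = 0.6,
                                 family = fam))
    expect_identical(mm$family, "fixed")
    expect_equal(sample_parameter(mm, 5), rep(0.6, 5))
  }
})

test_that("gamma sampling matches its target mean in the long run", {
  mm <- method_of_moments(list(baseline = 382.86, low = NA, high = NA,
                               family = "gamma", se = 39.07))
  set.seed(123)
  expect_equal(mean(sample_parameter(mm, 1e5)), 382.86, tolerance = 0.01)
})

test_that("infeasible moment combinations are refused", {
  expect_error(method_of_moments(list(baseline = 1.2, low = 1, high = 1.4,
                                      family = "beta")),
               "mean in \\(0, 1\\)")
  expect_error(method_of_moments(list(baseline = 0.5, low = NA, high = NA,
                                      family = "beta", se = 0.6)),
               "infeasible")
  expect_error(method_of_moments(list(baseline = -3, low = -4, high = -2,
                                      family = "gamma")),
               "mean > 0")
})

test_that("tornado bars respond only to parameters that matter", {
  cfg <- base_config
  params <- enumerate_parameters(cfg)
  # an event absent from one arm still has a cost parameter; silence it in
  # the other arm too and the cost bar must vanish
  cfg0 <- config_set(cfg, "adverse_events/rccep/incidence/CTC/baseline", 0)
  noop <- params[params$name == "cost_ae_rccep", ]
  tor0 <- one_way_dsa(cfg0, noop)
  base_icer <- attr(tor0, "icer_base")
  expect_equal(tor0$icer_low, base_icer, tolerance = 1e-12)
  expect_equal(tor0$icer_high, base_icer, tolerance = 1e-12)
  expect_equal(tor0$width, 0)
  # a frozen parameter (low = high = baseline) has zero width
  frozen <- params[params$name == "utility_pd", ]
  frozen$low <- frozen$high <- frozen$baseline
  expect_equal(one_way_dsa(cfg, frozen)$width, 0, tolerance = 1e-12)
})

test_that("tornado output is invariant to parameter evaluation order", {
  cfg <- base_config
  params <- enumerate_parameters(cfg)[1:8, ]
  t1 <- one_way_dsa(cfg, params)
  set.seed(1)
  t2 <- one_way_dsa(cfg, params[sample(nrow(params)), ])
  expect_equal(t1, t2, ignore_attr = TRUE)
  expect_true(all(diff(t1$width) <= 0))
})

test_that("an all-fixed PSA reproduces the base case exactly", {
  cfg <- base_config
  params <- enumerate_parameters(cfg)
  params$family <- "fixed"
  psa <- run_psa(cfg, n_draws = 5, seed = 1, parameters = params)
  bc <- run_base_case(cfg)
  expect_equal(unique(psa$samples$delta_cost), bc$incremental$delta_cost)
  expect_equal(unique(psa$samples$delta_qaly), bc$incremental$delta_qaly)
  expect_equal(psa$summary$icer, bc$incremental$icer_qaly)
})

test_that("PSA draws are reproducible and seed-sensitive", {
  cfg <- base_config
  a <- run_psa(cfg, n_draws = 20, seed = 5)
  b <- run_psa(cfg, n_draws = 20, seed = 5)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples,
                         run_psa(cfg, n_draws = 20, seed = 6)$samples))
})

test_that("PSA summaries are stable across seeds", {
  cfg <- base_config
  n <- 400
  runs <- lapply(1:6, function(s) run_psa(cfg, n_draws = n, seed = s))
  dq <- vapply(runs, function(r) r$summary$mean_delta_qaly, numeric(1))
  sd_dq <- vapply(runs, function(r) sd(r$samples$delta_qaly), numeric(1))
  mc_se <- mean(sd_dq) / sqrt(n)
  expect_true(all(abs(dq - mean(dq)) < 3 * mc_se * sqrt(2)))
})

test_that("hazard-ratio sampling honours the configured scale", {
  cfg <- base_config
  params <- enumerate_parameters(cfg)
  hr_rows <- params[params$role == "hr", ]
  psa <- run_psa(cfg, n_draws = 50, seed = 2, parameters = hr_rows)
  expect_true(all(is.finite(psa$samples$delta_qaly)))
  cfg_nat <- config_set(cfg, "settings/hr_sampling", "natural")
  psa_nat <- run_psa(cfg_nat, n_draws = 50, seed = 2, parameters = hr_rows)
  expect_false(identical(psa$samples, psa_nat$samples))
})

test_that("acceptability curves follow the net-monetary-benefit rule", {
  samples <- data.frame(draw = 1:4,
                        delta_cost = c(-10, 50, 100, 200),
                        delta_qaly = c(0.01, 0.02, 0.01, -0.01))
  cc <- ceac(samples, wtp_grid = c(0, 10000))
  # at zero willingness to pay only cost-saving draws count
  expect_equal(cc$p_reference[1], mean(samples$delta_cost < 0))
  expect_equal(cc$p_reference + cc$p_comparator, rep(1, 2))
  # identical draws give a step function at dCost/dQALY
  one <- data.frame(draw = 1:3, delta_cost = rep(100, 3),
                    delta_qaly = rep(0.01, 3))
  step <- ceac(one, wtp_grid = c(9999, 10000, 10001))
  expect_equal(step$p_reference, c(0, 0, 1))
  expect_error(ceac(one[0, ]), "non-empty")
  expect_error(ceac(one, numeric(0)), "non-empty")
})
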