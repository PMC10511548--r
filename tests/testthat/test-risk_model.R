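# Distributing the course-level FN risk over cycles and applying
# history/prophylaxis multipliers.

test_that("cycle-1 calibration solves the course-level identity", {
  # single cycle: the course risk is the cycle risk
  expect_equal(calibrate_cycle1_risk(0.3, 0.5, 1), 0.3)

  resid <- function(p1, P, rr, n) 1 - (1 - p1) * (1 - rr * p1)^(n - 1) - P
  p1_bc <- calibrate_cycle1_risk(0.158, 0.21, 6)
  expect_lt(abs(resid(p1_bc, 0.158, 0.21, 6)), 1e-10)
  # p1 must exceed the naive equal-hazard split P / (1 + (n-1) rr)
  expect_gt(p1_bc, 0.158 / (1 + 5 * 0.21))
  # monotone in the course-level risk: NSCLC (0.180) above BC (0.158)
  p1_nsclc <- calibrate_cycle1_risk(0.180, 0.21, 6)
  expect_gt(p1_nsclc, p1_bc)

  expect_error(calibrate_cycle1_risk(1, 0.21, 6), "calibration error")
})

test_that("calibration round-trips and is monotone on a parameter grid", {
  for (P in c(0.05, 0.158, 0.18, 0.4, 0.8))
    for (rr in c(0.1, 0.21, 0.9, 2))
      for (n in c(2, 4, 6, 10)) {
        p1 <- calibrate_cycle1_risk(P, rr, n)
        recomposed <- 1 - (1 - p1) * (1 - min(1, rr * p1))^(n - 1)
        expect_lt(abs(recomposed - P), 1e-10)
      }
  p_grid <- seq(0.02, 0.9, by = 0.02)
  roots <- vapply(p_grid, calibrate_cycle1_risk, numeric(1),
                  rr_later = 0.21, n_cycles = 6)
  expect_true(all(diff(roots) > 0))
})

test_that("per-cycle probabilities compose history and prophylaxis effects", {
  cl <- fx("austria_bc_filgrastim")$clinical
  tab <- cycle_risk_table(cl, 6)
  p1 <- tab$p_cycle1

  # PP reduces cycle-1 risk by the agent relative risk; SP does not
  expect_equal(per_cycle_fn_prob(1, FALSE, "PP", 0.42, tab), 0.42 * p1)
  expect_equal(per_cycle_fn_prob(1, FALSE, "SP", 0.42, tab), p1)
  # SP with history: agent effect on top of the later-cycle and history RRs
  expect_equal(per_cycle_fn_prob(3, TRUE, "SP", 0.25, tab),
               min(1, 0.25 * min(1, cl$rr_history * min(1, cl$rr_later_cycles * p1))))
  # no-prophylaxis arm never gets the agent effect
  expect_equal(per_cycle_fn_prob(4, TRUE, "none", 0.25, tab),
               tab$p_later_hist)
  expect_error(per_cycle_fn_prob(7, FALSE, "PP", 0.42, tab))
})

test_that("low-RDI probabilities match the published values and ordering", {
  expect_equal(rdi_distribution(FALSE, fx("austria_bc_filgrastim")$clinical),
               0.309)
  expect_equal(rdi_distribution(TRUE, fx("france_nhl_filgrastim")$clinical),
               0.706)
  for (id in all_fixture_ids()) {
    cl <- fx(id)$clinical
    expect_gte(rdi_distribution(TRUE, cl), rdi_distribution(FALSE, cl))
  }
})

test_that("risk-table probabilities stay in [0,1] under PSA draws", {
  cfg <- fx("france_nhl_filgrastim")
  params <- uncertain_parameters(cfg)
  set.seed(11)
  for (i in 1:50) {
    cfg2 <- cfg
    for (p in params)
      cfg2 <- scenario_set(cfg2, p$name, draw_parameter(p, 1))
    if (cfg2$clinical$rr_gcsf >= 1)
      cfg2$clinical$rr_gcsf <- 1 - 1e-9
    tab <- cycle_risk_table(cfg2$clinical, 6)
    vals <- c(tab$p_cycle1, tab$p_later_no_hist, tab$p_later_hist,
              vapply(1:6, function(k)
                per_cycle_fn_prob(k, k > 1, "SP", cfg2$clinical$rr_gcsf, tab),
                numeric(1)))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("primary prophylaxis yields fewer FN events on every fixture", {
  for (id in all_fixture_ids()) {
    cfg <- fx(id)
    pp <- run_strategy(cfg, "PP")
    sp <- run_strategy(cfg, "SP")
    expect_lt(pp$fn_events, sp$fn_events, label = id)
    expect_lt(pp$fn_deaths, sp$fn_deaths, label = id)
  }
})
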