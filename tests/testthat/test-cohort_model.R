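# Cohort engine: mortality conversion, chemo and post-chemo phases,
# discounting, and the microsimulation oracle.

test_that("5-year to annual mortality conversion round-trips", {
  expect_equal(annual_prob_from_5yr_death(0, 5), 0)
  for (p5 in c(0.05, 0.2786, 0.5, 0.9)) {
    p1 <- annual_prob_from_5yr_death(p5, 5)
    expect_lt(abs((1 - (1 - p1)^5) - p5), 1e-12)
  }
  # NHL: annual 0.0652 must be consistent with its implied 5-year value
  p5 <- 1 - (1 - 0.0652)^5
  expect_lt(abs(annual_prob_from_5yr_death(p5, 5) - 0.0652), 1e-12)
  expect_error(annual_prob_from_5yr_death(1, 5), "infinite rate")
})

test_that("null FN risk or null fatality gives no deaths during chemo", {
  cfg <- toy_scenario(baseline_fn_risk = 1e-9)
  ch <- run_chemo_phase(cfg, "PP")
  expect_lt(ch$fn_events, 1e-8)
  expect_lt(ch$occ[["dead"]], 1e-9)

  cfg2 <- toy_scenario(fn_case_fatality = 0)
  ch2 <- run_chemo_phase(cfg2, "SP")
  expect_equal(ch2$occ[["dead"]], 0)
  expect_gt(ch2$fn_events, 0)
})

test_that("an agent with no effect makes PP and SP differ only in drug cost", {
  cfg <- toy_scenario(rr_gcsf = 1 - 1e-12)
  pp <- run_strategy(cfg, "PP")
  sp <- run_strategy(cfg, "SP")
  expect_equal(pp$fn_events, sp$fn_events, tolerance = 1e-9)
  expect_equal(pp$fn_deaths, sp$fn_deaths, tolerance = 1e-9)
  expect_equal(pp$ly, sp$ly, tolerance = 1e-9)
  drug_delta <- (pp$disc_drug_cycles - sp$disc_drug_cycles) *
    gcsf_cost_per_cycle(cfg)
  expect_equal(pp$cost - sp$cost, drug_delta, tolerance = 1e-9)
})

test_that("occupancy is conserved to 1e-12 through every chemo cycle", {
  for (id in c("austria_bc_filgrastim", "germany_nhl_pegfilgrastim")) {
    for (strat in c("PP", "SP", "none")) {
      ch <- run_chemo_phase(fx(id), strat, trace = TRUE)
      expect_lt(abs(sum(ch$occ) - 1), 1e-12)
      sums <- rowSums(ch$trace[, c("no_hist", "hist", "dead")])
      expect_true(all(abs(sums - 1) < 1e-12))
    }
  }
})

test_that("with zero risks and costs, LY is the background life expectancy", {
  cfg <- toy_scenario(baseline_fn_risk = 1e-12, cancer_annual_mortality = 0,
                      gcsf_cost = 0, fn_cost = 0, discount = 0,
                      entry_age = 60, sex_mix = 1)
  out <- run_strategy(cfg, "SP")
  expect_equal(out$cost, 0)
  lt <- generate_life_table(cfg$life_table)
  chemo_yrs <- 6 * 21 / 365.25
  expect_lt(abs(out$ly - (chemo_yrs + life_expectancy(lt, 60, "female"))),
            1e-9)
})

test_that("flat-hazard post-chemo survival matches the closed-form annuity", {
  q <- 0.04; d <- 0.03
  cfg <- toy_scenario(baseline_fn_risk = 1e-12, cancer_annual_mortality = 0,
                      discount = d, entry_age = 30, sex_mix = 1)
  # push the terminal age far enough out that truncation is below 1e-12
  lt <- flat_life_table(q, terminal_age = 530)
  chemo <- run_chemo_phase(cfg, "SP")
  post <- run_post_chemo_phase(cfg, chemo, lt)
  k <- seq_len(lt$terminal_age - 30 + 1)
  annuity <- sum((1 - q)^k / (1 + d)^(chemo$duration_years + k - 0.5))
  expect_lt(abs(post$ly - annuity), 1e-9)
})

test_that("a unit low-RDI hazard ratio erases the RDI split", {
  cfg <- toy_scenario(hr_low_rdi = 1)
  out1 <- run_strategy(cfg, "PP")
  cfg2 <- cfg
  cfg2$clinical$p_low_rdi_no_fn <- 0.9
  cfg2$clinical$p_low_rdi_fn <- 0.95
  out2 <- run_strategy(cfg2, "PP")
  expect_equal(out1$ly, out2$ly, tolerance = 1e-12)
  expect_equal(out1$qaly, out2$qaly, tolerance = 1e-12)
  # and a real hazard ratio makes the low-RDI stratum live shorter
  cfg3 <- fx("austria_nhl_filgrastim")
  lt <- generate_life_table(cfg3$life_table)
  q_low <- fncea:::.post_chemo_q(cfg3, lt, "female", TRUE)
  q_high <- fncea:::.post_chemo_q(cfg3, lt, "female", FALSE)
  expect_true(all(q_low >= q_high))
  expect_gt(sum(cumprod(1 - q_high)), sum(cumprod(1 - q_low)))
})

test_that("after the 20-year cure horizon only background mortality applies", {
  cfg <- fx("france_bc_filgrastim")
  lt <- generate_life_table(cfg$life_table)
  q <- fncea:::.post_chemo_q(cfg, lt, "female", TRUE)
  entry <- floor(cfg$cohort$entry_age)
  ages <- entry + seq_along(q) - 1
  bg <- lt_qx(lt, ages, "female")
  expect_equal(q[21:length(q)], bg[21:length(q)])
  expect_true(all(q[1:20] > bg[1:20]))
})

test_that("discounting: zero rate is undiscounted, higher rates shrink all", {
  cfg0 <- toy_scenario(discount = 0)
  cfg3 <- toy_scenario(discount = 0.03)
  cfg5 <- toy_scenario(discount = 0.05)
  o0 <- run_strategy(cfg0, "PP")
  o3 <- run_strategy(cfg3, "PP")
  o5 <- run_strategy(cfg5, "PP")
  for (m in c("cost", "ly", "qaly")) {
    expect_gt(o0[[m]], o3[[m]])
    expect_gt(o3[[m]], o5[[m]])
  }
  # undiscounted life years: chemo time plus expected post-chemo years
  expect_equal(o0$fn_events, o3$fn_events)  # events are not discounted
})

test_that("QALY never exceeds LY, in base cases and under PSA draws", {
  for (id in all_fixture_ids()) {
    out <- run_strategy(fx(id), "PP")
    expect_lte(out$qaly, out$ly)
  }
  p <- psa(fx("austria_nhl_filgrastim"), n = 50, seed = 9)
  expect_true(all(p$draws$qaly_pp <= p$draws$ly_pp + 1e-12))
  expect_true(all(p$draws$qaly_sp <= p$draws$ly_sp + 1e-12))
})

test_that("doubling the FN hospitalisation cost hits SP harder than PP", {
  for (id in all_fixture_ids()) {
    cfg <- fx(id)
    cfg2 <- scenario_set(cfg, "fn_hospitalisation_cost",
                         2 * cfg$costs$fn_hospitalisation_cost)
    d_pp <- run_strategy(cfg2, "PP")$cost - run_strategy(cfg, "PP")$cost
    d_sp <- run_strategy(cfg2, "SP")$cost - run_strategy(cfg, "SP")$cost
    expect_gt(d_sp, d_pp, label = id)
  }
})

test_that("microsimulation is reproducible and degenerate cases are exact", {
  cfg <- toy_scenario(baseline_fn_risk = 1e-12)
  one <- simulate_individuals(cfg, "PP", n = 1, seed = 5)
  coh <- run_strategy(cfg, "PP")
  # with no FN risk the only randomness left is sex and death year
  expect_equal(one$cost["mean"], coh$cost, ignore_attr = TRUE,
               tolerance = 1e-9)
  a <- simulate_individuals(fx("austria_bc_filgrastim"), "SP", 2000, seed = 3)
  b <- simulate_individuals(fx("austria_bc_filgrastim"), "SP", 2000, seed = 3)
  expect_identical(a, b)
})

test_that("cohort engine agrees with the microsimulation oracle", {
  for (id in c("austria_bc_filgrastim", "france_nsclc_filgrastim")) {
    cfg <- fx(id)
    for (strat in c("PP", "SP")) {
      ms <- simulate_individuals(cfg, strat, n = 2e5, seed = 17)
      coh <- run_strategy(cfg, strat)
      for (m in c("cost", "ly", "qaly", "fn_events")) {
        z <- abs(ms[[m]]["mean"] - coh[[m]]) / ms[[m]]["se"]
        expect_lt(z, 3, label = paste(id, strat, m))
      }
    }
  }
})
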