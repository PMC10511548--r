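# Cost calibration against published totals; synthetic life tables.

test_that("calibration recovers known costs from a synthetic target", {
  cfg <- fx("austria_nhl_filgrastim")
  cfg$costs$gcsf_cost_per_cycle <- 212.5
  cfg$costs$fn_hospitalisation_cost <- 5125
  target <- list(pp_cost = run_strategy(cfg, "PP")$cost,
                 sp_cost = run_strategy(cfg, "SP")$cost)
  solved <- calibrate_costs(target, cfg)
  vials <- ceiling(5 * cfg$costs$patient_weight_kg / 300)
  g <- solved$drug_unit_price * vials * solved$doses_per_cycle
  expect_lt(abs(g - 212.5), 1e-6)
  expect_lt(abs(solved$fn_hospitalisation_cost - 5125), 1e-6)
})

test_that("the Austria BC filgrastim block reproduces its printed totals", {
  cfg <- fixture_scenario("Austria", "BC", "filgrastim")
  cfg$costs <- calibrate_costs(list(pp_cost = 1567, sp_cost = 980), cfg)
  expect_lt(abs(run_strategy(cfg, "PP")$cost - 1567), 0.5)
  expect_lt(abs(run_strategy(cfg, "SP")$cost - 980), 0.5)
})

test_that("equal strategy totals remain identifiable (distinct rows)", {
  cfg <- fixture_scenario("France", "NHL", "pegfilgrastim")
  solved <- calibrate_costs(list(pp_cost = 2000, sp_cost = 2000), cfg)
  cfg$costs <- solved
  expect_lt(abs(run_strategy(cfg, "PP")$cost - 2000), 1e-6)
  expect_lt(abs(run_strategy(cfg, "SP")$cost - 2000), 1e-6)
})

test_that("inconsistent targets fail loudly rather than go negative", {
  cfg <- fixture_scenario("Austria", "BC", "filgrastim")
  # SP cannot plausibly cost this much more than PP under the model
  expect_error(calibrate_costs(list(pp_cost = 100, sp_cost = 5000), cfg),
               "calibration error")
})

test_that("solved filgrastim drug costs sit in a plausible price band", {
  # scenario list price: 55.54 EUR per 300 ug vial; solved per-cycle costs
  # should be within 1x-20x of that unit price
  for (id in fixture_names("filgrastim")) {
    g <- gcsf_cost_per_cycle(fx(id))
    expect_gt(g, 55.54, label = id)
    expect_lt(g, 20 * 55.54, label = id)
  }
})

test_that("Gompertz life tables behave and match the cohort engine", {
  spec <- gompertz_spec(a = 2.5e-5, b = 0.1, female_scale = 0.5)
  lt <- generate_life_table(spec)
  # monotone in age, and vanishing as a -> 0
  expect_true(all(diff(lt$qx[, "male"]) >= 0))
  tiny <- generate_life_table(gompertz_spec(a = 1e-12, b = 0.1))
  expect_true(all(tiny$qx[1:100, "male"] < 1e-6))
  expect_equal(unname(lt_qx(lt, 200, "female")), 1)

  # life expectancy two ways: direct sum vs cohort model with no disease
  cfg <- toy_scenario(baseline_fn_risk = 1e-12, cancer_annual_mortality = 0,
                      gcsf_cost = 0, fn_cost = 0, discount = 0,
                      entry_age = 60, sex_mix = 0)
  out <- run_strategy(cfg, "none")
  direct <- life_expectancy(generate_life_table(cfg$life_table), 60, "male")
  expect_lt(abs((out$ly - out$chemo$ly) - direct), 1e-9)
})

test_that("life tables round-trip through the delimited text format", {
  lt <- generate_life_table(gompertz_spec(2.4e-5, 0.1, 0.5, 110))
  f <- tempfile(fileext = ".csv")
  write_life_table(lt, f)
  lt2 <- read_life_table(f)
  expect_equal(lt2$qx, lt$qx, tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("age,sex,qx", "0,female,2", "0,male,2"), bad)
  expect_error(read_life_table(bad), "0, 1")
})

test_that("the fixture set enumerates and matches the published narrative", {
  dir <- tempfile()
  report <- build_fixtures(dir)
  expect_equal(nrow(report), 18)
  expect_equal(length(list.files(dir, pattern = "\\.json$")), 18)
  expect_true(all(abs(report$pp_cost_residual) < 0.5))
  expect_true(all(abs(report$sp_cost_residual) < 0.5))

  # France NSCLC filgrastim base case is dominant
  cea <- run_cea(load_scenario(file.path(dir, "france_nsclc_filgrastim.json")))
  expect_identical(cea$incremental$status, "dominant")

  # German filgrastim incremental costs exceed Austria and France
  pub <- published_base_case()
  dcost <- function(ctry, cancer) {
    blk <- pub[pub$country == ctry & pub$cancer == cancer &
               pub$agent == "filgrastim", ]
    blk$cost[blk$strategy == "PP"] - blk$cost[blk$strategy == "SP"]
  }
  for (cancer in c("BC", "NSCLC", "NHL")) {
    expect_gt(dcost("Germany", cancer), dcost("Austria", cancer))
    expect_gt(dcost("Germany", cancer), dcost("France", cancer))
  }
})
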