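# Scenario configuration and distribution fitting.

test_that("bundled fixtures load with the published clinical values", {
  cfg <- fx("austria_bc_filgrastim")
  expect_s3_class(cfg, "fn_scenario")
  expect_equal(cfg$clinical$baseline_fn_risk, 0.158)
  expect_equal(cfg$clinical$rr_gcsf, 0.42)
  expect_equal(cfg$clinical$rr_history, 9.09)
  expect_equal(cfg$utilities$u_fn_hosp, 0.33)
  # pegfilgrastim fixtures carry the long-acting agent's relative risk
  expect_equal(fx("germany_nhl_pegfilgrastim")$clinical$rr_gcsf, 0.25)
  expect_equal(fx("germany_nhl_pegfilgrastim")$mortality$fn_case_fatality,
               0.058)
})

test_that("missing required keys and bound violations are rejected by name", {
  cfg <- fx("austria_bc_filgrastim")
  broken <- unclass(cfg)
  broken$clinical$baseline_fn_risk <- NULL
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(broken, f, auto_unbox = TRUE, digits = NA, na = "null")
  expect_error(load_scenario(f), "baseline_fn_risk")

  bad <- scenario_set(cfg, "u_fn_hosp", 1.5)
  expect_error(validate_scenario(bad), "u_fn_hosp")
  expect_error(validate_scenario(scenario_set(cfg, "rr_gcsf", 1.2)),
               "rr_gcsf")
  expect_error(load_scenario(tempfile()), "not found")
})

test_that("scenario serialisation round-trips for every bundled fixture", {
  for (id in all_fixture_ids()) {
    cfg <- fx(id)
    f <- tempfile(fileext = ".json")
    write_scenario(cfg, f)
    cfg2 <- load_scenario(f)
    expect_equal(cfg2, cfg, tolerance = 1e-12, label = id)
    # and serialising the reloaded scenario is idempotent
    f2 <- tempfile(fileext = ".json")
    write_scenario(cfg2, f2)
    expect_identical(readLines(f), readLines(f2), label = id)
  }
})

test_that("beta moment matching recovers the base value as analytic mean", {
  p <- fit_distribution(
    uncertain_parameter("u_fn_hosp", 0.33, 0.27, 0.40, "beta"))
  m <- p$hyper$shape1 / (p$hyper$shape1 + p$hyper$shape2)
  expect_equal(m, 0.33, tolerance = 1e-9)
  s2 <- with(p$hyper, shape1 * shape2 /
               ((shape1 + shape2)^2 * (shape1 + shape2 + 1)))
  expect_equal(sqrt(s2), (0.40 - 0.27) / 3.92, tolerance = 1e-9)
  # invalid supports are rejected
  expect_error(fit_distribution(
    uncertain_parameter("x", 1.2, 1.1, 1.3, "beta")), "0, 1")
  expect_error(fit_distribution(
    uncertain_parameter("x", 0, -0.1, 0.1, "lognormal")), "positive")
})

test_that("fixed family is degenerate at the base value", {
  p <- fit_distribution(uncertain_parameter("x", 0.4, 0.4, 0.4, "fixed"))
  expect_true(all(draw_parameter(p, 100) == 0.4))
})

test_that("lognormal fit is log-symmetric: empirical median near base", {
  # FN-history relative risk, 9.09 (6.19-13.35)
  p <- fit_distribution(
    uncertain_parameter("rr_history", 9.09, 6.19, 13.35, "lognormal"))
  set.seed(42)
  d <- draw_parameter(p, 1e5)
  expect_lt(abs(median(d) / 9.09 - 1), 0.02)
})

test_that("fitted distributions honour support, mean and tail targets", {
  # pool the unique (base, low, high, family) tuples across all fixtures
  seen <- list()
  for (id in all_fixture_ids())
    for (p in uncertain_parameters(fx(id))) {
      key <- paste(p$base, p$low, p$high, p$family)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      set.seed(7)
      d <- draw_parameter(p, 1e5)
      if (p$family == "beta") {
        expect_true(all(d >= 0 & d <= 1), label = key)
        se <- sd(d) / sqrt(length(d))
        expect_lt(abs(mean(d) - p$base), 3 * se)
      } else if (p$family == "lognormal") {
        qs <- quantile(d, c(0.025, 0.975), names = FALSE)
        expect_lt(abs(qs[1] / p$low - 1), 0.03)
        expect_lt(abs(qs[2] / p$high - 1), 0.03)
      }
    }
  expect_gt(length(seen), 10)
})
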