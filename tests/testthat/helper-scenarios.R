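# shared helpers: cached fixtures and a small controllable toy scenario

.fixture_cache <- new.env(parent = emptyenv())

fx <- function(id) {
  if (is.null(.fixture_cache[[id]]))
    .fixture_cache[[id]] <- scenario_fixture(id)
  .fixture_cache[[id]]
}

all_fixture_ids <- function() fixture_names()

# a flat-hazard life table, handy for closed-form checks
flat_life_table <- function(q, terminal_age = 110) {
  ages <- 0:terminal_age
  qx <- cbind(female = rep(q, length(ages)), male = rep(q, length(ages)))
  qx[length(ages), ] <- 1
  structure(list(ages = ages, qx = qx, terminal_age = terminal_age),
            class = "fn_life_table")
}

# minimal hand-built scenario with every knob explicit
toy_scenario <- function(baseline_fn_risk = 0.15, rr_gcsf = 0.5,
                         fn_case_fatality = 0.05, hr_low_rdi = 2,
                         cancer_annual_mortality = 0.03,
                         gcsf_cost = 200, fn_cost = 4000,
                         discount = 0.03, entry_age = 60, sex_mix = 0.5,
                         lt = list(type = "gompertz", a = 2.5e-5, b = 0.1,
                                   female_scale = 0.5, terminal_age = 110)) {
  new_scenario(
    cohort = list(cancer = "BC", entry_age = entry_age, sex_mix = sex_mix),
    clinical = list(baseline_fn_risk = baseline_fn_risk,
                    rr_later_cycles = 0.21, rr_history = 9.09,
                    rr_gcsf = rr_gcsf, p_low_rdi_no_fn = 0.3,
                    p_low_rdi_fn = 0.5, rdi_threshold_pct = 85),
    utilities = list(u_chemo = 0.55, u_fn_hosp = 0.33,
                     u_post_year1 = 0.66, u_post_later = 0.86),
    mortality = list(cancer_annual_mortality = cancer_annual_mortality,
                     fn_case_fatality = fn_case_fatality,
                     hr_low_rdi = hr_low_rdi),
    costs = list(fn_hospitalisation_cost = fn_cost, los_days = 6,
                 patient_weight_kg = 70, drug_unit_price = 0,
                 gcsf_cost_per_cycle = gcsf_cost),
    agent = "filgrastim",
    discount_rate_costs = discount, discount_rate_effects = discount,
    life_table = lt,
    psa = list(
      list(name = "baseline_fn_risk", low = 0.1, high = 0.2,
           family = "beta"),
      list(name = "rr_gcsf", low = 0.3, high = 0.7, family = "lognormal"),
      list(name = "fn_case_fatality", low = 0.03, high = 0.08,
           family = "beta")),
    meta = list(id = "toy"))
}
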