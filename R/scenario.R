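# Scenario configuration: typed parameter blocks, validation, JSON I/O.
#
# A scenario is one cancer x country x agent case. Blocks:
#   cohort    - entry age, sex mix, cycle structure, cure horizon
#   clinical  - FN risks and relative risks
#   utilities - health-state utilities (per year of state occupancy)
#   mortality - cancer excess mortality, FN case fatality, low-RDI hazard ratio
#   costs     - G-CSF and FN hospitalisation cost inputs
# plus discount rates, a life-table reference, the WTP grid and PSA settings.

CANCERS <- c("BC", "NSCLC", "NHL")
AGENTS  <- c("filgrastim", "pegfilgrastim")
STRATEGIES <- c("PP", "SP", "none")

# keys that may be absent from a scenario file; everything else is required
.scenario_defaults <- list(
  cohort = list(n_cycles = 6L, cycle_length_days = 21, cure_horizon_years = 20L),
  costs = list(gcsf_cost_per_cycle = NA_real_, units_per_dose = NA_real_,
               doses_per_cycle = 5),
  wtp_grid = c(0, 10000, 20000, 30000, 40000, 50000, 75000, 100000),
  psa_iterations = 1000L,
  seed = 1L
)

.required_scenario_keys <- list(
  cohort = c("cancer", "entry_age", "sex_mix"),
  clinical = c("baseline_fn_risk", "rr_later_cycles", "rr_history", "rr_gcsf",
               "p_low_rdi_no_fn", "p_low_rdi_fn", "rdi_threshold_pct"),
  utilities = c("u_chemo", "u_fn_hosp", "u_post_year1", "u_post_later"),
  mortality = c("cancer_annual_mortality", "fn_case_fatality", "hr_low_rdi"),
  costs = c("fn_hospitalisation_cost", "los_days", "patient_weight_kg",
            "drug_unit_price"),
  top = c("agent", "discount_rate_costs", "discount_rate_effects", "life_table")
)

#' Construct a scenario configuration
#'
#' Assembles and validates a scenario from its parameter blocks. Most users
#' will instead read a bundled fixture with [scenario_fixture()] or a file
#' with [load_scenario()].
#'
#' @param cohort,clinical,utilities,mortality,costs named lists; see the
#'   bundled fixtures for the full key set.
#' @param agent `"filgrastim"` or `"pegfilgrastim"`.
#' @param discount_rate_costs,discount_rate_effects annual discount rates
#'   (fractions, 0 to 0.2).
#' @param life_table either `list(type = "gompertz", a, b, female_scale,
#'   terminal_age)` or `list(type = "file", path = ...)`.
#' @param wtp_grid strictly increasing willingness-to-pay grid (EUR/QALY).
#' @param psa_iterations,seed defaults for [psa()].
#' @param psa list of uncertain-parameter descriptors
#'   (`list(name, low, high, family)`); base values are read from the blocks.
#' @param owsa extra one-way ranges for parameters without a PSA
#'   distribution (costs, length of stay, weight, discount rate).
#' @param meta free-form provenance metadata.
#' @return An object of class `fn_scenario`.
#' @export
new_scenario <- function(cohort, clinical, utilities, mortality, costs,
                         agent, discount_rate_costs, discount_rate_effects,
                         life_table, wtp_grid = .scenario_defaults$wtp_grid,
                         psa_iterations = 1000L, seed = 1L,
                         psa = list(), owsa = list(), meta = list()) {
  cfg <- structure(list(
    meta = meta, agent = agent, cohort = cohort, clinical = clinical,
    utilities = utilities, mortality = mortality, costs = costs,
    discount_rate_costs = discount_rate_costs,
    discount_rate_effects = discount_rate_effects,
    life_table = life_table, wtp_grid = wtp_grid,
    psa_iterations = as.integer(psa_iterations), seed = as.integer(seed),
    psa = psa, owsa = owsa), class = "fn_scenario")
  cfg <- .apply_scenario_defaults(cfg)
  validate_scenario(cfg)
}

.apply_scenario_defaults <- function(cfg) {
  for (k in names(.scenario_defaults$cohort))
    if (is.null(cfg$cohort[[k]])) cfg$cohort[[k]] <- .scenario_defaults$cohort[[k]]
  for (k in names(.scenario_defaults$costs))
    if (is.null(cfg$costs[[k]])) cfg$costs[[k]] <- .scenario_defaults$costs[[k]]
  if (is.null(cfg$wtp_grid)) cfg$wtp_grid <- .scenario_defaults$wtp_grid
  if (is.null(cfg$psa_iterations)) cfg$psa_iterations <- .scenario_defaults$psa_iterations
  if (is.null(cfg$seed)) cfg$seed <- .scenario_defaults$seed
  cfg
}

.check <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop("validation error: '", field, "' ", msg, call. = FALSE)
}

.prob <- function(x, field) {
  .check(is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1,
         field, "must be a probability in [0, 1]")
}

#' Validate a scenario configuration
#'
#' Checks every documented invariant (probabilities in \[0,1\], positive
#' relative risks, `rr_gcsf < 1`, utility ordering, discount-rate bounds,
#' strictly increasing WTP grid, ...). Called by [load_scenario()] and
#' [new_scenario()]; exported so sensitivity analyses can re-check perturbed
#' configurations.
#'
#' @param cfg an `fn_scenario`.
#' @return `cfg`, invisibly classed, if valid; otherwise an error naming the
#'   offending field and bound.
#' @export
validate_scenario <- function(cfg) {
  for (blk in c("cohort", "clinical", "utilities", "mortality", "costs")) {
    req <- .required_scenario_keys[[blk]]
    missing <- setdiff(req, names(cfg[[blk]]))
    if (length(missing))
      stop("configuration error: missing key '", blk, ".", missing[1], "'",
           call. = FALSE)
  }
  for (k in .required_scenario_keys$top)
    if (is.null(cfg[[k]]))
      stop("configuration error: missing key '", k, "'", call. = FALSE)

  co <- cfg$cohort
  .check(co$cancer %in% CANCERS, "cohort.cancer",
         paste("must be one of", paste(CANCERS, collapse = ", ")))
  .check(cfg$agent %in% AGENTS, "agent",
         paste("must be one of", paste(AGENTS, collapse = ", ")))
  .check(co$entry_age > 0, "cohort.entry_age", "must be > 0")
  .prob(co$sex_mix, "cohort.sex_mix")
  .check(co$n_cycles >= 1, "cohort.n_cycles", "must be >= 1")
  .check(co$cycle_length_days > 0, "cohort.cycle_length_days", "must be > 0")
  .check(co$cure_horizon_years >= 0, "cohort.cure_horizon_years", "must be >= 0")

  cl <- cfg$clinical
  .prob(cl$baseline_fn_risk, "clinical.baseline_fn_risk")
  for (k in c("rr_later_cycles", "rr_history", "rr_gcsf"))
    .check(cl[[k]] > 0, paste0("clinical.", k), "must be > 0")
  .check(cl$rr_gcsf < 1, "clinical.rr_gcsf", "must be < 1")
  .prob(cl$p_low_rdi_no_fn, "clinical.p_low_rdi_no_fn")
  .prob(cl$p_low_rdi_fn, "clinical.p_low_rdi_fn")

  ut <- cfg$utilities
  for (k in c("u_chemo", "u_fn_hosp", "u_post_year1", "u_post_later"))
    .prob(ut[[k]], paste0("utilities.", k))
  .check(ut$u_fn_hosp <= ut$u_chemo, "utilities.u_fn_hosp",
         "must be <= u_chemo")

  mo <- cfg$mortality
  .prob(mo$cancer_annual_mortality, "mortality.cancer_annual_mortality")
  .prob(mo$fn_case_fatality, "mortality.fn_case_fatality")
  .check(mo$hr_low_rdi > 0, "mortality.hr_low_rdi", "must be > 0")

  cs <- cfg$costs
  for (k in c("fn_hospitalisation_cost", "los_days", "patient_weight_kg",
              "drug_unit_price", "doses_per_cycle"))
    .check(cs[[k]] >= 0, paste0("costs.", k), "must be >= 0")
  .check(cs$los_days <= co$cycle_length_days, "costs.los_days",
         "must be <= cohort.cycle_length_days")

  for (k in c("discount_rate_costs", "discount_rate_effects"))
    .check(cfg[[k]] >= 0 && cfg[[k]] <= 0.2, k, "must be in [0, 0.2]")
  .check(cfg$psa_iterations >= 1, "psa_iterations", "must be >= 1")
  .check(length(cfg$wtp_grid) >= 1 && all(diff(cfg$wtp_grid) > 0),
         "wtp_grid", "must be strictly increasing")
  .check(cfg$life_table$type %in% c("gompertz", "file"), "life_table.type",
         "must be 'gompertz' or 'file'")
  invisible(cfg)
}

#' Read a scenario file
#'
#' Scenario files are JSON with the block structure documented in
#' [new_scenario()]; the 18 bundled fixtures under
#' `system.file("extdata", "scenarios", package = "fncea")` are the schema
#' reference. Defaults are applied only for documented defaultable keys
#' (cycle structure, PSA settings, cost derivation helpers); any other
#' missing key is a configuration error naming the key.
#'
#' @param path path to a scenario JSON file.
#' @return A validated `fn_scenario`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$psa <- .as_param_list(raw$psa)
  raw$owsa <- .as_param_list(raw$owsa)
  cfg <- structure(raw, class = "fn_scenario")
  cfg <- .apply_scenario_defaults(cfg)
  validate_scenario(cfg)
  cfg
}

# jsonlite simplifies a homogeneous list of {name, low, high, family} records
# to a data.frame; normalise back to a list of records
.as_param_list <- function(x) {
  if (is.null(x)) return(list())
  if (is.data.frame(x)) x <- lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
  lapply(x, function(p) { p$name <- as.character(p$name); p })
}

#' Write a scenario to a JSON file
#'
#' Inverse of [load_scenario()]; `load_scenario(write_scenario(cfg, f))`
#' round-trips.
#'
#' @param cfg an `fn_scenario`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(cfg, path) {
  x <- unclass(cfg)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

# ---- named parameter access (used by OWSA/PSA) ------------------------------

# registry: parameter name -> c(block, field); "discount_rate" fans out to both
.param_paths <- list(
  baseline_fn_risk = c("clinical", "baseline_fn_risk"),
  rr_later_cycles = c("clinical", "rr_later_cycles"),
  rr_history = c("clinical", "rr_history"),
  rr_gcsf = c("clinical", "rr_gcsf"),
  p_low_rdi_no_fn = c("clinical", "p_low_rdi_no_fn"),
  p_low_rdi_fn = c("clinical", "p_low_rdi_fn"),
  u_chemo = c("utilities", "u_chemo"),
  u_fn_hosp = c("utilities", "u_fn_hosp"),
  u_post_year1 = c("utilities", "u_post_year1"),
  u_post_later = c("utilities", "u_post_later"),
  cancer_annual_mortality = c("mortality", "cancer_annual_mortality"),
  fn_case_fatality = c("mortality", "fn_case_fatality"),
  hr_low_rdi = c("mortality", "hr_low_rdi"),
  gcsf_cost_per_cycle = c("costs", "gcsf_cost_per_cycle"),
  fn_hospitalisation_cost = c("costs", "fn_hospitalisation_cost"),
  los_days = c("costs", "los_days"),
  patient_weight_kg = c("costs", "patient_weight_kg"))

#' Get or set a named model parameter
#'
#' Flat accessors over the block structure, used by the sensitivity module.
#' `"gcsf_cost_per_cycle"` reads the derived per-cycle drug cost (see
#' [gcsf_cost_per_cycle()]) and sets the direct override;
#' `"discount_rate"` reads/sets both the cost and effect rates.
#'
#' @param cfg an `fn_scenario`.
#' @param name a parameter name from the registry (see source) or
#'   `"discount_rate"`.
#' @param value replacement value.
#' @return `scenario_get`: the value. `scenario_set`: the modified scenario
#'   (not revalidated; call [validate_scenario()] if bounds may be violated).
#' @export
scenario_get <- function(cfg, name) {
  if (name == "discount_rate") return(cfg$discount_rate_effects)
  if (name == "gcsf_cost_per_cycle") return(gcsf_cost_per_cycle(cfg))
  p <- .param_paths[[name]]
  if (is.null(p)) stop("unknown parameter name: ", name, call. = FALSE)
  cfg[[p[1]]][[p[2]]]
}

#' @rdname scenario_get
#' @export
scenario_set <- function(cfg, name, value) {
  value <- unname(value)
  if (name == "discount_rate") {
    cfg$discount_rate_costs <- value
    cfg$discount_rate_effects <- value
    return(cfg)
  }
  p <- .param_paths[[name]]
  if (is.null(p)) stop("unknown parameter name: ", name, call. = FALSE)
  cfg[[p[1]]][[p[2]]] <- value
  cfg
}

#' Per-cycle G-CSF drug cost
#'
#' If `costs.gcsf_cost_per_cycle` is set it is used directly. Otherwise the
#' cost is derived from the unit price: filgrastim is dosed at 5 ug/kg/day,
#' rounded up to whole 300-ug vials, for `doses_per_cycle` days per cycle;
#' pegfilgrastim is one fixed dose per cycle.
#'
#' @param cfg an `fn_scenario`.
#' @return Drug cost per prophylaxis cycle (EUR).
#' @export
gcsf_cost_per_cycle <- function(cfg) {
  cs <- cfg$costs
  if (!is.null(cs$gcsf_cost_per_cycle) && !is.na(cs$gcsf_cost_per_cycle))
    return(cs$gcsf_cost_per_cycle)
  units <- cs$units_per_dose
  if (is.null(units) || is.na(units)) {
    units <- if (cfg$agent == "filgrastim")
      ceiling(5 * cs$patient_weight_kg / 300) else 1
  }
  doses <- if (cfg$agent == "filgrastim") cs$doses_per_cycle else 1
  units * cs$drug_unit_price * doses
}

#' @export
print.fn_scenario <- function(x, ...) {
  id <- x$meta$id %||% "<unnamed>"
  cat("G-CSF prophylaxis scenario:", id, "\n")
  cat(sprintf("  cancer %s, agent %s, entry age %g, %.0f%% female\n",
              x$cohort$cancer, x$agent, x$cohort$entry_age,
              100 * x$cohort$sex_mix))
  cat(sprintf("  baseline FN risk %.3f (course), RR G-CSF %.2f\n",
              x$clinical$baseline_fn_risk, x$clinical$rr_gcsf))
  cat(sprintf("  G-CSF cost/cycle %.2f, FN hospitalisation %.2f EUR\n",
              gcsf_cost_per_cycle(x), x$costs$fn_hospitalisation_cost))
  cat(sprintf("  discount %g%% costs / %g%% effects; %d PSA parameters\n",
              100 * x$discount_rate_costs, 100 * x$discount_rate_effects,
              length(x$psa)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
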