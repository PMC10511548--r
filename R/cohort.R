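# Deterministic cohort engine.
#
# Phase 1 (chemotherapy): cycle 1 is a decision tree, cycles 2..n a Markov
# cycle tree over {alive no FN history, alive FN history, dead}. Each cycle:
# FN event -> inpatient admission (lump cost); FN case fatality applies at
# the end of the cycle; FN survivors carry a history flag that raises later
# FN risk and, under SP, triggers prophylaxis from the next cycle. All
# chemotherapy-phase deaths are FN deaths. Decedents accrue the dying
# cycle's utility and costs (end-of-cycle deaths). Mid-cycle discounting.
#
# Phase 2 (post-chemotherapy): annual Markov cycles. Survivors split once
# into low/high relative-dose-intensity (RDI) strata from their ever-FN
# status; annual death probability = background qx(age, sex) + cancer
# excess mortality (times the low-RDI hazard ratio in the low stratum),
# clamped at 1, for the first 20 years; background only thereafter (cure).
# Year k is accrued by its end-of-year survivors, discounted mid-year; no
# post-chemotherapy costs.

#' Convert a 5-year death probability to an annual probability
#'
#' Uses the constant-rate identity `r = -log(1 - P)/t`, then
#' `1 - exp(-r)` for the 1-year probability.
#'
#' @param p5 death probability over `t` years, in \[0, 1).
#' @param t horizon of `p5` in years (default 5).
#' @return Annual death probability.
#' @export
annual_prob_from_5yr_death <- function(p5, t = 5) {
  stopifnot(t > 0)
  if (any(p5 < 0) || any(p5 >= 1))
    stop("p5 must lie in [0, 1): a certain death implies an infinite rate",
         call. = FALSE)
  r <- -log(1 - p5) / t
  1 - exp(-r)
}

# discount factor at time t (years) for rate d, mid-period convention applied
# by the callers
.disc <- function(t, d) (1 + d)^(-t)

#' Run the chemotherapy phase for one strategy
#'
#' @param cfg an `fn_scenario`.
#' @param strategy `"PP"`, `"SP"` or `"none"`.
#' @param risks optional precomputed [cycle_risk_table()].
#' @param trace keep a per-cycle occupancy/accrual trace?
#' @return A list with final occupancy (`no_hist`, `hist`, `dead`),
#'   discounted cost / LY / QALY accruals, expected FN events and FN deaths,
#'   the discounted prophylaxis-cycle and FN-event counts used by
#'   [calibrate_costs()], and the phase duration in years.
#' @export
run_chemo_phase <- function(cfg, strategy = "PP", risks = NULL,
                            trace = FALSE) {
  strategy <- match.arg(strategy, STRATEGIES)
  co <- cfg$cohort; cl <- cfg$clinical; ut <- cfg$utilities
  n <- co$n_cycles
  if (is.null(risks)) risks <- cycle_risk_table(cl, n)
  cyc_yr <- co$cycle_length_days / 365.25
  los_yr <- min(cfg$costs$los_days, co$cycle_length_days) / 365.25
  cfr <- cfg$mortality$fn_case_fatality
  g <- gcsf_cost_per_cycle(cfg)
  h <- cfg$costs$fn_hospitalisation_cost
  d_c <- cfg$discount_rate_costs; d_e <- cfg$discount_rate_effects

  occ <- c(no_hist = 1, hist = 0, dead = 0)
  ly <- qaly <- cost <- fn_events <- fn_deaths <- 0
  disc_drug_cycles <- disc_fn_events <- 0
  tr <- if (trace) vector("list", n)

  for (k in seq_len(n)) {
    t_mid <- (k - 0.5) * cyc_yr
    we <- .disc(t_mid, d_e); wc <- .disc(t_mid, d_c)
    m_nh <- occ[["no_hist"]]; m_h <- occ[["hist"]]
    p_nh <- per_cycle_fn_prob(k, FALSE, strategy, cl$rr_gcsf, risks)
    p_h <- per_cycle_fn_prob(k, TRUE, strategy, cl$rr_gcsf, risks)
    fn_nh <- m_nh * p_nh; fn_h <- m_h * p_h
    fn <- fn_nh + fn_h
    die <- fn * cfr
    alive <- m_nh + m_h

    # drug given at the start of the cycle to everyone eligible and alive
    drug_mass <- (if (.prophylaxis_active(strategy, FALSE)) m_nh else 0) +
                 (if (.prophylaxis_active(strategy, TRUE)) m_h else 0)

    ly <- ly + alive * cyc_yr * we
    qaly <- qaly + ((alive - fn) * cyc_yr * ut$u_chemo +
                    fn * (los_yr * ut$u_fn_hosp +
                          (cyc_yr - los_yr) * ut$u_chemo)) * we
    cost <- cost + (drug_mass * g + fn * h) * wc
    disc_drug_cycles <- disc_drug_cycles + drug_mass * wc
    disc_fn_events <- disc_fn_events + fn * wc
    fn_events <- fn_events + fn
    fn_deaths <- fn_deaths + die

    occ <- c(no_hist = m_nh - fn_nh,
             hist = m_h - fn_h + (fn_nh + fn_h) * (1 - cfr),
             dead = occ[["dead"]] + die)
    if (abs(sum(occ) - 1) > 1e-9)
      stop("internal consistency error: occupancy drift ",
           abs(sum(occ) - 1), " after cycle ", k, call. = FALSE)
    if (trace)
      tr[[k]] <- data.frame(cycle = k, no_hist = occ[["no_hist"]],
                            hist = occ[["hist"]], dead = occ[["dead"]],
                            fn_events = fn, fn_deaths = die,
                            cost = (drug_mass * g + fn * h) * wc)
  }
  list(occ = occ, ly = ly, qaly = qaly, cost = cost,
       fn_events = fn_events, fn_deaths = fn_deaths,
       disc_drug_cycles = disc_drug_cycles, disc_fn_events = disc_fn_events,
       duration_years = n * cyc_yr,
       trace = if (trace) do.call(rbind, tr))
}

# annual death probabilities for one post-chemo stratum, years 1..K
.post_chemo_q <- function(cfg, lt, sex, low_rdi) {
  entry_age <- floor(cfg$cohort$entry_age)
  K <- lt$terminal_age - entry_age + 1
  ages <- entry_age + seq_len(K) - 1
  q <- lt_qx(lt, ages, sex)
  cure <- cfg$cohort$cure_horizon_years
  excess <- cfg$mortality$cancer_annual_mortality *
    (if (low_rdi) cfg$mortality$hr_low_rdi else 1)
  idx <- seq_len(min(cure, K))
  q[idx] <- pmin(1, q[idx] + excess)
  q
}

#' Run the post-chemotherapy phase
#'
#' Splits the chemotherapy survivors into low/high RDI strata from their
#' FN-history mix (the history mix is carried exactly, not approximated) and
#' accrues discounted life years and QALYs over annual cycles until the
#' life-table terminal age. Year k is weighted by its end-of-year survivors
#' and discounted at `chemo duration + k - 1/2` years.
#'
#' @param cfg an `fn_scenario`.
#' @param entry result of [run_chemo_phase()].
#' @param lt an `fn_life_table` (defaults to the scenario's).
#' @return A list with `ly`, `qaly` contributions and the entry masses per
#'   stratum.
#' @export
run_post_chemo_phase <- function(cfg, entry, lt = NULL) {
  if (is.null(lt)) lt <- scenario_life_table(cfg)
  cl <- cfg$clinical; ut <- cfg$utilities
  m_nh <- entry$occ[["no_hist"]]; m_h <- entry$occ[["hist"]]
  p_low_nh <- rdi_distribution(FALSE, cl)
  p_low_h <- rdi_distribution(TRUE, cl)
  mass_low <- m_nh * p_low_nh + m_h * p_low_h
  mass_high <- m_nh * (1 - p_low_nh) + m_h * (1 - p_low_h)
  sexes <- c(female = cfg$cohort$sex_mix, male = 1 - cfg$cohort$sex_mix)

  d_e <- cfg$discount_rate_effects
  t0 <- entry$duration_years
  entry_age <- floor(cfg$cohort$entry_age)
  K <- lt$terminal_age - entry_age + 1
  we <- .disc(t0 + seq_len(K) - 0.5, d_e)
  u <- c(ut$u_post_year1, rep(ut$u_post_later, K - 1))

  ly <- qaly <- 0
  strata <- list()
  for (sex in names(sexes)) {
    if (sexes[[sex]] == 0) next
    for (low in c(TRUE, FALSE)) {
      mass <- sexes[[sex]] * (if (low) mass_low else mass_high)
      if (mass == 0) next
      q <- .post_chemo_q(cfg, lt, sex, low)
      S <- cumprod(1 - q)
      ly <- ly + mass * sum(S * we)
      qaly <- qaly + mass * sum(S * u * we)
      strata[[paste0(sex, if (low) "_low" else "_high")]] <- mass
    }
  }
  list(ly = ly, qaly = qaly, entry_masses = strata)
}

#' Evaluate one prophylaxis strategy over the lifetime horizon
#'
#' Composes the cycle-1 risk calibration, the chemotherapy phase and the
#' post-chemotherapy phase. Deterministic: identical inputs give identical
#' outputs.
#'
#' @param cfg an `fn_scenario`.
#' @param strategy `"PP"`, `"SP"` or `"none"` (no prophylaxis; used to
#'   express FN events avoided).
#' @param lt optional precomputed life table (saves recomputation in
#'   sensitivity loops).
#' @param trace attach the per-cycle chemotherapy trace?
#' @return An object of class `fn_outcome`: total discounted cost (EUR),
#'   life years, QALYs, expected FN events and FN deaths per patient, plus
#'   the discounted quantities that make total cost linear in the two cost
#'   inputs (used by [calibrate_costs()]).
#' @export
run_strategy <- function(cfg, strategy = "PP", lt = NULL, trace = FALSE) {
  strategy <- match.arg(strategy, STRATEGIES)
  if (is.null(lt)) lt <- scenario_life_table(cfg)
  chemo <- run_chemo_phase(cfg, strategy, trace = trace)
  post <- run_post_chemo_phase(cfg, chemo, lt)
  structure(list(
    strategy = strategy,
    cost = chemo$cost,
    ly = chemo$ly + post$ly,
    qaly = chemo$qaly + post$qaly,
    fn_events = chemo$fn_events,
    fn_deaths = chemo$fn_deaths,
    fn_avoided = NA_real_,
    disc_drug_cycles = chemo$disc_drug_cycles,
    disc_fn_events = chemo$disc_fn_events,
    chemo = chemo, post = post), class = "fn_outcome")
}

#' Construct a strategy outcome from given numbers
#'
#' Wraps externally supplied outcome figures (for example the published
#' base-case rows) in the container that [incremental()] consumes.
#'
#' @param cost total discounted cost (EUR).
#' @param ly,qaly discounted life years and QALYs.
#' @param fn_events expected FN events per patient (optional).
#' @param fn_avoided FN events avoided versus no prophylaxis (optional; the
#'   published tables report this column).
#' @param fn_deaths expected FN deaths per patient (optional).
#' @param strategy label.
#' @return An `fn_outcome`.
#' @export
strategy_outcome <- function(cost, ly, qaly, fn_events = NA_real_,
                             fn_avoided = NA_real_, fn_deaths = NA_real_,
                             strategy = NA_character_) {
  stopifnot(cost >= 0, ly >= 0, qaly >= 0, qaly <= ly + 1e-9)
  structure(list(strategy = strategy, cost = cost, ly = ly, qaly = qaly,
                 fn_events = fn_events, fn_deaths = fn_deaths,
                 fn_avoided = fn_avoided), class = "fn_outcome")
}

#' @export
print.fn_outcome <- function(x, ...) {
  cat(sprintf("strategy %s: cost %.2f EUR, %.4f LY, %.4f QALY",
              x$strategy, x$cost, x$ly, x$qaly))
  if (!is.na(x$fn_events))
    cat(sprintf(", %.4f FN events (%.4f deaths)", x$fn_events, x$fn_deaths))
  cat("\n")
  invisible(x)
}

#' Base-case cost-effectiveness analysis of a scenario
#'
#' Runs primary prophylaxis, secondary prophylaxis and the no-prophylaxis
#' reference (the latter only to express FN events avoided, mirroring the
#' published table layout), then forms the incremental comparison PP vs SP.
#'
#' @param cfg an `fn_scenario`.
#' @return An object of class `fn_cea` with elements `pp`, `sp`, `none`
#'   (`fn_outcome`s) and `incremental` (an `fn_ceresult`).
#' @export
run_cea <- function(cfg) {
  validate_scenario(cfg)
  lt <- scenario_life_table(cfg)
  pp <- run_strategy(cfg, "PP", lt)
  sp <- run_strategy(cfg, "SP", lt)
  none <- run_strategy(cfg, "none", lt)
  pp$fn_avoided <- none$fn_events - pp$fn_events
  sp$fn_avoided <- none$fn_events - sp$fn_events
  structure(list(meta = cfg$meta, scenario = cfg,
                 pp = pp, sp = sp, none = none,
                 incremental = incremental(pp, sp)),
            class = "fn_cea")
}
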