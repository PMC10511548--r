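# Patient-level microsimulation of the identical event logic, used as an
# independent oracle for the cohort engine: Bernoulli FN events and deaths
# per cycle, then a sampled death year from the stratum-specific
# post-chemotherapy survival distribution. Accrual and discounting
# conventions match the cohort engine exactly (decedents accrue the dying
# chemotherapy cycle; post-chemotherapy year k is accrued only by patients
# alive at its end).

#' Microsimulate individual patients under one strategy
#'
#' @param cfg an `fn_scenario`.
#' @param strategy `"PP"`, `"SP"` or `"none"`.
#' @param n number of simulated patients.
#' @param seed RNG seed (reproducible: same seed, same estimates).
#' @return An object of class `fn_microsim`: means and Monte-Carlo standard
#'   errors for cost, LY, QALY and FN events per patient.
#' @export
simulate_individuals <- function(cfg, strategy = "PP", n = 1e4,
                                 seed = cfg$seed) {
  strategy <- match.arg(strategy, STRATEGIES)
  validate_scenario(cfg)
  stopifnot(n >= 1)
  set.seed(seed)
  co <- cfg$cohort; cl <- cfg$clinical; ut <- cfg$utilities
  lt <- scenario_life_table(cfg)
  risks <- cycle_risk_table(cl, co$n_cycles)
  cyc_yr <- co$cycle_length_days / 365.25
  los_yr <- min(cfg$costs$los_days, co$cycle_length_days) / 365.25
  cfr <- cfg$mortality$fn_case_fatality
  g <- gcsf_cost_per_cycle(cfg)
  h <- cfg$costs$fn_hospitalisation_cost
  d_c <- cfg$discount_rate_costs; d_e <- cfg$discount_rate_effects

  alive <- rep(TRUE, n)
  hist <- rep(FALSE, n)
  cost <- ly <- qaly <- numeric(n)
  fn_count <- integer(n)

  for (k in seq_len(co$n_cycles)) {
    we <- .disc((k - 0.5) * cyc_yr, d_e)
    wc <- .disc((k - 0.5) * cyc_yr, d_c)
    p <- ifelse(hist,
                per_cycle_fn_prob(k, TRUE, strategy, cl$rr_gcsf, risks),
                per_cycle_fn_prob(k, FALSE, strategy, cl$rr_gcsf, risks))
    on_gcsf <- alive & (strategy == "PP" | (strategy == "SP" & hist))
    cost[on_gcsf] <- cost[on_gcsf] + g * wc
    fn <- alive & (runif(n) < p)
    die <- fn & (runif(n) < cfr)
    cost[fn] <- cost[fn] + h * wc
    ly[alive] <- ly[alive] + cyc_yr * we
    qaly[alive & !fn] <- qaly[alive & !fn] + cyc_yr * ut$u_chemo * we
    qaly[fn] <- qaly[fn] + (los_yr * ut$u_fn_hosp +
                            (cyc_yr - los_yr) * ut$u_chemo) * we
    fn_count[fn] <- fn_count[fn] + 1L
    hist[fn & !die] <- TRUE
    alive[die] <- FALSE
  }

  # post-chemo: stratify, then sample the death year from the stratum's
  # discrete survival distribution and look up the cumulative discounted
  # accruals for the years survived
  surv <- which(alive)
  if (length(surv)) {
    female <- runif(n) < co$sex_mix
    p_low <- ifelse(hist, cl$p_low_rdi_fn, cl$p_low_rdi_no_fn)
    low <- runif(n) < p_low
    t0 <- co$n_cycles * cyc_yr
    entry_age <- floor(co$entry_age)
    K <- lt$terminal_age - entry_age + 1
    we <- .disc(t0 + seq_len(K) - 0.5, d_e)
    u <- c(ut$u_post_year1, rep(ut$u_post_later, K - 1))
    cum_ly <- cumsum(we)           # discounted LY if alive through year j
    cum_qaly <- cumsum(u * we)
    for (sex in c("female", "male")) for (lo in c(TRUE, FALSE)) {
      idx <- surv[female[surv] == (sex == "female") & low[surv] == lo]
      if (!length(idx)) next
      q <- .post_chemo_q(cfg, lt, sex, lo)
      S <- c(1, cumprod(1 - q))          # S[j+1] = P(alive through year j)
      pk <- S[-length(S)] * q            # die during year k
      # death year by inverse CDF; S hits 0 at the terminal age so pk sums to 1
      death_year <- findInterval(runif(length(idx)), cumsum(pk),
                                 left.open = TRUE) + 1L
      yrs <- death_year - 1L             # full years survived (and accrued)
      ly[idx] <- ly[idx] + ifelse(yrs > 0, cum_ly[pmax(yrs, 1)], 0)
      qaly[idx] <- qaly[idx] + ifelse(yrs > 0, cum_qaly[pmax(yrs, 1)], 0)
    }
  }

  est <- function(x) c(mean = mean(x), se = sd(x) / sqrt(n))
  structure(list(strategy = strategy, n = n, seed = seed,
                 cost = est(cost), ly = est(ly), qaly = est(qaly),
                 fn_events = est(fn_count)), class = "fn_microsim")
}

#' @export
print.fn_microsim <- function(x, ...) {
  cat(sprintf("microsimulation, %s, n = %d (seed %d)\n", x$strategy, x$n,
              x$seed))
  for (m in c("cost", "ly", "qaly", "fn_events"))
    cat(sprintf("  %-10s %.4f (SE %.5f)\n", m, x[[m]]["mean"], x[[m]]["se"]))
  invisible(x)
}
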