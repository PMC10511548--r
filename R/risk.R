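# Per-cycle FN risk model.
#
# The clinical inputs give one course-level FN probability (over all cycles)
# plus relative risks: later cycles vs cycle 1 (no history), FN history vs
# no history, and G-CSF prophylaxis vs none. The course-level risk is
# distributed over cycles by solving for the cycle-1 probability p1 such
# that, on the no-history no-prophylaxis path,
#   1 - (1 - p1) * (1 - rr_later * p1)^(n - 1) = p_total.

#' Calibrate the cycle-1 FN probability from the course-level risk
#'
#' Solves `1 - (1 - p1) (1 - rr_later p1)^(n_cycles - 1) = p_total` for `p1`
#' by bracketed root finding on `[0, min(1, 1/rr_later)]`; the residual of
#' the returned root is below 1e-10.
#'
#' @param p_total FN probability over the full course, in (0, 1).
#' @param rr_later relative risk of FN in cycles 2+ (no history) vs cycle 1.
#' @param n_cycles number of chemotherapy cycles.
#' @return Cycle-1 FN probability on the no-history, no-prophylaxis path.
#' @export
calibrate_cycle1_risk <- function(p_total, rr_later, n_cycles) {
  if (!(p_total > 0 && p_total < 1))
    stop("calibration error: p_total must lie in (0, 1)", call. = FALSE)
  stopifnot(rr_later > 0, n_cycles >= 1)
  if (n_cycles == 1) return(p_total)
  f <- function(p1)
    1 - (1 - p1) * (1 - pmin(1, rr_later * p1))^(n_cycles - 1) - p_total
  hi <- min(1, 1 / rr_later)
  if (f(hi) < 0)
    stop("calibration error: no root in [0, ", signif(hi, 6),
         "] for p_total = ", p_total, call. = FALSE)
  r <- uniroot(f, c(0, hi), tol = .Machine$double.eps / 4)$root
  # polish by bisection until the residual meets the contract
  lo2 <- max(0, r - 1e-8); hi2 <- min(hi, r + 1e-8)
  if (f(lo2) > 0) lo2 <- 0
  if (f(hi2) < 0) hi2 <- hi
  for (i in 1:200) {
    if (abs(f(r)) < 1e-12) break
    mid <- (lo2 + hi2) / 2
    if (f(mid) < 0) lo2 <- mid else hi2 <- mid
    r <- (lo2 + hi2) / 2
  }
  if (abs(f(r)) >= 1e-10)
    stop("calibration error: residual ", abs(f(r)), call. = FALSE)
  r
}

#' Per-cycle FN probability table
#'
#' @param clinical the `clinical` block of a scenario.
#' @param n_cycles number of chemotherapy cycles.
#' @return An `fn_cycle_risks` object with the no-prophylaxis per-cycle
#'   probabilities: `p_cycle1`, `p_later_no_hist = rr_later * p_cycle1` and
#'   `p_later_hist = rr_history * p_later_no_hist`, each clamped to \[0,1\].
#' @export
cycle_risk_table <- function(clinical, n_cycles = 6) {
  p1 <- calibrate_cycle1_risk(clinical$baseline_fn_risk,
                              clinical$rr_later_cycles, n_cycles)
  p_later <- min(1, clinical$rr_later_cycles * p1)
  structure(list(
    p_cycle1 = p1,
    p_later_no_hist = p_later,
    p_later_hist = min(1, clinical$rr_history * p_later),
    n_cycles = n_cycles), class = "fn_cycle_risks")
}

#' @export
print.fn_cycle_risks <- function(x, ...) {
  cat(sprintf(
    "per-cycle FN risk (no prophylaxis): cycle 1 %.4f; later %.4f (no history), %.4f (history)\n",
    x$p_cycle1, x$p_later_no_hist, x$p_later_hist))
  invisible(x)
}

#' @export
as.data.frame.fn_cycle_risks <- function(x, ...) {
  data.frame(cycle = seq_len(x$n_cycles),
             p_no_history = c(x$p_cycle1,
                              rep(x$p_later_no_hist, x$n_cycles - 1)),
             p_history = c(NA_real_, rep(x$p_later_hist, x$n_cycles - 1)))
}

# is G-CSF given this cycle? PP: every cycle; SP: only once a first FN event
# is on record (history); none: never
.prophylaxis_active <- function(strategy, history) {
  switch(strategy, PP = TRUE, SP = history, none = FALSE,
         stop("unknown strategy: ", strategy, call. = FALSE))
}

#' FN probability for one cycle, history stratum and strategy
#'
#' The baseline probability from the [cycle_risk_table()] is multiplied by
#' the agent relative risk if and only if prophylaxis is active that cycle:
#' always under primary prophylaxis (PP), only in the cycles after a first
#' FN event under secondary prophylaxis (SP).
#'
#' @param cycle cycle index, 1-based.
#' @param history does the patient enter the cycle with a history of FN?
#' @param strategy `"PP"`, `"SP"` or `"none"`.
#' @param agent_rr relative risk of FN on prophylaxis, in (0, 1\].
#' @param table an `fn_cycle_risks`.
#' @return FN probability for the cycle, clamped to \[0, 1\].
#' @export
per_cycle_fn_prob <- function(cycle, history, strategy, agent_rr, table) {
  stopifnot(cycle >= 1, cycle <= table$n_cycles,
            agent_rr > 0, agent_rr <= 1)
  base <- if (cycle == 1 && !history) table$p_cycle1
          else if (!history) table$p_later_no_hist
          else table$p_later_hist
  mult <- if (.prophylaxis_active(strategy, history)) agent_rr else 1
  min(1, max(0, base * mult))
}

#' Probability of low relative dose intensity
#'
#' At the end of chemotherapy patients split into low- and high-RDI strata;
#' the probability of falling below the cancer-specific RDI threshold is
#' higher for patients with an FN history.
#'
#' @param ever_fn did the patient experience at least one FN event?
#' @param clinical the `clinical` block of a scenario.
#' @return Probability of low RDI.
#' @export
rdi_distribution <- function(ever_fn, clinical) {
  if (ever_fn) clinical$p_low_rdi_fn else clinical$p_low_rdi_no_fn
}
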