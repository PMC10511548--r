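# Incremental cost-effectiveness statistics.

.icer_labels <- c(icer = "ICER", dominant = "Dominates",
                  dominated = "Dominated", not_effective = "Not effective",
                  equivalent = "Equivalent")

#' Incremental comparison of primary vs secondary prophylaxis
#'
#' Deltas are PP minus SP for cost, life years and QALYs; the FN-event delta
#' is expressed as events avoided (SP events minus PP events, or the
#' difference of the `fn_avoided` columns when outcomes carry those). PP is
#' *dominant* when it is cheaper and better on every effect measure,
#' *dominated* when dearer and worse on every measure; otherwise ratios
#' `delta cost / delta effect` are reported per measure. A zero effect delta
#' with a positive cost delta is flagged `not effective` rather than
#' divided; identical outcomes are `equivalent`.
#'
#' @param pp,sp `fn_outcome`s for primary and secondary prophylaxis from the
#'   same scenario.
#' @return An object of class `fn_ceresult` with fields `delta_cost`,
#'   `delta_fn_avoided`, `delta_ly`, `delta_qaly`, `icer_fn`, `icer_ly`,
#'   `icer_qaly` (NA unless `status == "icer"`) and `status`.
#' @export
incremental <- function(pp, sp) {
  dc <- pp$cost - sp$cost
  d_fn <- if (!is.na(pp$fn_avoided) && !is.na(sp$fn_avoided))
    pp$fn_avoided - sp$fn_avoided else sp$fn_events - pp$fn_events
  d_ly <- pp$ly - sp$ly
  d_qaly <- pp$qaly - sp$qaly
  eff <- c(fn = d_fn, ly = d_ly, qaly = d_qaly)
  eff_known <- eff[!is.na(eff)]

  status <-
    if (dc == 0 && all(eff_known == 0)) "equivalent"
    else if (dc < 0 && all(eff_known > 0)) "dominant"
    else if (dc > 0 && all(eff_known < 0)) "dominated"
    else if (dc > 0 && all(eff_known == 0)) "not_effective"
    else "icer"

  icers <- setNames(rep(NA_real_, 3), c("fn", "ly", "qaly"))
  if (status == "icer")
    for (m in names(icers))
      if (!is.na(eff[m]) && eff[m] != 0) icers[m] <- dc / eff[m]

  structure(list(delta_cost = dc, delta_fn_avoided = d_fn, delta_ly = d_ly,
                 delta_qaly = d_qaly, icer_fn = icers[["fn"]],
                 icer_ly = icers[["ly"]], icer_qaly = icers[["qaly"]],
                 status = status), class = "fn_ceresult")
}

#' @export
print.fn_ceresult <- function(x, ...) {
  cat(sprintf("PP vs SP: delta cost %.2f EUR, %.4f FN avoided, %.4f LY, %.4f QALY\n",
              x$delta_cost, x$delta_fn_avoided, x$delta_ly, x$delta_qaly))
  if (x$status == "icer")
    cat(sprintf("ICERs: %.0f EUR/FN avoided, %.0f EUR/LY, %.0f EUR/QALY\n",
                x$icer_fn, x$icer_ly, x$icer_qaly))
  else cat("status:", .icer_labels[[x$status]], "\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * QALY - cost`. Comparing NMB between strategies at a given
#' willingness to pay is equivalent to the ICER decision rule when the QALY
#' delta is positive.
#'
#' @param outcome an `fn_outcome` (or anything with `cost` and `qaly`).
#' @param wtp willingness to pay, EUR per QALY, `>= 0`.
#' @return Net monetary benefit in EUR.
#' @export
nmb <- function(outcome, wtp) {
  stopifnot(wtp >= 0)
  wtp * outcome$qaly - outcome$cost
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of paired PSA draws in
#' which primary prophylaxis has the strictly higher net monetary benefit
#' (ties count as not cost-effective).
#'
#' @param draws data frame of paired per-iteration results with columns
#'   `cost_pp`, `qaly_pp`, `cost_sp`, `qaly_sp` (as produced by [psa()]).
#' @param wtp_grid willingness-to-pay grid, EUR/QALY.
#' @return Data frame with columns `wtp` and `p_ce`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (is.null(draws) || nrow(draws) == 0)
    stop("ceac: empty draw set", call. = FALSE)
  p <- vapply(wtp_grid, function(w)
    mean(w * draws$qaly_pp - draws$cost_pp >
         w * draws$qaly_sp - draws$cost_sp), numeric(1))
  data.frame(wtp = wtp_grid, p_ce = p)
}
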