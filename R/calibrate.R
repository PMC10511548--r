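# Cost calibration.
#
# The per-country unit-cost tables behind the published totals are not
# redistributable, but total discounted cost per strategy is exactly linear
# in the two unknown cost inputs:
#   cost(strategy) = g * E[discounted prophylaxis cycles]
#                  + h * E[discounted FN events]
# with g the G-CSF cost per cycle and h the FN hospitalisation cost. The
# PP and SP rows of a published base-case block therefore identify (g, h)
# through a 2x2 linear system whose coefficients come from running the
# cohort model once per strategy. Clinical parameters are never touched.

#' Solve for the cost inputs from published strategy totals
#'
#' @param target list or one-row data frame with `pp_cost` and `sp_cost`
#'   (EUR, total discounted cost per strategy).
#' @param cfg an `fn_scenario`, complete apart from its cost inputs.
#' @param max_condition reject systems with a condition number above this.
#' @return A `costs` block for the scenario: solved
#'   `fn_hospitalisation_cost`, and the solved per-cycle G-CSF cost stored
#'   as a derived unit price (filgrastim: price per 300-ug vial given the
#'   configured weight-based vial count and doses per cycle, so that patient
#'   weight remains a live sensitivity input; pegfilgrastim: price per
#'   dose). `provenance` is set to `"calibrated"`.
#' @export
calibrate_costs <- function(target, cfg, max_condition = 1e6) {
  lt <- scenario_life_table(cfg)
  pp <- run_strategy(cfg, "PP", lt)
  sp <- run_strategy(cfg, "SP", lt)
  A <- rbind(c(pp$disc_drug_cycles, pp$disc_fn_events),
             c(sp$disc_drug_cycles, sp$disc_fn_events))
  if (!all(is.finite(A)) || kappa(A, exact = TRUE) > max_condition)
    stop("calibration error: cost system is singular or ill-conditioned ",
         "(condition number ", signif(kappa(A, exact = TRUE), 3), ")",
         call. = FALSE)
  x <- solve(A, c(target$pp_cost, target$sp_cost))
  g <- x[1]; h <- x[2]
  if (g < 0 || h < 0)
    stop("calibration error: negative solved cost (g = ", signif(g, 6),
         ", h = ", signif(h, 6),
         "); model and target are inconsistent", call. = FALSE)
  costs <- cfg$costs
  costs$fn_hospitalisation_cost <- h
  costs$gcsf_cost_per_cycle <- NA_real_
  if (cfg$agent == "filgrastim") {
    vials <- ceiling(5 * costs$patient_weight_kg / 300)
    costs$drug_unit_price <- g / (vials * costs$doses_per_cycle)
  } else {
    costs$drug_unit_price <- g
    costs$units_per_dose <- 1
    costs$doses_per_cycle <- 1
  }
  costs$provenance <- "calibrated"
  costs
}
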