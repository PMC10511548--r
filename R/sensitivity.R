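# One-way (tornado) and probabilistic sensitivity analysis.

# ICER on the cost-per-QALY scale with dominance mapped to 0 (for tornado
# ordering); "not effective" bounds (zero QALY delta at positive cost) have
# no finite ICER and are also mapped to 0
.icer_scale <- function(inc) {
  if (inc$status == "icer" && !is.na(inc$icer_qaly)) inc$icer_qaly else 0
}

#' One-way sensitivity analysis (tornado)
#'
#' Re-runs the full base case with each parameter at its lower and upper
#' bound in turn, all other parameters held at base, and ranks parameters by
#' the swing of the cost-per-QALY ICER (dominance is mapped to 0 on the ICER
#' scale for ordering). Bounds that violate a structural invariant are
#' skipped with a warning.
#'
#' @param cfg an `fn_scenario`.
#' @param params list of [uncertain_parameter()]s; defaults to the
#'   scenario's PSA parameters plus its OWSA-only ranges (costs, length of
#'   stay, patient weight, discount rate).
#' @return An object of class `fn_owsa`: a data frame with one row per
#'   parameter (`parameter`, `low`, `high`, `icer_at_low`, `icer_at_high`,
#'   `status_low`, `status_high`, `swing`), sorted by descending swing,
#'   with the base-case ICER as attribute `base_icer`.
#' @export
owsa <- function(cfg, params = NULL) {
  validate_scenario(cfg)
  if (is.null(params)) params <- uncertain_parameters(cfg, TRUE)
  lt <- scenario_life_table(cfg)
  base_inc <- incremental(run_strategy(cfg, "PP", lt),
                          run_strategy(cfg, "SP", lt))

  one_bound <- function(name, value) {
    cfg2 <- scenario_set(cfg, name, value)
    ok <- tryCatch({ validate_scenario(cfg2); TRUE },
                   error = function(e) { warning(
                     "owsa: skipping '", name, "' at ", value, ": ",
                     conditionMessage(e), call. = FALSE); FALSE })
    if (!ok) return(NULL)
    incremental(run_strategy(cfg2, "PP", lt), run_strategy(cfg2, "SP", lt))
  }

  rows <- lapply(params, function(p) {
    inc_lo <- one_bound(p$name, p$low)
    inc_hi <- one_bound(p$name, p$high)
    if (is.null(inc_lo) || is.null(inc_hi)) return(NULL)
    lo <- .icer_scale(inc_lo); hi <- .icer_scale(inc_hi)
    data.frame(parameter = p$name, low = p$low, high = p$high,
               icer_at_low = lo, icer_at_high = hi,
               status_low = inc_lo$status, status_high = inc_hi$status,
               swing = abs(hi - lo), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[order(-out$swing, out$parameter), ]
  rownames(out) <- NULL
  structure(out, class = c("fn_owsa", "data.frame"),
            base_icer = .icer_scale(base_inc), base_status = base_inc$status)
}

#' @export
print.fn_owsa <- function(x, n = 10, ...) {
  cat(sprintf("one-way sensitivity, base-case ICER %.0f EUR/QALY (%s)\n",
              attr(x, "base_icer"), attr(x, "base_status")))
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more parameters\n")
  invisible(x)
}

#' @export
plot.fn_owsa <- function(x, n = 12, ...) {
  d <- utils::head(x, n)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "base_icer")
  rng <- range(c(d$icer_at_low, d$icer_at_high, base))
  op <- par(mar = c(4, 12, 2, 1)); on.exit(par(op))
  plot(NA, xlim = rng, ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
       xlab = "ICER (EUR/QALY)", ylab = "",
       main = "One-way sensitivity (tornado)")
  axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1, cex.axis = 0.7)
  for (i in seq_len(nrow(d)))
    lines(c(d$icer_at_low[i], d$icer_at_high[i]), c(i, i), lwd = 8,
          col = "steelblue")
  abline(v = base, lty = 2)
  invisible(x)
}

# deterministic per-iteration seed below 2^31
.iter_seed <- function(seed, i) (abs(seed) + 11L * i) %% 2147483629L

#' Probabilistic sensitivity analysis
#'
#' Draws all of the scenario's uncertain parameters jointly and
#' independently from their fitted distributions, one value per parameter
#' per iteration shared between the PP and SP arms, evaluates the full
#' model per draw, and attaches the cost-effectiveness acceptability curve
#' over the scenario's WTP grid.
#'
#' Reproducibility: each iteration re-seeds a substream derived from `seed`
#' and the iteration counter, so results do not depend on parameter
#' evaluation order. The correlated RDI pair (probability of low RDI with /
#' without FN history) is sampled independently and order-restored by
#' swapping when a draw inverts the structural ordering. Relative-risk
#' draws at or above 1 for the prophylaxis effect are clamped just below 1;
#' clamped draws are counted and a warning is issued if they exceed 1% of
#' iterations.
#'
#' @param cfg an `fn_scenario`.
#' @param n iterations (default `cfg$psa_iterations`).
#' @param seed RNG seed (default `cfg$seed`).
#' @return An object of class `fn_psa`: list with `draws` (per-iteration
#'   paired outcomes and parameter values), `ceac`, `n`, `seed`,
#'   `n_clamped`.
#' @export
psa <- function(cfg, n = cfg$psa_iterations, seed = cfg$seed) {
  validate_scenario(cfg)
  params <- uncertain_parameters(cfg)
  if (length(params) == 0)
    stop("psa: scenario declares no uncertain parameters", call. = FALSE)
  lt <- scenario_life_table(cfg)
  nm <- names(params)

  vals <- matrix(NA_real_, n, length(params), dimnames = list(NULL, nm))
  n_clamped <- 0L
  for (i in seq_len(n)) {
    set.seed(.iter_seed(seed, i))
    v <- vapply(params, draw_parameter, numeric(1))
    if (!is.na(v["rr_gcsf"]) && v[["rr_gcsf"]] >= 1) {
      v[["rr_gcsf"]] <- 1 - 1e-9
      n_clamped <- n_clamped + 1L
    }
    if (all(c("p_low_rdi_no_fn", "p_low_rdi_fn") %in% nm) &&
        v[["p_low_rdi_no_fn"]] > v[["p_low_rdi_fn"]])
      v[c("p_low_rdi_no_fn", "p_low_rdi_fn")] <-
        v[c("p_low_rdi_fn", "p_low_rdi_no_fn")]
    vals[i, ] <- v
  }
  if (n_clamped > 0.01 * n)
    warning("psa: ", n_clamped, " of ", n, " draws clamped", call. = FALSE)

  res <- matrix(NA_real_, n, 8, dimnames = list(NULL,
    c("cost_pp", "ly_pp", "qaly_pp", "fn_pp",
      "cost_sp", "ly_sp", "qaly_sp", "fn_sp")))
  for (i in seq_len(n)) {
    cfg2 <- cfg
    for (j in seq_along(nm)) cfg2 <- scenario_set(cfg2, nm[j], vals[i, j])
    pp <- run_strategy(cfg2, "PP", lt)
    sp <- run_strategy(cfg2, "SP", lt)
    res[i, ] <- c(pp$cost, pp$ly, pp$qaly, pp$fn_events,
                  sp$cost, sp$ly, sp$qaly, sp$fn_events)
  }
  draws <- cbind(data.frame(iteration = seq_len(n)), as.data.frame(res),
                 as.data.frame(vals))
  structure(list(draws = draws, ceac = ceac(draws, cfg$wtp_grid),
                 n = n, seed = seed, n_clamped = n_clamped,
                 meta = cfg$meta), class = "fn_psa")
}

#' @export
print.fn_psa <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %d)%s\n", x$n, x$seed,
              if (x$n_clamped) sprintf(", %d clamped draws", x$n_clamped)
              else ""))
  cat(sprintf("mean delta cost %.1f EUR, mean delta QALY %.4f\n",
              mean(x$draws$cost_pp - x$draws$cost_sp),
              mean(x$draws$qaly_pp - x$draws$qaly_sp)))
  cat("CEAC (P PP cost-effective):\n")
  print(x$ceac, row.names = FALSE)
  invisible(x)
}

#' @export
summary.fn_psa <- function(object, wtp = 30000, ...) {
  d <- object$draws
  dn <- d$cost_pp - d$cost_sp; dq <- d$qaly_pp - d$qaly_sp
  structure(list(n = object$n, seed = object$seed,
                 delta_cost = c(mean = mean(dn), sd = sd(dn)),
                 delta_qaly = c(mean = mean(dq), sd = sd(dq)),
                 p_ce = mean(wtp * dq > dn), wtp = wtp,
                 ceac = object$ceac), class = "summary.fn_psa")
}

#' @export
print.summary.fn_psa <- function(x, ...) {
  cat(sprintf("PSA summary (%d iterations)\n", x$n))
  cat(sprintf("  delta cost: %.1f (sd %.1f) EUR\n",
              x$delta_cost["mean"], x$delta_cost["sd"]))
  cat(sprintf("  delta QALY: %.4f (sd %.4f)\n",
              x$delta_qaly["mean"], x$delta_qaly["sd"]))
  cat(sprintf("  P(PP cost-effective at %.0f EUR/QALY): %.3f\n",
              x$wtp, x$p_ce))
  invisible(x)
}

#' @export
plot.fn_psa <- function(x, which = c("ceac", "plane"), wtp = 30000, ...) {
  which <- match.arg(which)
  d <- x$draws
  if (which == "ceac") {
    plot(x$ceac$wtp, x$ceac$p_ce, type = "b", pch = 16, ylim = c(0, 1),
         xlab = "Willingness to pay (EUR/QALY)",
         ylab = "P(PP cost-effective)",
         main = "Cost-effectiveness acceptability curve")
    abline(h = c(0.5, 0.95), lty = 3)
  } else {
    dq <- d$qaly_pp - d$qaly_sp; dc <- d$cost_pp - d$cost_sp
    plot(dq, dc, pch = 16, col = "#33669955",
         xlab = "Incremental QALYs (PP - SP)",
         ylab = "Incremental cost (EUR)",
         main = "Cost-effectiveness plane")
    abline(h = 0, v = 0, lty = 2)
    abline(a = 0, b = wtp, col = "red3", lty = 2)
  }
  invisible(x)
}
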