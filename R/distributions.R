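# Uncertain parameters: base value, range, distribution family, fitted
# hyperparameters. Ranges are read as 95% intervals (a documented modelling
# convention, see the vignette): sd = (high - low) / 3.92 for beta moment
# matching; log-sd = (log(high) - log(low)) / 3.92 for lognormal.

#' Describe an uncertain model parameter
#'
#' @param name parameter name (must be settable via [scenario_set()] to be
#'   usable in sensitivity analyses).
#' @param base base-case value.
#' @param low,high range used for the PSA distribution and the OWSA bounds.
#' @param family `"beta"`, `"lognormal"` or `"fixed"`.
#' @return An object of class `fn_uparam`. Hyperparameters are empty until
#'   [fit_distribution()] is called.
#' @export
uncertain_parameter <- function(name, base, low, high,
                                family = c("beta", "lognormal", "fixed")) {
  family <- match.arg(family)
  if (!(low <= base && base <= high))
    stop("uncertain parameter '", name, "': need low <= base <= high",
         call. = FALSE)
  structure(list(name = name, base = base, low = low, high = high,
                 family = family, hyper = NULL), class = "fn_uparam")
}

#' Fit the sampling distribution of an uncertain parameter
#'
#' Beta: moment matching with mean = base and sd = (high - low)/3.92; the
#' range is read as a central 95% interval. Lognormal: log-mean = log(base),
#' log-sd = (log(high) - log(low))/3.92, i.e. the range is a log-symmetric
#' 95% interval around the base value. Fixed: degenerate at base.
#'
#' @param p an `fn_uparam`.
#' @return `p` with `$hyper` populated (`shape1`/`shape2` for beta,
#'   `meanlog`/`sdlog` for lognormal).
#' @export
fit_distribution <- function(p) {
  stopifnot(inherits(p, "fn_uparam"))
  if (p$family == "fixed" || p$high == p$low) {
    p$hyper <- list(value = p$base)
    p$family <- "fixed"
    return(p)
  }
  if (p$family == "beta") {
    m <- p$base
    if (m <= 0 || m >= 1)
      stop("beta fit for '", p$name, "': base must lie in (0, 1)",
           call. = FALSE)
    if (p$low < 0 || p$high > 1)
      stop("beta fit for '", p$name, "': range must lie within [0, 1]",
           call. = FALSE)
    s <- (p$high - p$low) / 3.92
    nu <- m * (1 - m) / s^2 - 1
    if (nu <= 0)
      stop("beta fit for '", p$name, "': range too wide for mean ", m,
           call. = FALSE)
    p$hyper <- list(shape1 = m * nu, shape2 = (1 - m) * nu)
  } else {
    if (p$low <= 0 || p$base <= 0)
      stop("lognormal fit for '", p$name, "': support must be positive",
           call. = FALSE)
    p$hyper <- list(meanlog = log(p$base),
                    sdlog = (log(p$high) - log(p$low)) / 3.92)
  }
  p
}

#' Draw from a fitted uncertain parameter
#'
#' @param p a fitted `fn_uparam` (see [fit_distribution()]).
#' @param n number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_parameter <- function(p, n = 1) {
  if (is.null(p$hyper)) p <- fit_distribution(p)
  switch(p$family,
    fixed = rep(p$hyper$value, n),
    beta = rbeta(n, p$hyper$shape1, p$hyper$shape2),
    lognormal = rlnorm(n, p$hyper$meanlog, p$hyper$sdlog))
}

#' @export
print.fn_uparam <- function(x, ...) {
  cat(sprintf("%s: %g (%g-%g), %s%s\n", x$name, x$base, x$low, x$high,
              x$family, if (is.null(x$hyper)) " [unfitted]" else ""))
  invisible(x)
}

# scenario psa/owsa descriptor record -> fn_uparam, base looked up in cfg
.uparam_from_record <- function(cfg, rec) {
  uncertain_parameter(rec$name, scenario_get(cfg, rec$name),
                      rec$low, rec$high, rec$family)
}

#' Uncertain parameters of a scenario
#'
#' Materialises the scenario's PSA descriptor records (and, if
#' `include_owsa_extras`, the OWSA-only records: costs, length of stay,
#' weight, discount rate) as fitted [uncertain_parameter()] objects with
#' base values read from the configuration.
#'
#' @param cfg an `fn_scenario`.
#' @param include_owsa_extras also return the OWSA-only ranges.
#' @return Named list of fitted `fn_uparam` objects.
#' @export
uncertain_parameters <- function(cfg, include_owsa_extras = FALSE) {
  recs <- cfg$psa
  if (include_owsa_extras) recs <- c(recs, cfg$owsa)
  ps <- lapply(recs, function(r) fit_distribution(.uparam_from_record(cfg, r)))
  setNames(ps, vapply(ps, `[[`, "", "name"))
}
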