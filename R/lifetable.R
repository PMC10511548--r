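# Background mortality: age- and sex-specific annual death probabilities qx.
#
# Two sources: delimited text files (header age,sex,qx; 1-year bins from age
# 0; sex coded female/male) and a synthetic Gompertz generator used by the
# bundled fixtures, qx(age) = 1 - exp(-a * exp(b * age)) with a per-sex
# scaling of the baseline hazard a. The generator stands in for national
# life tables, which are not redistributed here.

#' Synthetic Gompertz life-table specification
#'
#' @param a baseline annual hazard at age 0 (males).
#' @param b log-hazard slope per year of age.
#' @param female_scale multiplier on `a` for females (< 1 means lower
#'   female mortality).
#' @param terminal_age age at which `qx` is forced to 1.
#' @return An object of class `fn_lt_spec`.
#' @export
gompertz_spec <- function(a, b, female_scale = 1, terminal_age = 110) {
  stopifnot(a > 0, b > 0, female_scale > 0, terminal_age > 0)
  structure(list(type = "gompertz", a = a, b = b,
                 female_scale = female_scale, terminal_age = terminal_age),
            class = "fn_lt_spec")
}

#' Generate a life table from a Gompertz specification
#'
#' `qx(age) = 1 - exp(-a exp(b age))` per sex, ages 0 to `terminal_age`,
#' with `qx(terminal_age) = 1`.
#'
#' @param spec an [gompertz_spec()] (or a plain list with the same fields,
#'   as stored in scenario files).
#' @return An object of class `fn_life_table`.
#' @export
generate_life_table <- function(spec) {
  stopifnot(spec$a > 0, spec$b > 0)
  terminal <- spec$terminal_age %||% 110
  ages <- 0:terminal
  qx_m <- 1 - exp(-spec$a * exp(spec$b * ages))
  qx_f <- 1 - exp(-spec$a * (spec$female_scale %||% 1) * exp(spec$b * ages))
  qx <- cbind(female = pmin(1, qx_f), male = pmin(1, qx_m))
  qx[length(ages), ] <- 1
  structure(list(ages = ages, qx = qx, terminal_age = terminal),
            class = "fn_life_table")
}

#' Read / write a life table as delimited text
#'
#' Format: CSV with header `age,sex,qx`, 1-year age bins starting at age 0,
#' `sex` in \{`female`, `male`\}, `qx` the annual death probability. The
#' final age must carry `qx = 1` (terminal age).
#'
#' @param path file path.
#' @return `read_life_table`: an `fn_life_table`. `write_life_table`:
#'   `path`, invisibly.
#' @export
read_life_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "sex", "qx")
  if (!all(need %in% names(d)))
    stop("life table must have columns age,sex,qx", call. = FALSE)
  if (any(d$qx < 0 | d$qx > 1))
    stop("life table qx outside [0, 1]", call. = FALSE)
  ages <- sort(unique(d$age))
  if (ages[1] != 0 || any(diff(ages) != 1))
    stop("life table ages must be contiguous 1-year bins from 0", call. = FALSE)
  qx <- sapply(c("female", "male"), function(s) {
    sub <- d[d$sex == s, ]
    if (nrow(sub) != length(ages))
      stop("life table must cover every age for sex '", s, "'", call. = FALSE)
    sub$qx[order(sub$age)]
  })
  terminal <- max(ages)
  if (any(qx[length(ages), ] != 1))
    stop("life table must end with qx = 1 at the terminal age", call. = FALSE)
  structure(list(ages = ages, qx = qx, terminal_age = terminal),
            class = "fn_life_table")
}

#' @rdname read_life_table
#' @param lt an `fn_life_table`.
#' @export
write_life_table <- function(lt, path) {
  d <- as.data.frame(lt)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.fn_life_table <- function(x, ...) {
  data.frame(age = rep(x$ages, 2),
             sex = rep(c("female", "male"), each = length(x$ages)),
             qx = c(x$qx[, "female"], x$qx[, "male"]))
}

#' Annual death probability lookup
#'
#' Ages beyond the terminal age are absorbed at `qx = 1`.
#'
#' @param lt an `fn_life_table`.
#' @param age age in years (vectorised; fractional ages are floored).
#' @param sex `"female"` or `"male"`.
#' @return Annual death probabilities.
#' @export
lt_qx <- function(lt, age, sex) {
  a <- pmin(floor(age), lt$terminal_age)
  lt$qx[a + 1L, sex]
}

#' Curtate life expectancy from a life table
#'
#' `sum_k prod_{j<=k} (1 - qx(age + j - 1))`: expected whole years of life
#' remaining, the discrete-survival convention used by the cohort engine's
#' post-chemotherapy phase.
#'
#' @param lt an `fn_life_table`.
#' @param age starting age (integer years).
#' @param sex `"female"` or `"male"`.
#' @return Expected remaining whole years.
#' @export
life_expectancy <- function(lt, age, sex) {
  k <- lt$terminal_age - floor(age) + 1
  q <- lt_qx(lt, floor(age) + seq_len(k) - 1, sex)
  sum(cumprod(1 - q))
}

#' @export
print.fn_life_table <- function(x, ...) {
  cat(sprintf("life table: ages 0-%d, e0 female %.1f / male %.1f years\n",
              x$terminal_age, life_expectancy(x, 0, "female"),
              life_expectancy(x, 0, "male")))
  invisible(x)
}

# resolve a scenario's life-table reference (generator spec or file path)
scenario_life_table <- function(cfg) {
  ref <- cfg$life_table
  switch(ref$type,
    gompertz = generate_life_table(ref),
    file = read_life_table(ref$path),
    stop("unknown life_table type: ", ref$type, call. = FALSE))
}
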