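# Table rendering and artifact writers.

.fmt_eur <- function(x) paste0("€", formatC(round(x), format = "d",
                                                 big.mark = ","))

.fmt_icer <- function(value, status) {
  if (status == "icer" && !is.na(value)) .fmt_eur(value)
  else .icer_labels[[status]]
}

#' Base-case results table
#'
#' Mirrors the published column layout: one row per strategy with costs, FN
#' events avoided (vs no prophylaxis), LYs, QALYs, and the three ICERs on
#' the PP row (dominance rendered as "Dominates" when `formatted`).
#'
#' @param x an `fn_cea` from [run_cea()].
#' @param formatted return display strings (currency symbols, thousands
#'   separators)? Raw numbers otherwise (machine output).
#' @return A data frame with rows PP and SP.
#' @export
base_case_table <- function(x, formatted = FALSE) {
  stopifnot(inherits(x, "fn_cea"))
  inc <- x$incremental
  num <- data.frame(
    strategy = c("PP", "SP"),
    cost = c(x$pp$cost, x$sp$cost),
    fn_events_avoided = c(x$pp$fn_avoided, x$sp$fn_avoided),
    ly = c(x$pp$ly, x$sp$ly),
    qaly = c(x$pp$qaly, x$sp$qaly),
    icer_fn = c(inc$icer_fn, NA), icer_ly = c(inc$icer_ly, NA),
    icer_qaly = c(inc$icer_qaly, NA), stringsAsFactors = FALSE)
  if (!formatted) return(num)
  data.frame(
    strategy = c("Primary prophylaxis", "Secondary prophylaxis"),
    cost = .fmt_eur(num$cost),
    fn_events_avoided = sprintf("%.3f", num$fn_events_avoided),
    ly = sprintf("%.3f", num$ly), qaly = sprintf("%.3f", num$qaly),
    icer_fn = c(.fmt_icer(inc$icer_fn, inc$status), "Reference"),
    icer_ly = c(.fmt_icer(inc$icer_ly, inc$status), "Reference"),
    icer_qaly = c(.fmt_icer(inc$icer_qaly, inc$status), "Reference"),
    stringsAsFactors = FALSE)
}

#' @export
print.fn_cea <- function(x, ...) {
  id <- x$meta$id %||% "scenario"
  cat("Base-case cost-effectiveness:", id, "\n")
  print(base_case_table(x, formatted = TRUE), row.names = FALSE)
  inc <- x$incremental
  cat(sprintf(
    "incremental (PP - SP): cost %.1f EUR, %.4f FN avoided, %.4f LY, %.4f QALY [%s]\n",
    inc$delta_cost, inc$delta_fn_avoided, inc$delta_ly, inc$delta_qaly,
    inc$status))
  invisible(x)
}

#' @export
summary.fn_cea <- function(object, wtp = 30000, ...) {
  inc <- object$incremental
  pref <- nmb(object$pp, wtp) > nmb(object$sp, wtp)
  cat(sprintf("PP %s SP at a WTP of %s/QALY (status: %s)\n",
              if (pref) "is preferred to" else "is not preferred to",
              .fmt_eur(wtp), inc$status))
  invisible(object)
}

#' Run manifest
#'
#' Provenance record for a written artifact: package version, command,
#' scenario id, seed, timestamp and md5 digests of the input files (digests
#' are stable for identical inputs; the timestamp is informational only).
#'
#' @param command short command label (e.g. `"psa"`).
#' @param scenario scenario id or path.
#' @param seed seed used, or NA for deterministic runs.
#' @param inputs character vector of input file paths to digest.
#' @return Named list of class `fn_manifest`.
#' @export
run_manifest <- function(command, scenario, seed = NA_integer_,
                         inputs = character()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  structure(list(command = command, scenario = scenario, seed = seed,
                 version = as.character(packageVersion("fncea")),
                 timestamp = format(Sys.time(), tz = "UTC",
                                    "%Y-%m-%dT%H:%M:%SZ"),
                 input_digests = digests), class = "fn_manifest")
}

.write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write analysis artifacts as delimited text
#'
#' Each writer emits the machine-readable table (raw floats, CSV) plus a
#' `<name>.manifest.json` provenance record next to it. Reruns with
#' identical inputs produce byte-identical tables.
#'
#' @param x the object to write (`fn_cea`, `fn_owsa` or `fn_psa`).
#' @param path output CSV path.
#' @param scenario scenario id for the manifest.
#' @param inputs input files to digest into the manifest.
#' @return `path`, invisibly.
#' @export
write_base_case <- function(x, path, scenario = x$meta$id %||% "",
                            inputs = character()) {
  write.csv(base_case_table(x), path, row.names = FALSE, quote = FALSE)
  .write_manifest(run_manifest("run", scenario, NA, inputs),
                  paste0(path, ".manifest.json"))
  invisible(path)
}

#' @rdname write_base_case
#' @export
write_owsa <- function(x, path, scenario = "", inputs = character()) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  .write_manifest(run_manifest("owsa", scenario, NA, inputs),
                  paste0(path, ".manifest.json"))
  invisible(path)
}

#' @rdname write_owsa
#' @export
write_psa <- function(x, path, scenario = x$meta$id %||% "",
                      inputs = character()) {
  write.csv(x$draws, path, row.names = FALSE, quote = FALSE)
  write.csv(x$ceac, sub("\\.csv$", "_ceac.csv", path), row.names = FALSE,
            quote = FALSE)
  .write_manifest(run_manifest("psa", scenario, x$seed, inputs),
                  paste0(path, ".manifest.json"))
  invisible(path)
}
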