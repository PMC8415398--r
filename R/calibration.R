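#' Calibration anchor for the expenditure escalation rate
#'
#' The escalation rate is identified from a single anchor: the annual
#' balance of a revenue-side scenario (whose revenue does not depend on
#' `esc`) at one anchor year. The default anchor is the high
#' individual-payment-rate scenario (`r_ind = 0.001`) with a 2030 annual
#' balance of +381.7 million yuan.
#'
#' @param scenario an [ltci_scenario()] whose overrides touch only
#'   revenue-side levers.
#' @param year anchor calendar year.
#' @param balance anchored annual balance in that year (yuan).
#' @return a `ltci_calibration_spec` list.
#' @export
calibration_spec <- function(scenario = ltci_scenario("r_ind_0.0010", r_ind = 0.001),
                             year = 2030, balance = 381.7e6) {
  stopifnot(inherits(scenario, "ltci_scenario"))
  exp_levers <- intersect(names(scenario$overrides), c("reimb", "d_sev"))
  if (length(exp_levers) > 0) {
    stop("anchor scenario must not override expenditure levers (",
      paste(exp_levers, collapse = ", "), "): its revenue side must be ",
      "independent of the escalation rate",
      call. = FALSE
    )
  }
  structure(list(scenario = scenario, year = year, balance = balance),
    class = "ltci_calibration_spec"
  )
}

#' Calibrate the expenditure escalation rate in closed form
#'
#' Under the stock-flow model, anchor-year expenditure factorises as
#' `E(y) = E0(y) * (1 + esc)^(y - year_start)` where `E0` is the
#' expenditure with zero escalation. Setting the anchor scenario's
#' required expenditure `E* = rev_total(anchor) - balance(anchor)` gives
#' the exact closed form
#' `esc = (E* / E0(anchor_year))^(1 / (anchor_year - year_start)) - 1`.
#' Re-simulating with the returned rate reproduces the anchor balance to
#' floating-point precision.
#'
#' @param params an [ltci_params()] object (its `esc` value is ignored).
#' @param spec a [calibration_spec()].
#' @return the calibrated escalation rate (fraction per year).
#' @examples
#' esc <- calibrate_escalation(ltci_params())
#' round(esc, 4)
#' @export
calibrate_escalation <- function(params, spec = calibration_spec()) {
  stopifnot(inherits(params, "ltci_params"), inherits(spec, "ltci_calibration_spec"))
  if (spec$year <= params$year_start || spec$year > params$year_end) {
    stop("anchor year must lie in (year_start, year_end]", call. = FALSE)
  }
  anchored <- apply_scenario(params, spec$scenario)
  state <- project_state(anchored, spec$year)
  rev <- revenue_flows(state, anchored)$rev_total
  e_star <- rev - spec$balance
  if (e_star <= 0) {
    stop(
      "anchor infeasible: required expenditure ", format(e_star),
      " yuan is not positive (anchor balance ", format(spec$balance),
      " exceeds anchor-year revenue ", format(rev), ")",
      call. = FALSE
    )
  }
  p0 <- unclass(anchored)
  p0$esc <- 0
  e0 <- expenditure_flow(state, do.call(ltci_params, p0))
  (e_star / e0)^(1 / (spec$year - params$year_start)) - 1
}

#' Signed percent error of a simulated value against an actual value
#'
#' @param actual observed (non-zero) value.
#' @param simulated model value.
#' @return `100 * (simulated - actual) / actual`. Vectorized.
#' @examples
#' percent_error(182.15, 180.7244)
#' @export
percent_error <- function(actual, simulated) {
  if (any(actual == 0)) stop("actual must be non-zero", call. = FALSE)
  100 * (simulated - actual) / actual
}

#' Per-row error rates of a historical actual/simulated table
#'
#' Recomputes each row's published error rate from its actual and
#' simulated values. Source yearbook validation tables do not always use
#' one orientation for the relative error: the packaged historical table
#' records, per series, whether the published rate was
#' `(simulated - actual) / actual` (`"sim_minus_actual"`) or
#' `(actual - simulated) / actual` (`"actual_minus_sim"`). The default is
#' the former.
#'
#' @param pairs a data frame with columns `actual`, `simulated`, and
#'   optionally `orientation` (one of the two strings above, per row).
#' @return `pairs` with an added `error_pct` column (percent).
#' @seealso [ltci_table2()], [mean_error()]
#' @export
historical_errors <- function(pairs) {
  stopifnot(all(c("actual", "simulated") %in% names(pairs)))
  err <- percent_error(pairs$actual, pairs$simulated)
  if ("orientation" %in% names(pairs)) {
    ok <- pairs$orientation %in% c("sim_minus_actual", "actual_minus_sim")
    if (!all(ok)) {
      stop("unknown orientation value(s): ",
        paste(unique(pairs$orientation[!ok]), collapse = ", "),
        call. = FALSE
      )
    }
    flip <- pairs$orientation == "actual_minus_sim"
    err[flip] <- -err[flip]
  }
  pairs$error_pct <- err
  pairs
}

#' Mean signed percent error over historical actual/simulated pairs
#'
#' The headline historical-validation statistic: the arithmetic mean of
#' the signed per-row error rates as published (see [historical_errors()]
#' for the orientation convention). Signed errors cancel; the mean
#' absolute error is also returned for reference via
#' [historical_validation()].
#'
#' @param pairs a non-empty data frame with columns `actual`, `simulated`,
#'   and optionally `orientation`.
#' @return mean signed percent error (scalar, percent).
#' @examples
#' mean_error(ltci_table2())
#' @export
mean_error <- function(pairs) {
  if (NROW(pairs) == 0) stop("pairs must be non-empty", call. = FALSE)
  mean(historical_errors(pairs)$error_pct)
}

#' Historical validation summary on the packaged yearbook table
#'
#' Recomputes every per-row error rate of the packaged historical
#' actual/simulated table and summarises the fit.
#'
#' @param pairs historical pairs; defaults to [ltci_table2()].
#' @return a list with `errors` (tibble incl. `error_pct`),
#'   `mean_signed_pct`, and `mean_absolute_pct`.
#' @export
historical_validation <- function(pairs = ltci_table2()) {
  errs <- historical_errors(pairs)
  list(
    errors = errs,
    mean_signed_pct = mean(errs$error_pct),
    mean_absolute_pct = mean(abs(errs$error_pct))
  )
}
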