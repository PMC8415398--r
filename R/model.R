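#' Compound growth over discrete annual steps
#'
#' @param x0 positive starting quantity.
#' @param rate annual growth rate (fraction per year, may be negative).
#' @param n non-negative whole number of annual steps.
#' @return `x0 * (1 + rate)^n`. Vectorized over `n`.
#' @examples
#' compound_growth(2738800, 0.06, 11)
#' @export
compound_growth <- function(x0, rate, n) {
  stopifnot(is.numeric(x0), is.numeric(rate), is.numeric(n))
  if (any(x0 <= 0)) stop("x0 must be strictly positive", call. = FALSE)
  if (any(n < 0) || any(n != round(n))) {
    stop("n must be a non-negative whole number of steps", call. = FALSE)
  }
  x0 * (1 + rate)^n
}

#' Exogenous drivers at one simulated year
#'
#' Compounds each demographic and economic driver independently from its
#' base-year value: the two insured pools at their own growth rates, and
#' the two contribution bases (disposable income, per-capita GDP) at
#' theirs.
#'
#' @param params an [ltci_params()] object.
#' @param year calendar year within the simulation horizon.
#' @return A one-row [tibble::tibble] with columns `year`, `n_emp`,
#'   `n_res` (persons), `di`, `gdp` (yuan/person/year).
#' @examples
#' project_state(ltci_params(), 2030)
#' @export
project_state <- function(params, year) {
  stopifnot(inherits(params, "ltci_params"))
  if (any(year < params$year_start) || any(year > params$year_end)) {
    stop("year must lie within the simulation horizon ",
      params$year_start, "-", params$year_end,
      call. = FALSE
    )
  }
  n <- year - params$year_start
  tibble::tibble(
    year = year,
    n_emp = compound_growth(params$n_emp0, params$g_emp, n),
    n_res = compound_growth(params$n_res0, params$g_res, n),
    di = compound_growth(params$di0, params$g_di, n),
    gdp = compound_growth(params$gdp0, params$g_gdp, n)
  )
}

#' Annual revenue flows of the LTCI fund
#'
#' Individual premiums are paid by every insured person (both pools) at
#' rate `r_ind` on per-capita disposable income. Enterprise contributions
#' cover the employee pool at rate `r_ent` on per-capita GDP; the
#' government subsidises the resident pool at rate `r_gov` on per-capita
#' GDP.
#'
#' @param state a driver row from [project_state()] (vectorized over rows).
#' @param params an [ltci_params()] object.
#' @return A tibble with columns `year`, `rev_individual`,
#'   `rev_enterprise`, `rev_government`, `rev_total` (yuan/year).
#' @export
revenue_flows <- function(state, params) {
  stopifnot(inherits(params, "ltci_params"))
  rev_ind <- (state$n_emp + state$n_res) * params$r_ind * state$di
  rev_ent <- state$n_emp * params$r_ent * state$gdp
  rev_gov <- state$n_res * params$r_gov * state$gdp
  tibble::tibble(
    year = state$year,
    rev_individual = rev_ind,
    rev_enterprise = rev_ent,
    rev_government = rev_gov,
    rev_total = rev_ind + rev_ent + rev_gov
  )
}

#' Annual expenditure flow of the LTCI fund
#'
#' Benefit-eligible persons are the severely disabled share `d_sev` of all
#' insured; each costs the fund the care-mix-weighted annual cost times
#' the reimbursement ratio, escalated geometrically at `esc` per year from
#' the base year:
#' `(n_emp + n_res) * d_sev * (p_inst*c_inst + p_home*c_home) * reimb *
#'  (1 + esc)^(year - year_start)`.
#'
#' @inheritParams revenue_flows
#' @return numeric vector of expenditures (yuan/year), one per state row.
#' @export
expenditure_flow <- function(state, params) {
  stopifnot(inherits(params, "ltci_params"))
  (state$n_emp + state$n_res) * params$d_sev *
    net_cost_per_beneficiary(params) *
    (1 + params$esc)^(state$year - params$year_start)
}

#' Simulate the LTCI fund over the full horizon
#'
#' Deterministic annual stock-flow simulation: for each year from
#' `year_start` to `year_end`, drivers are compounded, revenue and
#' expenditure flows computed, and the annual balance (revenue minus
#' expenditure) accumulated into the fund stock (cumulative balance,
#' ignoring investment income).
#'
#' @param params an [ltci_params()] object.
#' @return An `ltci_trajectory`: a tibble with one row per year and
#'   columns `year`, `rev_individual`, `rev_enterprise`, `rev_government`,
#'   `rev_total`, `expenditure`, `balance_annual`, `balance_cumulative`,
#'   all monetary columns in yuan/year (cumulative balance in yuan).
#' @examples
#' traj <- ltci_simulate(ltci_params())
#' traj[traj$year == 2030, c("rev_total", "expenditure", "balance_annual")]
#' @export
ltci_simulate <- function(params) {
  stopifnot(inherits(params, "ltci_params"))
  years <- seq(params$year_start, params$year_end)
  state <- project_state(params, years)
  out <- revenue_flows(state, params)
  out$expenditure <- expenditure_flow(state, params)
  out$balance_annual <- out$rev_total - out$expenditure
  out$balance_cumulative <- cumsum(out$balance_annual)
  class(out) <- c("ltci_trajectory", class(out))
  attr(out, "params") <- params
  out
}

#' Convert monetary trajectory columns between yuan and millions of yuan
#'
#' @param traj a trajectory tibble from [ltci_simulate()].
#' @param units `"yuan"` (leave unchanged) or `"millions"`.
#' @return the trajectory with monetary columns scaled accordingly.
#' @export
trajectory_in_units <- function(traj, units = c("yuan", "millions")) {
  units <- match.arg(units)
  if (units == "millions") {
    money <- setdiff(names(traj), c("year", "scenario"))
    traj[money] <- lapply(traj[money], function(v) v / 1e6)
  }
  traj
}
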