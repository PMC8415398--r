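#' Policy scenario: a named set of lever overrides
#'
#' A scenario overrides one or more policy levers on top of a base
#' parameter set. Recognised levers:
#' \describe{
#'   \item{`r_ind`}{individual payment rate on disposable income}
#'   \item{`reimb`}{reimbursement ratio of nursing services}
#'   \item{`r_gov_r_ent`}{joint lever setting the government subsidy rate
#'     and the enterprise contribution rate to the same value (the two
#'     move together in all policy batteries)}
#'   \item{`d_sev`}{severe disability rate}
#' }
#'
#' @param name scenario label.
#' @param ... lever overrides, e.g. `r_ind = 0.001`.
#' @return an `ltci_scenario` object.
#' @examples
#' ltci_scenario("r_ind_0.0010", r_ind = 0.001)
#' @export
ltci_scenario <- function(name, ...) {
  overrides <- list(...)
  known <- c("r_ind", "reimb", "r_gov_r_ent", "d_sev")
  bad <- setdiff(names(overrides), known)
  if (length(overrides) > 0 &&
    (is.null(names(overrides)) || any(names(overrides) == ""))) {
    stop("lever overrides must be named", call. = FALSE)
  }
  if (length(bad) > 0) {
    stop("unknown lever(s): ", paste(bad, collapse = ", "),
      "; recognised levers: ", paste(known, collapse = ", "),
      call. = FALSE
    )
  }
  structure(list(name = name, overrides = overrides),
    class = "ltci_scenario"
  )
}

#' @export
print.ltci_scenario <- function(x, ...) {
  ov <- if (length(x$overrides) == 0) {
    "baseline (no overrides)"
  } else {
    paste(names(x$overrides), unlist(x$overrides), sep = " = ", collapse = ", ")
  }
  cat("<ltci_scenario> ", x$name, ": ", ov, "\n", sep = "")
  invisible(x)
}

# documented ranges explored by the policy batteries; values outside
# are accepted but flagged as extrapolation by load_config()
lever_ranges <- function() {
  list(
    r_ind = c(0.0006, 0.001),
    reimb = c(0.5, 0.9),
    r_gov_r_ent = c(0.0004, 0.0007),
    d_sev = c(0.003, 0.005)
  )
}

#' Apply a scenario's lever overrides to a parameter set
#'
#' Returns a copy of `base` with the overrides applied; `base` itself is
#' never modified. The joint `r_gov_r_ent` lever sets both `r_gov` and
#' `r_ent`.
#'
#' @param base an [ltci_params()] object.
#' @param scenario an [ltci_scenario()] object.
#' @return a new, validated `ltci_params` object.
#' @export
apply_scenario <- function(base, scenario) {
  stopifnot(inherits(base, "ltci_params"), inherits(scenario, "ltci_scenario"))
  p <- unclass(base)
  for (lever in names(scenario$overrides)) {
    v <- scenario$overrides[[lever]]
    if (lever == "r_gov_r_ent") {
      p$r_gov <- v
      p$r_ent <- v
    } else {
      p[[lever]] <- v
    }
  }
  do.call(ltci_params, p)
}

#' Built-in policy scenario batteries
#'
#' The four standard batteries varying one lever each across its
#' documented policy range:
#' * `individual_rate`: `r_ind` in 0.06%, 0.08%, 0.1% of disposable income
#' * `reimbursement`: `reimb` in 50%, 60%, 70%, 80%, 90%
#' * `government_enterprise`: joint `r_gov`/`r_ent` in 0.04%-0.07% of GDP
#' * `disability_rate`: `d_sev` in 0.3%, 0.4%, 0.5%
#'
#' Within each battery the first scenario keeps the lever at its default
#' value, so it doubles as the within-battery reference.
#'
#' @return a named list of four batteries, each a list of
#'   [ltci_scenario()] objects.
#' @examples
#' names(default_batteries())
#' @export
default_batteries <- function() {
  mk <- function(lever, values) {
    lapply(values, function(v) {
      args <- list(name = sprintf("%s_%.4g", lever, v))
      args[[lever]] <- v
      do.call(ltci_scenario, args)
    })
  }
  list(
    individual_rate = mk("r_ind", c(0.0006, 0.0008, 0.001)),
    reimbursement = mk("reimb", c(0.5, 0.6, 0.7, 0.8, 0.9)),
    government_enterprise = mk("r_gov_r_ent", c(0.0004, 0.0005, 0.0006, 0.0007)),
    disability_rate = mk("d_sev", c(0.003, 0.004, 0.005))
  )
}

#' Run a battery of scenarios
#'
#' Simulates each scenario on top of the base parameters, preserving
#' order. The base parameter object is never mutated.
#'
#' @param base an [ltci_params()] object.
#' @param battery a non-empty list of [ltci_scenario()] objects.
#' @return a named list of `ltci_result` objects, each with fields
#'   `name`, `params`, `trajectory`, and `deficit_year_annual` (first year
#'   of negative annual balance, or `NA` if none).
#' @examples
#' res <- run_battery(ltci_params(), default_batteries()$individual_rate)
#' sapply(res, function(r) r$deficit_year_annual)
#' @export
run_battery <- function(base, battery) {
  stopifnot(inherits(base, "ltci_params"))
  if (length(battery) == 0) stop("battery must be non-empty", call. = FALSE)
  res <- lapply(battery, function(s) {
    stopifnot(inherits(s, "ltci_scenario"))
    traj <- ltci_simulate(apply_scenario(base, s))
    structure(
      list(
        name = s$name, params = attr(traj, "params"), trajectory = traj,
        deficit_year_annual = deficit_year(traj, "annual")
      ),
      class = "ltci_result"
    )
  })
  names(res) <- vapply(battery, function(s) s$name, character(1))
  res
}

#' @export
print.ltci_result <- function(x, ...) {
  dy <- if (is.na(x$deficit_year_annual)) "none" else x$deficit_year_annual
  last <- x$trajectory[nrow(x$trajectory), ]
  cat("<ltci_result> ", x$name, ": final-year balance ",
    sprintf("%.2fM yuan", last$balance_annual / 1e6),
    ", annual deficit from ", dy, "\n",
    sep = ""
  )
  invisible(x)
}

result_field <- function(r, year, field) {
  traj <- if (inherits(r, "ltci_result")) r$trajectory else r
  fields <- c("rev_total", "expenditure", "balance_annual")
  if (!field %in% fields) {
    stop("field must be one of: ", paste(fields, collapse = ", "), call. = FALSE)
  }
  i <- match(year, traj$year)
  if (is.na(i)) stop("year ", year, " outside the simulated horizon", call. = FALSE)
  traj[[field]][i]
}

#' Cross-scenario delta of a flow in a given year
#'
#' @param a,b scenario results from [run_battery()] (or trajectories).
#' @param year calendar year covered by both trajectories.
#' @param field one of `"rev_total"`, `"expenditure"`, `"balance_annual"`.
#' @return `field(b, year) - field(a, year)` in yuan/year.
#' @examples
#' res <- run_battery(ltci_params(), default_batteries()$individual_rate)
#' compare_scenarios(res[[1]], res[[3]], 2030, "rev_total") / 1e6 # M yuan
#' @export
compare_scenarios <- function(a, b, year, field = "balance_annual") {
  result_field(b, year, field) - result_field(a, year, field)
}

#' First deficit year of a trajectory
#'
#' @param traj an `ltci_trajectory` from [ltci_simulate()].
#' @param mode `"annual"` (first year with negative annual balance; the
#'   convention used for deficit statements) or `"cumulative"` (first year
#'   the fund stock goes negative).
#' @return the calendar year, or `NA` if the balance never turns negative
#'   within the horizon.
#' @export
deficit_year <- function(traj, mode = c("annual", "cumulative")) {
  mode <- match.arg(mode)
  bal <- if (mode == "annual") traj$balance_annual else traj$balance_cumulative
  i <- which(bal < 0)
  if (length(i) == 0) NA_integer_ else as.integer(traj$year[min(i)])
}

#' Proportional-bump intervention comparison
#'
#' Raises one lever by a given fraction (default 10%) with everything else
#' unchanged, and reports the per-year percent change of the annual
#' balance. The percent base is `|balance_base|`, so the sign of the
#' output reflects the direction of the effect rather than the sign of the
#' baseline balance; years with a zero baseline balance are flagged
#' (`undefined = TRUE`) and carry `NA` instead of an infinity.
#'
#' @param base an [ltci_params()] object.
#' @param lever one of `"r_ind"`, `"reimb"`, `"r_gov_r_ent"`, `"d_sev"`.
#' @param bump proportional increase of the lever (must exceed -1).
#' @return a list with `series` (tibble: `year`, `pct_change`,
#'   `undefined`) and `delta_final` (absolute change of the final-year
#'   annual balance, yuan).
#' @examples
#' bump_analysis(ltci_params(), "r_ind")$delta_final / 1e6
#' @export
bump_analysis <- function(base, lever, bump = 0.10) {
  stopifnot(inherits(base, "ltci_params"))
  if (bump <= -1) stop("bump must be > -1", call. = FALSE)
  current <- switch(lever,
    r_ind = base$r_ind,
    reimb = base$reimb,
    r_gov_r_ent = base$r_gov,
    d_sev = base$d_sev,
    stop("unknown lever: ", lever, call. = FALSE)
  )
  args <- list(name = sprintf("%s_bumped", lever))
  args[[lever]] <- current * (1 + bump)
  bumped <- apply_scenario(base, do.call(ltci_scenario, args))
  t0 <- ltci_simulate(base)
  t1 <- ltci_simulate(bumped)
  zero <- t0$balance_annual == 0
  pct <- ifelse(zero, NA_real_,
    100 * (t1$balance_annual - t0$balance_annual) / abs(t0$balance_annual)
  )
  list(
    series = tibble::tibble(year = t0$year, pct_change = pct, undefined = zero),
    delta_final = t1$balance_annual[nrow(t1)] - t0$balance_annual[nrow(t0)]
  )
}
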