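#' Generate a synthetic yearbook-like annual series
#'
#' Statistical yearbook quantities (insured pools, income, GDP per head)
#' are positive and grow roughly geometrically; deviations from trend are
#' small and multiplicative. The generator therefore draws
#' `value(t) = x0 * (1 + g)^t * exp(eps_t)` with
#' `eps_t ~ Normal(0, sigma^2)` i.i.d., where `t = 0, 1, ...` indexes the
#' years. With `sigma = 0` the series is the exact compound-growth path.
#'
#' @param x0 positive base-year value.
#' @param g annual growth rate (fraction per year).
#' @param sigma standard deviation of the log-scale noise (>= 0); the
#'   default 0.02 produces relative deviations of the order of 1-2%,
#'   comparable to typical yearbook-vs-model validation errors.
#' @param years vector of calendar years (first element is the base year).
#' @param seed RNG seed; the session RNG is left untouched.
#' @return a tibble with columns `year`, `value`, and attributes
#'   `x0`, `g`, `sigma`, `seed`.
#' @examples
#' generate_yearbook_series(182.15, 0.06, years = 2012:2018, seed = 1)
#' @export
generate_yearbook_series <- function(x0, g, sigma = 0.02,
                                     years = 2019:2030, seed = 2019) {
  stopifnot(is.numeric(x0), length(x0) == 1, is.numeric(g), length(g) == 1)
  if (x0 <= 0) stop("x0 must be strictly positive", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  t <- seq_along(years) - 1
  eps <- if (sigma == 0) {
    rep(0, length(years))
  } else {
    withr::with_seed(seed, stats::rnorm(length(years), 0, sigma))
  }
  out <- tibble::tibble(year = years, value = x0 * (1 + g)^t * exp(eps))
  attr(out, "x0") <- x0
  attr(out, "g") <- g
  attr(out, "sigma") <- sigma
  attr(out, "seed") <- seed
  out
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "ltcisim")
  if (path == "") stop("packaged fixture not found: ", file, call. = FALSE)
  path
}

#' Packaged base-year parameter table
#'
#' The yearbook/survey parameter table shipped with the package, in its
#' source units (populations in units of 10,000 persons, rates in
#' percent, costs and bases in yuan).
#'
#' @return a tibble with columns `parameter`, `value`, `unit`, `source`.
#' @seealso [params_from_table()] for conversion to model units.
#' @export
ltci_table1 <- function() {
  tibble::as_tibble(utils::read.csv(extdata("table1_parameters.csv"),
    stringsAsFactors = FALSE
  ))
}

#' Build model parameters from the packaged parameter table
#'
#' Converts the source-unit parameter table (10,000-person population
#' counts, percent rates) into an [ltci_params()] object in model units
#' (persons, fractions). The escalation rate and horizon are not part of
#' the source table and are taken from their [ltci_params()] defaults
#' unless overridden via `...`.
#'
#' @param table a parameter table as returned by [ltci_table1()].
#' @param ... overrides passed on to [ltci_params()] (e.g. `esc = 0.12`).
#' @return an `ltci_params` object.
#' @export
params_from_table <- function(table = ltci_table1(), ...) {
  val <- function(key) {
    i <- match(key, table$parameter)
    if (is.na(i)) stop("parameter table lacks entry '", key, "'", call. = FALSE)
    table$value[i]
  }
  args <- list(
    n_emp0 = val("insured_urban_employees") * 1e4,
    n_res0 = val("insured_urban_rural_residents") * 1e4,
    di0 = val("per_capita_disposable_income"),
    gdp0 = val("per_capita_gdp"),
    g_emp = val("growth_insured_urban_employees") / 100,
    g_res = val("growth_insured_urban_rural_residents") / 100,
    g_di = val("growth_per_capita_disposable_income") / 100,
    g_gdp = val("growth_per_capita_gdp") / 100,
    r_ind = val("individual_payment_rate") / 100,
    r_ent = val("enterprise_contribution_rate") / 100,
    r_gov = val("government_subsidy_rate") / 100,
    d_sev = val("severe_disability_rate") / 100,
    p_inst = val("share_institutional_care") / 100,
    p_home = val("share_home_care") / 100,
    c_inst = val("cost_institutional_care"),
    c_home = val("cost_home_care"),
    reimb = val("reimbursement_ratio") / 100
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(ltci_params, args)
}

#' Packaged historical actual-vs-simulated validation table
#'
#' Seven years (2012-2018) of two yearbook series — medical-insured urban
#' employees (10,000 persons) and per-capita disposable income of urban
#' residents (yuan) — paired with the reference model values they were
#' validated against. The `orientation` column records, per series, which
#' way round the source published its relative error rate (see
#' [historical_errors()]).
#'
#' @return a tibble with columns `year`, `series`, `actual`, `simulated`,
#'   `orientation`.
#' @examples
#' mean_error(ltci_table2())
#' @export
ltci_table2 <- function() {
  tibble::as_tibble(utils::read.csv(extdata("table2_historical.csv"),
    stringsAsFactors = FALSE
  ))
}

#' Packaged fixtures in one call
#'
#' @return a list with `params` (the default [ltci_params()] built from
#'   the packaged parameter table) and `historical` ([ltci_table2()]).
#' @export
table_fixtures <- function() {
  list(params = params_from_table(), historical = ltci_table2())
}
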