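#' Model parameters for the LTCI fund simulator
#'
#' Constructs the full parameter set of the long-term care insurance (LTCI)
#' financing model: base-year pool sizes and economic bases, their annual
#' growth rates, the three contribution rates, the care-demand block
#' (severe disability rate, care mix, unit costs, reimbursement ratio), the
#' expenditure escalation rate, and the simulation horizon. A
#' `ltci_params` object is the single source of truth for one model run.
#'
#' Defaults correspond to the Xiamen 2019 base year: 2,738,800 insured
#' urban employees, 1,480,000 insured urban/rural residents, per-capita
#' disposable income of 55,870 yuan, per-capita GDP of 142,739 yuan.
#' Individuals pay `r_ind` on per-capita disposable income across both
#' pools; enterprises pay `r_ent` on per-capita GDP for the employee pool;
#' government subsidises `r_gov` on per-capita GDP for the resident pool.
#'
#' The default escalation rate `esc` is the value returned by
#' [calibrate_escalation()] at these defaults: per-beneficiary net cost is
#' assumed to grow geometrically at `esc` per year on top of insured-pool
#' growth, capturing cost inflation and prevalence drift jointly.
#'
#' @param n_emp0 insured urban employees at the base year (persons).
#' @param n_res0 insured urban and rural residents at the base year (persons).
#' @param di0 per-capita disposable income of urban residents at the base
#'   year (yuan/person/year); contribution base for individual premiums.
#' @param gdp0 per-capita GDP at the base year (yuan/person/year);
#'   contribution base for enterprise and government payments.
#' @param g_emp,g_res annual growth rate of the employee / resident pool
#'   (fraction per year).
#' @param g_di,g_gdp annual growth rate of disposable income / per-capita
#'   GDP (fraction per year).
#' @param r_ind individual payment rate applied to `di` (fraction).
#' @param r_ent enterprise contribution rate applied to `gdp`, employee
#'   pool (fraction).
#' @param r_gov government subsidy rate applied to `gdp`, resident pool
#'   (fraction).
#' @param d_sev severe disability rate over all insured persons (fraction).
#' @param p_inst,p_home share of beneficiaries choosing institutional /
#'   home care; must sum to 1.
#' @param c_inst,c_home per-capita annual cost of institutional / home care
#'   (yuan/person/year).
#' @param reimb reimbursement ratio: share of eligible care cost paid by
#'   the fund (fraction).
#' @param esc annual expenditure escalation rate beyond insured-population
#'   growth (fraction per year).
#' @param year_start,year_end first and last simulated calendar year
#'   (inclusive).
#'
#' @return An object of class `ltci_params`: a validated named list.
#' @seealso [ltci_simulate()], [calibrate_escalation()]
#' @examples
#' p <- ltci_params()
#' p$n_emp0 + p$n_res0 # total insured at base year
#' ltci_params(r_ind = 0.001) # raised individual payment rate
#' @export
ltci_params <- function(n_emp0 = 2738800, n_res0 = 1480000,
                        di0 = 55870, gdp0 = 142739,
                        g_emp = 0.06, g_res = 0.059,
                        g_di = 0.08, g_gdp = 0.05,
                        r_ind = 0.0006, r_ent = 0.0004, r_gov = 0.0004,
                        d_sev = 0.003, p_inst = 0.03, p_home = 0.97,
                        c_inst = 30000, c_home = 18000, reimb = 0.70,
                        esc = 0.150412473661473,
                        year_start = 2019, year_end = 2030) {
  p <- list(
    n_emp0 = n_emp0, n_res0 = n_res0, di0 = di0, gdp0 = gdp0,
    g_emp = g_emp, g_res = g_res, g_di = g_di, g_gdp = g_gdp,
    r_ind = r_ind, r_ent = r_ent, r_gov = r_gov,
    d_sev = d_sev, p_inst = p_inst, p_home = p_home,
    c_inst = c_inst, c_home = c_home, reimb = reimb,
    esc = esc, year_start = year_start, year_end = year_end
  )
  validate_params(p)
  structure(p, class = "ltci_params")
}

#' Validate an LTCI parameter set
#'
#' Checks the structural invariants of a parameter list: strictly positive
#' populations, costs, and bases; payment and demand fractions in \[0, 1\];
#' growth and escalation rates in (-1, 1); care-mix shares summing to 1;
#' and a non-empty horizon. Called by [ltci_params()]; exported so that
#' externally assembled lists (e.g. from a config file) can be checked.
#'
#' @param p a named list with the fields of [ltci_params()].
#' @return `p`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_params <- function(p) {
  need <- c(
    "n_emp0", "n_res0", "di0", "gdp0", "g_emp", "g_res", "g_di", "g_gdp",
    "r_ind", "r_ent", "r_gov", "d_sev", "p_inst", "p_home",
    "c_inst", "c_home", "reimb", "esc", "year_start", "year_end"
  )
  missing <- setdiff(need, names(p))
  if (length(missing) > 0) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter '", field, "' must be a single finite number",
        call. = FALSE
      )
    }
    v
  }
  for (f in c("n_emp0", "n_res0", "di0", "gdp0", "c_inst", "c_home")) {
    if (num1(f) <= 0) {
      stop("parameter '", f, "' must be strictly positive", call. = FALSE)
    }
  }
  for (f in c("g_emp", "g_res", "g_di", "g_gdp", "esc")) {
    v <- num1(f)
    if (v <= -1 || v >= 1) {
      stop("rate '", f, "' must lie in (-1, 1)", call. = FALSE)
    }
  }
  for (f in c("r_ind", "r_ent", "r_gov", "d_sev", "p_inst", "p_home", "reimb")) {
    v <- num1(f)
    if (v < 0 || v > 1) {
      stop("fraction '", f, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  if (abs(p$p_inst + p$p_home - 1) > 1e-12) {
    stop("care-mix shares p_inst + p_home must sum to 1 (got ",
      format(p$p_inst + p$p_home), ")",
      call. = FALSE
    )
  }
  y0 <- num1("year_start")
  y1 <- num1("year_end")
  if (y0 != round(y0) || y1 != round(y1)) {
    stop("year_start and year_end must be whole calendar years", call. = FALSE)
  }
  if (y1 < y0) stop("year_end must be >= year_start", call. = FALSE)
  invisible(p)
}

#' @export
print.ltci_params <- function(x, ...) {
  cat("<ltci_params> ", x$year_start, "-", x$year_end, "\n", sep = "")
  cat(sprintf(
    "  insured: %s employees + %s residents (growth %.1f%% / %.1f%%)\n",
    format(x$n_emp0, big.mark = ","), format(x$n_res0, big.mark = ","),
    100 * x$g_emp, 100 * x$g_res
  ))
  cat(sprintf(
    "  bases: di %s (+%.0f%%), gdp %s (+%.0f%%) yuan\n",
    format(x$di0, big.mark = ","), 100 * x$g_di,
    format(x$gdp0, big.mark = ","), 100 * x$g_gdp
  ))
  cat(sprintf(
    "  rates: r_ind %.4f%%, r_ent %.4f%%, r_gov %.4f%%\n",
    100 * x$r_ind, 100 * x$r_ent, 100 * x$r_gov
  ))
  cat(sprintf(
    "  demand: d_sev %.2f%%, mix %d/%d, costs %s/%s, reimb %.0f%%, esc %.4f\n",
    100 * x$d_sev, round(100 * x$p_inst), round(100 * x$p_home),
    format(x$c_inst, big.mark = ","), format(x$c_home, big.mark = ","),
    100 * x$reimb, x$esc
  ))
  invisible(x)
}

# net cost per severely disabled beneficiary before escalation (yuan/yr)
net_cost_per_beneficiary <- function(p) {
  (p$p_inst * p$c_inst + p$p_home * p$c_home) * p$reimb
}
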