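# expected values below were frozen from independent closed-form
# spreadsheet-style arithmetic on the base-year figures

test_that("compound growth matches closed-form compounding and rejects bad steps", {
  expect_rel(compound_growth(2738800, 0.06, 11), 5199060.09, tol = 1e-6)
  expect_rel(compound_growth(55870, 0.08, 11), 130268.67, tol = 1e-6)
  expect_identical(compound_growth(148, 0, 7), 148)
  expect_equal(compound_growth(100, -0.5, 2), 25)
  expect_error(compound_growth(100, 0.05, -1), "non-negative")
  expect_error(compound_growth(100, 0.05, 1.5), "whole number")
  expect_error(compound_growth(-5, 0.05, 1), "positive")
})

test_that("projected drivers equal base values at the base year and compound independently", {
  p <- ltci_params()
  s0 <- project_state(p, 2019)
  expect_equal(s0$n_emp, 2738800)
  expect_equal(s0$n_res, 1480000)
  expect_equal(s0$di, 55870)
  expect_equal(s0$gdp, 142739)

  s11 <- project_state(p, 2030)
  expect_rel(s11$n_emp + s11$n_res, 7979600, tol = 0.001)

  frozen <- ltci_params(g_emp = 0, g_res = 0, g_di = 0, g_gdp = 0)
  for (y in c(2019, 2024, 2030)) {
    expect_equal(unlist(project_state(frozen, y)[-1]),
      unlist(project_state(frozen, 2019)[-1]))
  }
  expect_error(project_state(p, 2031), "horizon")
  expect_error(project_state(p, 2018), "horizon")
})

test_that("base-year revenue flows reproduce hand arithmetic from the source figures", {
  p <- ltci_params()
  r <- revenue_flows(project_state(p, 2019), p)
  # 4,218,800 insured x 0.0006 x 55,870 yuan etc.
  expect_rel(r$rev_individual, 141.42e6)
  expect_rel(r$rev_enterprise, 156.37e6)
  expect_rel(r$rev_government, 84.50e6)
  expect_equal(r$rev_total,
    r$rev_individual + r$rev_enterprise + r$rev_government,
    tolerance = 1e-12
  )

  zero <- ltci_params(r_ind = 0, r_ent = 0, r_gov = 0)
  rz <- revenue_flows(project_state(zero, 2025), zero)
  expect_equal(rz$rev_total, 0)
})

test_that("base-year expenditure equals insured x prevalence x net reimbursed cost", {
  p <- ltci_params()
  # net per-beneficiary cost (0.03*30000 + 0.97*18000)*0.7 = 12,852 yuan
  expect_rel(expenditure_flow(project_state(p, 2019), p), 162.66e6)
  p0 <- ltci_params(reimb = 0)
  expect_equal(expenditure_flow(project_state(p0, 2030), p0), 0)
})

test_that("simulation satisfies conservation and horizon invariants", {
  traj <- ltci_simulate(ltci_params())
  expect_equal(nrow(traj), 12)
  expect_equal(traj$year, 2019:2030)
  expect_true(all(diff(traj$year) == 1))
  expect_lt(max(abs(
    traj$rev_total -
      (traj$rev_individual + traj$rev_enterprise + traj$rev_government)
  )), 1)
  expect_lt(max(abs(traj$balance_annual - (traj$rev_total - traj$expenditure))), 1)
  expect_equal(traj$balance_cumulative, cumsum(traj$balance_annual))
})

test_that("all-zero growth and escalation reduce every year to the base year", {
  p <- ltci_params(
    g_emp = 0, g_res = 0, g_di = 0, g_gdp = 0, esc = 0
  )
  traj <- ltci_simulate(p)
  for (col in setdiff(names(traj), c("year", "balance_cumulative"))) {
    expect_equal(traj[[col]], rep(traj[[col]][1], 12))
  }
})

test_that("flows are exactly linear in their rate parameters", {
  base <- ltci_simulate(ltci_params())
  halved_reimb <- ltci_simulate(ltci_params(reimb = 0.35))
  expect_equal(halved_reimb$expenditure, base$expenditure / 2, tolerance = 1e-12)
  doubled_sev <- ltci_simulate(ltci_params(d_sev = 0.006))
  expect_equal(doubled_sev$expenditure, 2 * base$expenditure, tolerance = 1e-12)
  doubled_ind <- ltci_simulate(ltci_params(r_ind = 0.0012))
  expect_equal(doubled_ind$rev_individual, 2 * base$rev_individual,
    tolerance = 1e-12
  )
})

test_that("simulation agrees with an independent year-by-year recurrence", {
  p <- ltci_params()
  traj <- ltci_simulate(p)
  # brute-force oracle: advance each driver one year at a time
  ne <- p$n_emp0
  nr <- p$n_res0
  di <- p$di0
  gdp <- p$gdp0
  cost <- (p$p_inst * p$c_inst + p$p_home * p$c_home) * p$reimb
  for (i in seq_len(12)) {
    rev <- (ne + nr) * p$r_ind * di + ne * p$r_ent * gdp + nr * p$r_gov * gdp
    ex <- (ne + nr) * p$d_sev * cost
    expect_equal(traj$rev_total[i], rev, tolerance = 1e-12)
    expect_equal(traj$expenditure[i], ex, tolerance = 1e-12)
    ne <- ne * (1 + p$g_emp)
    nr <- nr * (1 + p$g_res)
    di <- di * (1 + p$g_di)
    gdp <- gdp * (1 + p$g_gdp)
    cost <- cost * (1 + p$esc)
  }
})

test_that("non-negative growth implies non-decreasing revenue and expenditure", {
  traj <- ltci_simulate(ltci_params())
  expect_true(all(diff(traj$rev_total) >= 0))
  expect_true(all(diff(traj$expenditure) >= 0))
})
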