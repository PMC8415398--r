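test_that("scenario overrides apply without mutating the base parameters", {
  base <- ltci_params()
  snapshot <- unclass(base)

  hi <- apply_scenario(base, ltci_scenario("hi", r_ind = 0.001))
  expect_equal(hi$r_ind, 0.001)
  expect_equal(unclass(hi)[setdiff(names(snapshot), "r_ind")],
    snapshot[setdiff(names(snapshot), "r_ind")])

  joint <- apply_scenario(base, ltci_scenario("joint", r_gov_r_ent = 0.0007))
  expect_equal(joint$r_gov, 0.0007)
  expect_equal(joint$r_ent, 0.0007)

  noop <- apply_scenario(base, ltci_scenario("noop"))
  expect_equal(unclass(noop), snapshot)

  expect_equal(unclass(base), snapshot) # untouched throughout
  expect_error(ltci_scenario("bad", g_emp = 0.1), "unknown lever")
  expect_error(ltci_scenario("bad", 0.5), "named")
})

test_that("built-in batteries enumerate the documented policy ranges", {
  bats <- default_batteries()
  expect_named(bats, c(
    "individual_rate", "reimbursement", "government_enterprise",
    "disability_rate"
  ))
  get_vals <- function(b, lever) {
    vapply(b, function(s) s$overrides[[lever]], numeric(1))
  }
  expect_equal(get_vals(bats$individual_rate, "r_ind"), c(0.0006, 0.0008, 0.001))
  expect_equal(get_vals(bats$reimbursement, "reimb"), seq(0.5, 0.9, 0.1))
  expect_equal(
    get_vals(bats$government_enterprise, "r_gov_r_ent"),
    c(0.0004, 0.0005, 0.0006, 0.0007)
  )
  expect_equal(get_vals(bats$disability_rate, "d_sev"), c(0.003, 0.004, 0.005))
})

test_that("running a battery preserves order and a baseline scenario equals plain simulation", {
  base <- ltci_params()
  bat <- default_batteries()$reimbursement
  res <- run_battery(base, bat)
  expect_length(res, 5)
  expect_equal(names(res), vapply(bat, `[[`, character(1), "name"))

  solo <- run_battery(base, list(ltci_scenario("baseline")))
  expect_equal(
    as.data.frame(solo[[1]]$trajectory),
    as.data.frame(ltci_simulate(base))
  )
  expect_error(run_battery(base, list()), "non-empty")
})

test_that("revenue levers leave expenditure untouched and vice versa", {
  base <- ltci_params()
  t0 <- ltci_simulate(base)
  for (bat in c("individual_rate", "government_enterprise")) {
    for (r in run_battery(base, default_batteries()[[bat]])) {
      expect_equal(r$trajectory$expenditure, t0$expenditure)
    }
  }
  for (bat in c("reimbursement", "disability_rate")) {
    for (r in run_battery(base, default_batteries()[[bat]])) {
      expect_equal(r$trajectory$rev_total, t0$rev_total)
    }
  }
})

test_that("cross-scenario deltas and self-comparison behave as differences", {
  base <- ltci_params()
  res <- run_battery(base, default_batteries()$individual_rate)
  expect_equal(compare_scenarios(res[[2]], res[[2]], 2025, "rev_total"), 0)
  d <- compare_scenarios(res[[1]], res[[3]], 2030, "rev_total")
  expect_rel(d, 416e6) # raising r_ind 0.06% -> 0.1%
  expect_equal(
    compare_scenarios(res[[1]], res[[3]], 2030, "balance_annual"), d
  ) # expenditure unchanged by a revenue lever
  expect_error(compare_scenarios(res[[1]], res[[2]], 2031, "rev_total"), "horizon")
  expect_error(compare_scenarios(res[[1]], res[[2]], 2030, "rev_individual"), "field")
})

test_that("expenditure scales exactly linearly across reimbursement and disability extremes", {
  base <- ltci_params()
  reimb <- run_battery(base, default_batteries()$reimbursement)
  expect_equal(
    result_2030 <- reimb[["reimb_0.9"]]$trajectory$expenditure[12] /
      reimb[["reimb_0.5"]]$trajectory$expenditure[12],
    1.8,
    tolerance = 1e-9
  )
  dis <- run_battery(base, default_batteries()$disability_rate)
  expect_equal(
    dis[["d_sev_0.005"]]$trajectory$expenditure[12] /
      dis[["d_sev_0.003"]]$trajectory$expenditure[12],
    5 / 3,
    tolerance = 1e-9
  )
})

test_that("deficit year detection distinguishes annual and cumulative conventions", {
  p <- calibrated_params()
  traj <- ltci_simulate(p)
  expect_equal(deficit_year(traj, "annual"), 2030L)
  expect_true(is.na(deficit_year(traj, "cumulative"))) # stock still positive

  mid <- ltci_simulate(apply_scenario(p, ltci_scenario("mid", r_ind = 0.0008)))
  expect_true(is.na(deficit_year(mid, "annual")))

  free <- ltci_simulate(ltci_params(reimb = 0))
  expect_true(is.na(deficit_year(free, "annual")))
})

test_that("raising the individual payment rate never brings the deficit year forward", {
  p <- calibrated_params()
  yrs <- vapply(seq(0.0004, 0.001, by = 0.0001), function(r) {
    t <- ltci_simulate(apply_scenario(p, ltci_scenario("r", r_ind = r)))
    y <- deficit_year(t, "annual")
    if (is.na(y)) as.integer(p$year_end) + 1L else y # NA = never, latest possible
  }, integer(1))
  expect_true(all(diff(yrs) >= 0))
})

test_that("10% bump effects order as disability >= reimbursement > joint gov/ent > individual", {
  p <- calibrated_params()
  deltas <- vapply(
    c("d_sev", "reimb", "r_gov_r_ent", "r_ind"),
    function(l) abs(bump_analysis(p, l)$delta_final), numeric(1)
  )
  # both expenditure levers scale the same flow, so they tie exactly
  expect_equal(deltas[["d_sev"]], deltas[["reimb"]], tolerance = 1e-9)
  expect_gt(deltas[["reimb"]], deltas[["r_gov_r_ent"]])
  expect_gt(deltas[["r_gov_r_ent"]], deltas[["r_ind"]])
  expect_rel(deltas[["r_ind"]], 62.4e6) # 10% of 2030 individual premiums

  flat <- bump_analysis(p, "r_ind", bump = 0)
  expect_equal(flat$series$pct_change, rep(0, 12))
  expect_equal(flat$delta_final, 0)
  expect_error(bump_analysis(p, "nope"), "unknown lever")
  expect_error(bump_analysis(p, "r_ind", bump = -1), "bump")
})

test_that("percent-change series flags zero-baseline years instead of erroring", {
  # zero revenue and zero expenditure -> identically zero balance
  p <- ltci_params(r_ind = 0, r_ent = 0, r_gov = 0, reimb = 0)
  b <- bump_analysis(p, "d_sev")
  expect_true(all(b$series$undefined))
  expect_true(all(is.na(b$series$pct_change)))
})
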