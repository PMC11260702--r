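# A coarse two-age incidence mix keeps these orchestration tests fast; the
# full 25-99 mix is exercised by the headline-economics checks in
# test-acceptance.R.
coarse_inc <- function() data.frame(age = c(55, 75), weight = c(0.5, 0.5))

test_that("identical NTCPs give exactly zero incrementals", {
  ps <- test_ps()
  for (id in c("ntcp_imrt", "ntcp_3dcrt")) ps <- set_param(ps, id, 0.180)
  bc <- run_base_case(ps, make_life_table(), coarse_inc(),
                      make_utility_curve())
  expect_equal(bc$incremental$dcost_discounted, c(0, 0), tolerance = 1e-9)
  expect_equal(bc$incremental$dqaly_discounted, c(0, 0), tolerance = 1e-12)
})

test_that("more conformal techniques save costs and gain QALYs", {
  ps <- test_ps()
  bc <- run_base_case(ps, make_life_table(), coarse_inc(),
                      make_utility_curve())
  expect_true(all(bc$incremental$dcost_discounted < 0))
  expect_true(all(bc$incremental$dqaly_discounted > 0))
  # direct-only incrementals shrink in magnitude but keep their sign
  expect_true(all(bc$incremental$dcost_direct_discounted < 0))
  expect_true(all(abs(bc$incremental$dcost_direct_discounted) <
                    abs(bc$incremental$dcost_discounted)))
  for (r in bc$results) {
    expect_lte(r$cost_discounted, r$cost_undiscounted)
    expect_lte(r$qaly_discounted, r$qaly_undiscounted)
  }
})

test_that("the hospitalization scenario has the published NA pattern and monotonicity", {
  ps <- test_ps()
  sc <- run_hospitalization_scenario(ps, make_life_table())$counts
  # 90-year cohort is only defined for the 10-year horizon
  n90 <- sc[sc$age == 90, ]
  expect_true(all(is.na(n90$hospitalizations[n90$horizon > 10])))
  expect_true(all(!is.na(n90$hospitalizations[n90$horizon == 10])))
  # cumulative in horizon, for every cohort and technique
  for (a in unique(sc$age)) {
    for (t in sbtox_techniques()) {
      v <- sc$hospitalizations[sc$age == a & sc$technique == t]
      v <- v[!is.na(v)]
      expect_true(all(diff(v) >= 0))
    }
  }
  # technique ordering at every defined cell
  wide <- reshape(sc[c("age", "technique", "horizon", "hospitalizations")],
                  idvar = c("age", "horizon"), timevar = "technique",
                  direction = "wide")
  ok <- !is.na(wide$hospitalizations.3dcrt)
  expect_true(all(wide$hospitalizations.3dcrt[ok] >=
                    wide$hospitalizations.imrt[ok]))
  expect_true(all(wide$hospitalizations.imrt[ok] >=
                    wide$hospitalizations.imrt_igrt[ok]))
})

test_that("zero grade-3/4 and recurrence risk produce zero admissions", {
  ps <- test_ps()
  for (id in c("p_tox_grade3", "p_tox_grade4",
               paste0("p_rec", rep(1:4, each = 2),
                      c("_surgery", "_supportive"))))
    ps <- set_param(ps, id, 0)
  sc <- run_hospitalization_scenario(ps, make_life_table(),
                                     cohort_ages = 50,
                                     horizons = c(10, 30))$counts
  expect_true(all(sc$hospitalizations == 0))
})

test_that("one-way sensitivity brackets linear parameters symmetrically", {
  ps <- test_ps()
  lt <- make_life_table()
  uc <- make_utility_curve()
  tor <- run_owsa(ps, lt, coarse_inc(), uc, param_ids = "wage_daily")
  row <- tor[tor$comparator == "imrt_igrt_vs_3dcrt" &
               tor$outcome == "dcost_discounted", ]
  # the daily wage enters the incremental cost linearly
  expect_equal((row$low + row$high) / 2, row$base,
               tolerance = 1e-6 * abs(row$base))
  # wages do not touch QALYs at all
  qrow <- tor[tor$outcome == "dqaly_discounted", ]
  expect_equal(qrow$spread, rep(0, nrow(qrow)), tolerance = 1e-12)
  expect_error(run_owsa(ps, lt, coarse_inc(), uc, param_ids = "bogus"),
               "unknown parameter")
})

test_that("parameters without influence produce zero tornado spread", {
  ps <- test_ps()
  # with the whole second line on antibiotics, the sequestrant price is idle
  ps <- set_param(set_param(ps, "p_second_line_ab", 100),
                  "p_second_line_bas", 0)
  tor <- run_owsa(ps, make_life_table(), coarse_inc(),
                  make_utility_curve(), param_ids = "cost_bas_unit")
  expect_equal(tor$spread, rep(0, nrow(tor)), tolerance = 1e-12)
})

test_that("toxicity-risk parameters dominate the cost tornado", {
  ps <- test_ps()
  tor <- run_owsa(ps, make_life_table(), coarse_inc(),
                  make_utility_curve(),
                  param_ids = c("ntcp_3dcrt", "cost_loperamide_unit"))
  cost <- tor[tor$comparator == "imrt_igrt_vs_3dcrt" &
                tor$outcome == "dcost_discounted", ]
  expect_equal(cost$param[1], "ntcp_3dcrt")
  expect_gt(cost$spread[1], 100 * cost$spread[2])
})

test_that("PSA is reproducible under a seed and degenerates to the base case", {
  ps <- test_ps()
  lt <- make_life_table()
  uc <- make_utility_curve()
  p1 <- run_psa(ps, lt, coarse_inc(), uc, n_draws = 3, seed = 21)
  p2 <- run_psa(ps, lt, coarse_inc(), uc, n_draws = 3, seed = 21)
  expect_identical(p1$draws, p2$draws)
  deg <- run_psa(ps, lt, coarse_inc(), uc, n_draws = 2, seed = 21,
                 mode = "degenerate")
  bc <- run_base_case(ps, lt, coarse_inc(), uc)
  for (d in split(deg$draws, deg$draws$draw)) {
    expect_equal(d$dcost_discounted, bc$incremental$dcost_discounted,
                 tolerance = 1e-12)
    expect_equal(d$dqaly_discounted, bc$incremental$dqaly_discounted,
                 tolerance = 1e-12)
  }
})

test_that("calibrated PSA means are consistent with the base case", {
  ps <- test_ps()
  lt <- make_life_table()
  uc <- make_utility_curve()
  inc <- coarse_inc()
  psa <- run_psa(ps, lt, inc, uc, n_draws = 60, seed = 8)
  bc <- run_base_case(ps, lt, inc, uc)
  d <- psa$draws[psa$draws$comparator == "imrt_igrt_vs_3dcrt", ]
  se <- sd(d$dcost_discounted) / sqrt(nrow(d))
  base <- bc$incremental$dcost_discounted[
    bc$incremental$comparator == "imrt_igrt_vs_3dcrt"]
  expect_lt(abs(mean(d$dcost_discounted) - base), 3 * se)
})
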