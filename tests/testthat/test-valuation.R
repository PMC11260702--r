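test_that("discount factors match closed forms", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03, tolerance = 1e-12)
  expect_equal(discount_factor(1, 0.03), 0.970874, tolerance = 1e-6)
  expect_equal(discount_factor(2, 0.015), 1.015^-2, tolerance = 1e-12)
  expect_equal(discount_factor(2, 0.015), 0.970662, tolerance = 1e-6)
  expect_error(discount_factor(-1, 0.03), "non-negative")
})

test_that("cost accrual prices event flows through the collapsed trees", {
  ps <- test_ps(half_cycle = FALSE)
  ph <- collapse_tree(build_pharma_tree(ps))
  ho <- collapse_tree(build_hospital_tree(ps))
  # the daily-wage x activity-rate block matches the hand calculation:
  # 14.55 sick days cost 14.55 x 250.118 x 0.751 = 2733.05
  expect_equal(param_value(ps, "sickdays_event") *
                 param_value(ps, "wage_daily") *
                 param_value(ps, "activity_rate"),
               2733.05, tolerance = 1e-2)
  tr <- mk_trace(ps, n_cycles = 4, start_age = 40)
  tr$flows$pharma_events[1] <- 1
  tr$flows$hosp_first[2] <- 1
  costs <- accrue_costs(tr, ps)
  expect_equal(costs$drugs[1], ph$expected_cost_drug)
  expect_equal(costs$hospitalizations[2], ho$expected_cost_hosp)
  expect_equal(costs$hospitalizations[2], 6296.52, tolerance = 1e-2)
  expect_equal(costs$productivity_morbidity[1],
               ph$expected_sick_days * 250.118 * 0.751, tolerance = 1e-9)
  # hospitalization sick leave carries the 1.5x event factor
  expect_equal(costs$productivity_morbidity[2],
               (14.55 * 1.5 + 9.65 * (1 - ho$death_prob)) *
                 250.118 * 0.751, tolerance = 1e-9)
  # zero flows accrue nothing
  expect_true(all(costs$total[3:4] == 0))
  # excluding indirect costs removes exactly the productivity components
  direct <- accrue_costs(tr, ps, include_indirect = FALSE)
  expect_true(all(direct$productivity_morbidity == 0))
  expect_equal(direct$total, costs$drugs + costs$hospitalizations)
})

test_that("sick leave and mortality productivity apply to working ages only", {
  ps <- test_ps()
  tr <- mk_trace(ps, n_cycles = 2, start_age = 70)
  tr$flows$pharma_events[1] <- 1
  tr$flows$sb_deaths[2] <- 0.5
  costs <- accrue_costs(tr, ps)
  expect_true(all(costs$productivity_morbidity == 0))
  expect_true(all(costs$productivity_mortality == 0))
  # a death at 40 is valued by remaining earnings to 65
  tr2 <- mk_trace(ps, n_cycles = 1, start_age = 40)
  tr2$flows$sb_deaths[1] <- 1
  costs2 <- accrue_costs(tr2, ps)
  expect_equal(costs2$productivity_mortality[1],
               55025.9 * 0.751 * 25, tolerance = 1e-6)
  expect_lt(costs2$productivity_mortality_disc[1],
            costs2$productivity_mortality[1])
})

test_that("QALY accrual applies one-cycle multiplicative disutility to event flows", {
  ps <- test_ps(half_cycle = FALSE, utility_discount = 0)
  curve <- make_utility_curve(u_young = 0.8, u_old = 0.8)
  # all alive, no events: half a QALY per cycle at U = 1
  tr <- mk_trace(ps, n_cycles = 3, start_age = 40)
  q1 <- accrue_qalys(tr, ps, make_utility_curve(1, 1))
  expect_equal(q1$qaly, rep(0.5, 3))
  # a surgery-pathway event cycle at U = 0.8 yields 0.8 x (1-0.387) x 0.5
  ps_surg <- set_param(set_param(ps, "p_surgery", 100),
                       "p_supportive", 0)
  ps_surg <- set_param(ps_surg, "p_surgery_death", 0)
  ps_surg <- set_param(ps_surg, "p_surgery_survival", 100)
  tr2 <- mk_trace(ps_surg, n_cycles = 1, start_age = 40)
  tr2$flows$hosp_first[1] <- 1
  tr2$flows$hosp_surviving[1] <- 1
  q2 <- accrue_qalys(tr2, ps_surg, curve)
  expect_equal(q2$qaly[1], 0.8 * (1 - 0.387) * 0.5, tolerance = 1e-12)
  expect_equal(q2$qaly[1], 0.2452, tolerance = 1e-4)
  # zero disutility makes event cycles equal baseline cycles
  ps0 <- set_param(ps_surg, "disutility_surgery", 0)
  tr3 <- mk_trace(ps0, n_cycles = 1, start_age = 40)
  tr3$flows$hosp_first[1] <- 1
  tr3$flows$hosp_surviving[1] <- 1
  expect_equal(accrue_qalys(tr3, ps0, curve)$qaly[1], 0.8 * 0.5)
  # ages outside the curve are refused
  expect_error(accrue_qalys(mk_trace(ps, 2, start_age = 40), ps,
                            make_utility_curve(ages = 50:100)),
               "outside")
})

test_that("summaries discount correctly and components add up", {
  ps <- test_ps(half_cycle = FALSE)
  ho <- collapse_tree(build_hospital_tree(ps))
  # constant 100 EUR hospitalization cost per cycle for 4 cycles at 3%:
  # 100 * (1 + 1.03^-0.5 + 1.03^-1 + 1.03^-1.5)
  oracle <- 100 * sum(1.03^(-(0:3) * 0.5))
  tr <- mk_trace(ps, n_cycles = 4, start_age = 70)
  tr$flows$hosp_first <- 100 / ho$expected_cost_hosp
  tr$flows$recurrences <- 0
  costs <- accrue_costs(tr, ps)
  expect_equal(sum(costs$hospitalizations_disc), oracle, tolerance = 1e-9)
  qalys <- accrue_qalys(tr, ps, make_utility_curve())
  res <- summarize_economics(costs, qalys, "3dcrt")
  expect_equal(res$cost_undiscounted,
               sum(costs$total))
  bk <- res$breakdown
  expect_equal(sum(bk$discounted), res$cost_discounted,
               tolerance = 1e-6 * max(1, res$cost_discounted))
  expect_lte(res$cost_discounted, res$cost_undiscounted)
  expect_lte(res$qaly_discounted, res$qaly_undiscounted)
})

test_that("with unit utility and no events QALYs equal discounted life-years", {
  ps <- zero_tox_ps(utility_discount = 0)
  lt <- make_life_table()
  tr <- run_cohort(ps, "3dcrt", 60, lt)
  q <- accrue_qalys(tr, ps, make_utility_curve(1, 1))
  expect_equal(sum(q$qaly), sum(q$ly), tolerance = 1e-12)
  ps2 <- zero_tox_ps()
  q2 <- accrue_qalys(run_cohort(ps2, "3dcrt", 60, lt), ps2,
                     make_utility_curve(1, 1))
  expect_lt(sum(q2$qaly_disc), sum(q2$ly))
})
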