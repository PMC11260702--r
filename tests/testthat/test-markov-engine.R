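test_that("transition matrices are row-stochastic with correct structure", {
  ps <- test_ps()
  lt <- make_life_table()
  tm <- build_transition_matrix(ps, "3dcrt", cycle_index = 4, age = 62,
                                life_table = lt)
  expect_equal(unname(rowSums(tm)), rep(1, 22), tolerance = 1e-9)
  expect_true(all(tm >= 0))
  # absorbing deaths
  expect_equal(tm["death_sb", "death_sb"], 1)
  expect_equal(tm["death_other", "death_other"], 1)
  # tunnel states cannot be re-occupied by themselves
  for (s in paste0("recurrent_", 1:4)) expect_equal(tm[s, s], 0)
  # half-yearly background mortality from the annual life-table q
  q <- lt$qx[lt$age == 62]
  expect_equal(tm["post_treatment", "death_other"], 1 - (1 - q)^0.5)
  expect_lt(abs((1 - (1 - 0.02)^0.5) - 0.010050), 1e-6)
})

test_that("zero toxicity and zero mortality freeze the reachable dynamics", {
  ps <- zero_tox_ps()
  tm <- build_transition_matrix(ps, "3dcrt", 0, 40, zero_lt())
  # all occupiable states are fixed points; tunnel rows keep their
  # structural hospital-pathway exits but are unreachable (no inflow)
  expect_equal(unname(tm[c(1:16, 21:22), ]),
               diag(22)[c(1:16, 21:22), ])
  expect_true(all(tm[, paste0("recurrent_", 1:4)] == 0))
})

test_that("row sums stay 1 across random parameter draws", {
  ps <- test_ps()
  lt <- make_life_table()
  set.seed(5)
  for (i in 1:50) {
    psi <- draw_parameter_set(ps)
    tm <- build_transition_matrix(psi, sample(sbtox_techniques(), 1),
                                  cycle_index = sample(0:100, 1),
                                  age = sample(30:95, 1), life_table = lt)
    expect_equal(unname(rowSums(tm)), rep(1, 22), tolerance = 1e-9)
  }
})

test_that("the cohort iteration conserves mass and matches the matrix product", {
  ps <- test_ps()
  lt <- make_life_table()
  tr <- run_cohort(ps, "3dcrt", 60, lt)
  expect_equal(unname(rowSums(tr$occupancy)),
               rep(1, nrow(tr$occupancy)), tolerance = 1e-9)
  expect_true(all(tr$occupancy >= -1e-15))
  # absorbing occupancy is non-decreasing
  for (s in c("death_sb", "death_other"))
    expect_true(all(diff(tr$occupancy[, s]) >= -1e-12))
  # one-step engine update equals occupancy %*% transition matrix
  for (k in c(0, 7, 30)) {
    tm <- build_transition_matrix(ps, "3dcrt", k, 60 + k * 0.5, lt)
    expect_equal(unname(tr$occupancy[k + 2, ]),
                 unname(as.vector(tr$occupancy[k + 1, ] %*% tm)),
                 tolerance = 1e-12)
  }
})

test_that("tunnel occupancy equals the previous cycle's recurrence inflow", {
  ps <- test_ps()
  tr <- run_cohort(ps, "3dcrt", 40, zero_lt())
  tun <- rowSums(tr$occupancy[, paste0("recurrent_", 1:4)])
  # with zero background mortality nothing is lost inside the tunnel
  expect_equal(unname(tun[-1]), tr$flows$recurrences, tolerance = 1e-12)
  expect_equal(tr$flows$rec_resolved[-1],
               tr$flows$recurrences[-nrow(tr$flows)], tolerance = 1e-12)
})

test_that("with zero toxicity the cohort reproduces life-table survival exactly", {
  ps <- zero_tox_ps()
  lt <- make_life_table()
  tr <- run_cohort(ps, "3dcrt", 50, lt)
  q <- lt$qx[match(50:99, lt$age)]
  qh <- 1 - (1 - q)^0.5
  surv <- cumprod(rep(1 - qh, each = 2))
  expect_equal(unname(tr$occupancy[-1, "post_treatment"]), surv,
               tolerance = 1e-12)
  expect_true(all(tr$flows$sb_deaths == 0))
  expect_true(all(tr$flows$hospitalizations == 0))
})

test_that("run_cohort validates its age arguments", {
  ps <- test_ps()
  expect_error(run_cohort(ps, "3dcrt", 20, zero_lt()), "start_age")
  expect_error(run_cohort(ps, "3dcrt", 60, zero_lt(), horizon_age = 55),
               "horizon")
})

test_that("technique ordering is monotone in admissions and SB deaths", {
  ps <- test_ps()
  lt <- make_life_table()
  runs <- lapply(sbtox_techniques(), function(t)
    run_cohort(ps, t, 50, lt))
  hosp <- vapply(runs, function(r) sum(r$flows$hospitalizations),
                 numeric(1))
  sbd <- vapply(runs, function(r) sum(r$flows$sb_deaths), numeric(1))
  expect_true(all(diff(hosp) > 0))  # imrt_igrt < imrt < 3dcrt
  expect_true(all(diff(sbd) > 0))
})

test_that("mixed cohorts reduce to single-age runs and are linear in weights", {
  ps <- test_ps()
  lt <- make_life_table()
  one <- run_mixed_cohort(ps, "imrt",
                          data.frame(age = 70, weight = 1), lt)
  ref <- run_cohort(ps, "imrt", 70, lt)
  expect_equal(one$occupancy, ref$occupancy, tolerance = 1e-12)
  two <- run_mixed_cohort(ps, "imrt",
                          data.frame(age = c(60, 80),
                                     weight = c(0.5, 0.5)), lt)
  r60 <- run_cohort(ps, "imrt", 60, lt)
  r80 <- run_cohort(ps, "imrt", 80, lt)
  n80 <- nrow(r80$flows)
  expect_equal(two$flows$hospitalizations[seq_len(n80)],
               0.5 * r60$flows$hospitalizations[seq_len(n80)] +
                 0.5 * r80$flows$hospitalizations, tolerance = 1e-12)
  expect_error(run_mixed_cohort(ps, "imrt",
                                data.frame(age = c(60, 80),
                                           weight = c(0.5, 0.4)), lt),
               "sum to 1")
})

test_that("the cohort trace matches an independent microsimulation", {
  ps <- test_ps()
  lt <- make_life_table()
  tr <- run_cohort(ps, "3dcrt", 60, lt)
  n <- 20000
  occ <- microsim_occupancy(ps, "3dcrt", 60, lt, n_patients = n,
                            n_cycles = 40, seed = 99)
  for (k in c(10, 40)) {
    p_hat <- occ[k + 1, ]
    p_coh <- unname(tr$occupancy[k + 1, ])
    p_mid <- (p_hat + p_coh) / 2
    se <- sqrt(pmax(p_mid * (1 - p_mid), 1e-12) / n)
    expect_true(all(abs(p_hat - p_coh) <= 3 * se + 1e-9),
                info = paste("cycle", k))
  }
})
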