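cfg <- base_case_config()

test_that("short-run model prices the second-session assumption", {
  sr <- short_run(cfg)
  # arithmetic oracles: total cost x (1 + (1 - p_success))
  expect_equal(sr$expected_acute_cost[sr$name == "surgery"], 19389 * 1.01)
  expect_equal(sr$expected_acute_cost[sr$name == "RFA"], 11189 * 1.07)
  expect_equal(sr$first_month_utility, cfg$strategies$qol_first_month)

  # perfect first session: no second-session cost
  st <- cfg$strategies[1, ]
  st$p_success_first <- 1
  sr1 <- short_run(st, cfg$settings)
  expect_equal(sr1$expected_acute_cost, 19389)
})

test_that("transition matrices are row-stochastic with the specified entries", {
  lt <- us_lifetable()
  m <- transition_matrix(cfg$strategies[1, ], cfg$settings, lt, cycle = 1, age = 73)
  # cycle 1 recurrence-free row: residual, hepatic, other, year-1 mortality
  expect_equal(unname(m[1, ]), c(0.8425, 0.025, 0.05, 0.0825))
  expect_equal(unname(m[4, ]), c(0, 0, 0, 1))  # death absorbing

  # recurrence states never cross over or return
  expect_equal(unname(m[2, c(1, 3)]), c(0, 0))
  expect_equal(unname(m[3, c(1, 2)]), c(0, 0))

  # with a zero life table the hepatic death entry is the state probability
  z <- zero_lifetable()
  for (bg in c(TRUE, FALSE)) {
    s <- cfg$settings; s$background_mortality_in_recurrence <- bg
    mz <- transition_matrix(cfg$strategies[1, ], s, z, cycle = 2, age = 80)
    expect_equal(mz[2, 4], 0.12)
    expect_equal(mz[3, 4], 0.05)
  }

  # competing-risk combination when background mortality is enabled
  ltq <- flat_lifetable(0.1)
  s <- cfg$settings; s$background_mortality_in_recurrence <- TRUE
  mq <- transition_matrix(cfg$strategies[1, ], s, ltq, cycle = 3, age = 80)
  expect_equal(mq[2, 4], 1 - 0.9 * 0.88)
  expect_equal(mq[3, 4], 1 - 0.9 * 0.95)

  # rows always sum to 1, across strategies, cycles, ages and conventions
  for (seed in 1:20) {
    rc <- random_config(seed)
    for (i in 1:3) {
      for (cyc in c(1, 2, 10)) {
        mm <- transition_matrix(rc$strategies[i, ], rc$settings, lt,
                                cycle = cyc, age = 73 + cyc)
        expect_true(all(abs(rowSums(mm) - 1) < 1e-12))
        expect_true(all(mm >= 0 & mm <= 1))
      }
    }
  }

  # infeasible outgoing mass errors rather than renormalising
  hotq <- flat_lifetable(0.95)
  expect_error(
    transition_matrix(cfg$strategies[2, ], cfg$settings, hotq, cycle = 2, age = 80),
    class = "cea_validation_error"
  )
})

test_that("immortal undiscounted cohort accrues one QALY per cycle", {
  z <- zero_lifetable()
  st <- cfg$strategies[1, ]
  st$mortality_year1 <- 0; st$p_hepatic_recurrence <- 0; st$p_other_recurrence <- 0
  st$qol_first_month <- 1
  s <- tweak_config(cfg, discount_rate = 0)$settings
  out <- run_cohort(st, s, z)
  expect_equal(out$expected_qaly, 27)
  expect_equal(max(out$trace$cycle), 27)
})

test_that("constant-hazard no-recurrence cohort matches the annuity closed form", {
  # start-of-cycle accrual mode, which the closed form describes
  for (case in list(list(q = 0.1, r = 0.03, qol1 = 1),
                    list(q = 0.25, r = 0, qol1 = 0.7),
                    list(q = 0.05, r = 0.07, qol1 = 0.95))) {
    lt <- flat_lifetable(case$q)
    st <- cfg$strategies[1, ]
    st$mortality_year1 <- case$q
    st$p_hepatic_recurrence <- 0; st$p_other_recurrence <- 0
    st$qol_first_month <- case$qol1
    s <- tweak_config(cfg, discount_rate = case$r,
                      half_cycle_correction = FALSE)$settings
    out <- run_cohort(st, s, lt)
    expect_equal(out$expected_qaly, annuity_qaly(case$q, case$r, 27, case$qol1),
                 tolerance = 1e-9)
  }
})

test_that("cohort trace conserves occupancy and death occupancy is monotone", {
  lt <- us_lifetable()
  for (seed in 1:15) {
    rc <- random_config(seed)
    out <- run_all(rc, lt)
    for (tr in out$trace) {
      occ <- as.matrix(tr[, c("occ_no_recurrence", "occ_hepatic",
                              "occ_other", "occ_death")])
      expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
      expect_true(all(diff(tr$occ_death) >= -1e-12))
    }
  }
})

test_that("expected QALYs fall as discount rate or recurrence risk rises", {
  lt <- us_lifetable()
  base <- run_cohort(cfg$strategies[2, ], cfg$settings, lt)
  for (r in c(0.01, 0.05, 0.1)) {
    s <- tweak_config(cfg, discount_rate = r)$settings
    out <- run_cohort(cfg$strategies[2, ], s, lt)
    if (r < 0.03) expect_gt(out$expected_qaly, base$expected_qaly)
    else expect_lt(out$expected_qaly, base$expected_qaly)
  }

  # raising hepatic recurrence never raises QALYs, never reduces recurrence time
  st <- cfg$strategies[2, ]
  prev_q <- Inf; prev_rec <- -Inf
  for (p in c(0.02, 0.077, 0.15, 0.3)) {
    st$p_hepatic_recurrence <- p
    out <- run_cohort(st, cfg$settings, lt)
    rec_time <- sum(out$trace$occ_hepatic + out$trace$occ_other)
    expect_lte(out$expected_qaly, prev_q)
    expect_gte(rec_time, prev_rec)
    prev_q <- out$expected_qaly; prev_rec <- rec_time
  }
})

test_that("lifetime cost always covers the short-run cost and QALYs fit the horizon", {
  lt <- us_lifetable()
  for (seed in 1:10) {
    rc <- random_config(seed)
    out <- run_all(rc, lt)
    sr <- short_run(rc)
    expect_true(all(out$cost >= sr$expected_acute_cost - 1e-9))
    expect_true(all(out$qaly >= 0))
    expect_true(all(out$qaly <= rc$settings$age_max - rc$settings$age_start))
  }
})

test_that("run_all returns order-stable per-strategy outcomes", {
  lt <- us_lifetable()
  out <- run_all(cfg, lt)
  expect_equal(nrow(out), 3)
  expect_equal(out$strategy, c("surgery", "RFA", "MWA"))

  # identical strategies yield identical outcomes
  twin <- cfg
  twin$strategies[2, -1] <- twin$strategies[3, -1]
  out2 <- run_all(twin, lt)
  expect_equal(out2$cost[2], out2$cost[3])
  expect_equal(out2$qaly[2], out2$qaly[3])

  # base case: cost ordering MWA < RFA < surgery
  expect_lt(out$cost[out$strategy == "MWA"], out$cost[out$strategy == "RFA"])
  expect_lt(out$cost[out$strategy == "RFA"], out$cost[out$strategy == "surgery"])
})

test_that("trace export writes the documented CSV columns", {
  lt <- us_lifetable()
  out <- run_cohort(cfg$strategies[1, ], cfg$settings, lt)
  path <- tempfile(fileext = ".csv")
  write_trace(out, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back),
               c("cycle", "age", "occ_no_recurrence", "occ_hepatic",
                 "occ_other", "occ_death", "cost_increment", "qaly_increment"))
  expect_equal(nrow(back), 28)
  expect_equal(sum(back$cost_increment), out$expected_cost)
  unlink(path)
})
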