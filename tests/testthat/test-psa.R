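cfg <- base_case_config()
lt <- us_lifetable()

test_that("method-of-moments distributions recover the stated parameters", {
  b <- make_distribution(0.5, 0.1, "beta")
  expect_equal(b$shape1, 12)
  expect_equal(b$shape2, 12)
  g <- make_distribution(855, 171, "gamma")
  expect_equal(g$shape, 25)
  expect_equal(g$scale, 34.2)

  expect_error(make_distribution(0.5, 0.5, "beta"), "se\\^2",
               class = "cea_validation_error")
  expect_error(make_distribution(1, 0.1, "beta"), class = "cea_validation_error")
  expect_error(make_distribution(-5, 1, "gamma"), class = "cea_validation_error")
  expect_error(make_distribution(855, 0, "gamma"), class = "cea_validation_error")
})

test_that("parameter draws are seeded, feasible and converge to the means", {
  d1 <- draw_parameters(cfg, spread = 0.2, seed = 11)
  d2 <- draw_parameters(cfg, spread = 0.2, seed = 11)
  expect_equal(d1$strategies, d2$strategies)
  expect_equal(unclass(d1$settings), unclass(d2$settings))
  expect_s3_class(validate_config(d1), "cea_config")

  # structural constants never drawn
  expect_equal(d1$settings$discount_rate, 0.03)
  expect_equal(d1$settings$wtp, 1e5)
  expect_equal(d1$settings$p_success_second_session, 1)
  expect_equal(d1$strategies$hospital_days, cfg$strategies$hospital_days)
  # boundary-mean beta parameters are degenerate and stay fixed
  expect_equal(d1$settings$utility_no_recurrence, 1)
  # shared non-hepatic recurrence: one common draw
  expect_equal(length(unique(d1$strategies$p_other_recurrence)), 1L)

  # spread -> 0: draws converge on the base-case means
  tiny <- draw_parameters(cfg, spread = 1e-5, seed = 3)
  expect_equal(tiny$strategies$p_hepatic_recurrence,
               cfg$strategies$p_hepatic_recurrence, tolerance = 1e-3)
  expect_equal(tiny$settings$cost_recurrence_per_cycle, 3935, tolerance = 1)

  # law of large numbers: mean of many hepatic-recurrence draws near 0.077
  n <- 10000
  draws <- vapply(seq_len(n), function(i) {
    ablatecea:::draw_row(cfg, 0.2, 1000 + i)$strategies$p_hepatic_recurrence[2]
  }, numeric(1))
  se <- 0.2 * 0.077
  expect_lt(abs(mean(draws) - 0.077), 3 * se / sqrt(n))
})

test_that("PSA is reproducible and composes with single draws", {
  p1 <- run_psa(cfg, lt, n = 25, seed = 5)
  p2 <- run_psa(cfg, lt, n = 25, seed = 5)
  expect_identical(p1$draws, p2$draws)
  expect_equal(nrow(p1$draws), 75)

  # n = 1 equals one draw_parameters + run_all evaluation
  p <- run_psa(cfg, lt, n = 1, seed = 9)
  manual <- run_all(draw_parameters(cfg, spread = 0.2, seed = 10), lt)
  expect_equal(p$draws$cost, manual$cost, tolerance = 1e-9)
  expect_equal(p$draws$qaly, manual$qaly, tolerance = 1e-9)
})

test_that("vectorised PSA evaluation matches the cohort engine draw by draw", {
  for (hcc in c(TRUE, FALSE)) {
    for (bg in c(TRUE, FALSE)) {
      cc <- tweak_config(cfg, half_cycle_correction = hcc,
                         background_mortality_in_recurrence = bg)
      p <- run_psa(cc, lt, n = 4, seed = 31)
      for (i in 1:4) {
        drawn <- draw_parameters(cc, spread = 0.2, seed = 31 + i)
        manual <- run_all(drawn, lt)
        sub <- p$draws[p$draws$iteration == i, ]
        expect_equal(sub$cost, manual$cost, tolerance = 1e-9)
        expect_equal(sub$qaly, manual$qaly, tolerance = 1e-9)
      }
    }
  }
})

test_that("PSA means stay near the base case and MWA costs less than surgery", {
  p <- run_psa(cfg, lt, n = 2000, seed = 17)
  g <- glance(p)
  base <- tidy(run_all(cfg, lt))
  for (s in base$strategy) {
    expect_lt(abs(g$mean_qaly[g$strategy == s] / base$qaly[base$strategy == s] - 1),
              0.05)
  }
  expect_lt(g$mean_cost[g$strategy == "MWA"], g$mean_cost[g$strategy == "surgery"])
})

test_that("acceptability curves partition the iterations at every WTP", {
  p <- run_psa(cfg, lt, n = 400, seed = 23)
  grid <- seq(0, 2e5, by = 2e4)
  cc <- ceac(p, grid)
  sums <- dplyr::summarise(dplyr::group_by(cc, wtp), s = sum(probability))
  expect_true(all(abs(sums$s - 1) < 1e-12))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))

  # single strategy: probability 1 everywhere
  solo <- p
  solo$draws <- solo$draws[solo$draws$strategy == "MWA", ]
  cs <- ceac(solo, grid)
  expect_true(all(cs$probability == 1))
})

test_that("CEAC limits rank by cost at WTP 0 and by QALYs as WTP grows", {
  p <- run_psa(cfg, lt, n = 300, seed = 29)
  w <- tidyr::pivot_wider(p$draws, id_cols = iteration, names_from = strategy,
                          values_from = c(cost, qaly))
  cm <- as.matrix(w[, paste0("cost_", c("surgery", "RFA", "MWA"))])
  qm <- as.matrix(w[, paste0("qaly_", c("surgery", "RFA", "MWA"))])

  c0 <- ceac(p, 0)
  cheap <- table(factor(c("surgery", "RFA", "MWA")[apply(cm, 1, which.min)],
                        levels = c("surgery", "RFA", "MWA"))) / nrow(cm)
  expect_equal(c0$probability, as.numeric(cheap[c0$strategy]))

  chigh <- ceac(p, 1e9)
  effmax <- table(factor(c("surgery", "RFA", "MWA")[apply(qm, 1, which.max)],
                         levels = c("surgery", "RFA", "MWA"))) / nrow(qm)
  expect_equal(chigh$probability, as.numeric(effmax[chigh$strategy]),
               tolerance = 0.01)
})
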