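#' Patient-level microsimulation of one strategy
#'
#' Simulates individual patients through exactly the rules of the cohort
#' engine — the 30-day treatment model (a failed first session incurs one
#' additional full treatment cost), then annual transitions drawn from the
#' same per-cycle transition matrices — accruing the same discounted costs
#' and QALYs. Serves as an independent Monte Carlo check on [run_cohort()]:
#' the cohort result is the exact expectation of the microsimulation, so
#' means agree within Monte Carlo error.
#'
#' All randomness comes from a single seeded uniform matrix indexed by
#' (patient, cycle), so results do not depend on the order patients are
#' evaluated in.
#'
#' @param strategy One strategy row (one-row data frame or named list).
#' @param settings `cea_settings`.
#' @param table `cea_lifetable`.
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed.
#' @param n_cycles Optional shorter horizon.
#' @return An object of class `cea_microsim`: list with `n_patients`,
#'   `seed`, `mean_cost`, `mean_qaly`, `se_cost`, `se_qaly`.
#' @export
#' @examples
#' cfg <- base_case_config()
#' run_microsim(cfg$strategies[1, ], cfg$settings, generate_lifetable(),
#'              n_patients = 500, seed = 1, n_cycles = 5)
run_microsim <- function(strategy, settings, table, n_patients, seed,
                         n_cycles = NULL) {
  if (is.data.frame(strategy)) {
    stopifnot(nrow(strategy) == 1L)
    strategy <- as.list(strategy)
  }
  stopifnot(n_patients >= 1)
  s <- settings
  n_total <- s$age_max - s$age_start
  n <- if (is.null(n_cycles)) n_total else min(n_cycles, n_total)
  hcc <- isTRUE(s$half_cycle_correction)

  set.seed(as.integer(seed))
  U <- matrix(stats::runif(n_patients * (n + 1L)), nrow = n_patients)

  total <- strategy$acute_procedure_cost +
    strategy$hospital_days * s$cost_per_hospital_day
  # column 1: second-session lottery
  cost <- total * (1 + (U[, 1L] >= strategy$p_success_first))
  qaly <- numeric(n_patients)

  u <- c(s$utility_no_recurrence, s$utility_hepatic_recurrence,
         s$utility_other_recurrence, s$utility_death)
  cvec <- c(s$cost_no_recurrence_per_cycle, s$cost_recurrence_per_cycle,
            s$cost_recurrence_per_cycle, 0)

  state <- rep(1L, n_patients)
  for (t in seq_len(n)) {
    age <- s$age_start + t - 1L
    P <- transition_matrix(strategy, s, table, t, age)
    cum <- t(apply(P, 1L, cumsum))
    uu <- U[, t + 1L]
    state2 <- 1L + (uu > cum[state, 1L]) + (uu > cum[state, 2L]) +
      (uu > cum[state, 3L])

    ut <- u
    if (t == 1L) {
      ut[1L] <- strategy$qol_first_month / 12 + (11 / 12) * s$utility_no_recurrence
    }
    disc <- (1 + s$discount_rate)^-(t - 1)
    if (hcc) {
      qaly <- qaly + disc * 0.5 * (ut[state] + ut[state2])
      cost <- cost + disc * 0.5 * (cvec[state] + cvec[state2])
    } else {
      qaly <- qaly + disc * ut[state]
      cost <- cost + disc * cvec[state]
    }
    state <- state2
  }

  structure(
    list(n_patients = n_patients, seed = seed,
         mean_cost = mean(cost), mean_qaly = mean(qaly),
         se_cost = stats::sd(cost) / sqrt(n_patients),
         se_qaly = stats::sd(qaly) / sqrt(n_patients)),
    class = "cea_microsim"
  )
}

#' @export
print.cea_microsim <- function(x, ...) {
  cat(sprintf("<cea_microsim> n = %d: cost %.2f (se %.2f), QALY %.4f (se %.4f)\n",
              x$n_patients, x$mean_cost, x$se_cost, x$mean_qaly, x$se_qaly))
  invisible(x)
}

#' Random valid model configuration
#'
#' Draws a structurally valid random configuration for property testing:
#' probabilities jointly feasible (outgoing sums below 1 at every age of a
#' standard life table), positive costs, utilities in `[0, 1]` with death
#' fixed at 0. Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @return A validated `cea_config`.
#' @export
random_config <- function(seed) {
  set.seed(as.integer(seed))
  settings <- model_settings(
    age_start = sample(60:80, 1),
    age_max = 100,
    discount_rate = stats::runif(1, 0, 0.08),
    wtp = stats::runif(1, 2e4, 2e5),
    cost_per_hospital_day = stats::runif(1, 500, 5000),
    cost_no_recurrence_per_cycle = stats::runif(1, 100, 2000),
    cost_recurrence_per_cycle = stats::runif(1, 1000, 8000),
    utility_no_recurrence = stats::runif(1, 0.7, 1),
    utility_hepatic_recurrence = stats::runif(1, 0.3, 0.7),
    utility_other_recurrence = stats::runif(1, 0.05, 0.3),
    p_death_hepatic_recurrence = stats::runif(1, 0.02, 0.4),
    p_death_other_recurrence = stats::runif(1, 0.02, 0.4),
    half_cycle_correction = sample(c(TRUE, FALSE), 1),
    background_mortality_in_recurrence = sample(c(TRUE, FALSE), 1)
  )
  strategies <- tibble::tibble(
    name = c("surgery", "RFA", "MWA"),
    p_success_first = stats::runif(3, 0.7, 1),
    acute_procedure_cost = stats::runif(3, 500, 10000),
    hospital_days = sample(0:10, 3, replace = TRUE),
    qol_first_month = stats::runif(3, 0.4, 1),
    mortality_year1 = stats::runif(3, 0, 0.3),
    p_hepatic_recurrence = stats::runif(3, 0, 0.25),
    p_other_recurrence = rep(stats::runif(1, 0, 0.25), 3)
  )
  new_config(settings, strategies)
}
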