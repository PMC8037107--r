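#' Short-run (30-day) treatment model
#'
#' Expected acute treatment cost and first-month utility per strategy. An
#' incomplete first session (probability `1 - p_success_first`) is followed
#' by a repeat session that is assumed complete and incurs one additional
#' full treatment cost, so the expected acute cost is
#' `total_treatment_cost * (1 + (1 - p_success_first))`. All patients enter
#' the long-run Markov model treatment-complete.
#'
#' @param strategies Strategy tibble or a `cea_config`.
#' @param settings `cea_settings`; taken from the config when one is given.
#' @return Tibble with columns `name`, `expected_acute_cost`,
#'   `first_month_utility`.
#' @export
#' @examples
#' short_run(base_case_config())
short_run <- function(strategies, settings = NULL) {
  if (inherits(strategies, "cea_config")) {
    settings <- strategies$settings
    strategies <- strategies$strategies
  }
  tc <- total_treatment_cost(strategies, settings)
  tibble::tibble(
    name = strategies$name,
    expected_acute_cost = tc$total_cost * (1 + (1 - strategies$p_success_first)),
    first_month_utility = strategies$qol_first_month
  )
}

#' Per-cycle transition matrix
#'
#' The 4x4 row-stochastic matrix over the states no recurrence,
#' hepatic-only recurrence, any other recurrence, death, for a given
#' strategy, cycle and attained age. From the recurrence-free state the
#' annual death probability is the strategy's observed one-year mortality
#' in cycle 1 and the life-table background `qx` thereafter; hepatic and
#' other recurrence are entered with the strategy's annual probabilities
#' and are mutually absorbing (no cross-over, no return). In the recurrence
#' states the death probability is the state-specific annual probability,
#' optionally combined with background `qx` as independent competing risks
#' (`settings$background_mortality_in_recurrence`). Death is absorbing.
#'
#' @param strategy One strategy: a one-row data frame or named list.
#' @param settings `cea_settings`.
#' @param table `cea_lifetable`.
#' @param cycle Cycle index, >= 1.
#' @param age Attained age at the start of the cycle.
#' @return A 4x4 matrix with `STATES` dimnames; rows sum to 1.
#' @export
transition_matrix <- function(strategy, settings, table, cycle, age) {
  stopifnot(cycle >= 1)
  q <- qx_at(table, age)
  d_no <- if (cycle == 1L) strategy$mortality_year1 else q
  p_hep <- strategy$p_hepatic_recurrence
  p_oth <- strategy$p_other_recurrence
  stay <- 1 - d_no - p_hep - p_oth
  if (stay < -1e-12) {
    rlang::abort(
      sprintf("outgoing probability from the recurrence-free state exceeds 1 (%.4f) at cycle %d.",
              d_no + p_hep + p_oth, cycle),
      class = "cea_validation_error"
    )
  }
  stay <- max(stay, 0)
  if (isTRUE(settings$background_mortality_in_recurrence)) {
    d_hep <- 1 - (1 - q) * (1 - settings$p_death_hepatic_recurrence)
    d_oth <- 1 - (1 - q) * (1 - settings$p_death_other_recurrence)
  } else {
    d_hep <- settings$p_death_hepatic_recurrence
    d_oth <- settings$p_death_other_recurrence
  }
  m <- rbind(
    c(stay, p_hep, p_oth, d_no),
    c(0, 1 - d_hep, 0, d_hep),
    c(0, 0, 1 - d_oth, d_oth),
    c(0, 0, 0, 1)
  )
  dimnames(m) <- list(STATES, STATES)
  m
}

# Reward/transition recursion shared by run_cohort and the trace builder.
# Returns per-cycle occupancy (after each transition) and discounted
# increments. `strategy` and `settings` are plain lists here; validation
# happens upstream.
cohort_engine <- function(strategy, settings, table, n_cycles = NULL) {
  s <- settings
  n_total <- s$age_max - s$age_start
  n <- if (is.null(n_cycles)) n_total else min(n_cycles, n_total)
  stopifnot(n >= 1)

  sr_cost <- (strategy$acute_procedure_cost +
                strategy$hospital_days * s$cost_per_hospital_day) *
    (1 + (1 - strategy$p_success_first))

  u <- c(s$utility_no_recurrence, s$utility_hepatic_recurrence,
         s$utility_other_recurrence, s$utility_death)
  cvec <- c(s$cost_no_recurrence_per_cycle, s$cost_recurrence_per_cycle,
            s$cost_recurrence_per_cycle, 0)
  hcc <- isTRUE(s$half_cycle_correction)

  occ <- c(1, 0, 0, 0)
  occ_mat <- matrix(0, nrow = n + 1L, ncol = 4L,
                    dimnames = list(NULL, STATES))
  occ_mat[1L, ] <- occ
  cost_inc <- numeric(n + 1L)
  qaly_inc <- numeric(n + 1L)
  cost_inc[1L] <- sr_cost   # acute treatment cost, undiscounted at time 0

  for (t in seq_len(n)) {
    age <- s$age_start + t - 1L
    P <- transition_matrix(strategy, s, table, t, age)
    occ2 <- as.vector(occ %*% P)
    memb <- if (hcc) 0.5 * (occ + occ2) else occ
    ut <- u
    if (t == 1L) {
      ut[1L] <- strategy$qol_first_month / 12 + (11 / 12) * s$utility_no_recurrence
    }
    disc <- (1 + s$discount_rate)^-(t - 1)
    cost_inc[t + 1L] <- disc * sum(memb * cvec)
    qaly_inc[t + 1L] <- disc * sum(memb * ut)
    occ <- occ2
    occ_mat[t + 1L, ] <- occ
  }

  list(
    expected_cost = sum(cost_inc),
    expected_qaly = sum(qaly_inc),
    occ = occ_mat,
    cost_inc = cost_inc,
    qaly_inc = qaly_inc,
    n_cycles = n
  )
}

#' Run the cohort model for one strategy
#'
#' Propagates the cohort occupancy through the annual-cycle Markov model
#' from `age_start` to `age_max` (or a shorter horizon), accruing
#' discounted costs and QALYs. The expected acute treatment cost enters
#' undiscounted at time 0; cycle `t` rewards are discounted by
#' `(1 + r)^-(t - 1)`. The first cycle blends one month at the strategy's
#' post-treatment utility with eleven months at the recurrence-free
#' utility; recurrence and death risks apply from cycle 1.
#'
#' @param strategy One strategy row (one-row data frame or named list).
#' @param settings `cea_settings`.
#' @param table `cea_lifetable`.
#' @param n_cycles Optional shorter horizon (number of annual cycles).
#' @return An object of class `cea_outcome`: a list with `strategy`,
#'   `expected_cost`, `expected_qaly` and `trace` (a tibble with one row
#'   per cycle 0..N holding the occupancy after that many transitions and
#'   the discounted increments accrued during the cycle).
#' @export
#' @examples
#' cfg <- base_case_config()
#' out <- run_cohort(cfg$strategies[1, ], cfg$settings, generate_lifetable())
#' c(out$expected_cost, out$expected_qaly)
run_cohort <- function(strategy, settings, table, n_cycles = NULL) {
  if (is.data.frame(strategy)) {
    stopifnot(nrow(strategy) == 1L)
    strategy <- as.list(strategy)
  }
  res <- cohort_engine(strategy, settings, table, n_cycles)
  n <- res$n_cycles
  trace <- tibble::tibble(
    cycle = 0:n,
    age = settings$age_start + 0:n,
    occ_no_recurrence = res$occ[, 1L],
    occ_hepatic = res$occ[, 2L],
    occ_other = res$occ[, 3L],
    occ_death = res$occ[, 4L],
    cost_increment = res$cost_inc,
    qaly_increment = res$qaly_inc
  )
  structure(
    list(strategy = strategy$name, expected_cost = res$expected_cost,
         expected_qaly = res$expected_qaly, trace = trace),
    class = "cea_outcome"
  )
}

#' @export
print.cea_outcome <- function(x, ...) {
  cat(sprintf("<cea_outcome> %s: cost %.2f USD, %.4f QALYs over %d cycles\n",
              x$strategy, x$expected_cost, x$expected_qaly,
              max(x$trace$cycle)))
  invisible(x)
}

#' Run the cohort model for every strategy in a configuration
#'
#' @param config A `cea_config`.
#' @param table A `cea_lifetable`.
#' @param n_cycles Optional shorter horizon.
#' @return A tibble of class `cea_outcomes` with columns `strategy`,
#'   `cost`, `qaly` and a `trace` list-column, one row per strategy in
#'   configuration order. The settings used are kept in the `settings`
#'   attribute.
#' @export
#' @examples
#' run_all(base_case_config(), generate_lifetable())
run_all <- function(config, table, n_cycles = NULL) {
  validate_config(config)
  outs <- lapply(seq_len(nrow(config$strategies)), function(i) {
    run_cohort(config$strategies[i, ], config$settings, table, n_cycles)
  })
  res <- tibble::tibble(
    strategy = vapply(outs, `[[`, character(1), "strategy"),
    cost = vapply(outs, `[[`, numeric(1), "expected_cost"),
    qaly = vapply(outs, `[[`, numeric(1), "expected_qaly"),
    trace = lapply(outs, `[[`, "trace")
  )
  attr(res, "settings") <- config$settings
  class(res) <- c("cea_outcomes", class(res))
  res
}

#' @export
tidy.cea_outcomes <- function(x, ...) {
  tibble::as_tibble(x[, c("strategy", "cost", "qaly")])
}

#' @export
glance.cea_outcomes <- function(x, ...) {
  tibble::tibble(
    n_strategies = nrow(x),
    min_cost_strategy = x$strategy[which.min(x$cost)],
    max_qaly_strategy = x$strategy[which.max(x$qaly)]
  )
}

#' Export a cohort trace as CSV
#'
#' Writes the per-cycle trace (`cycle`, `age`, the four occupancy columns,
#' and the discounted cost and QALY increments) of a [run_cohort()] result.
#'
#' @param outcome A `cea_outcome`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(outcome, path) {
  stopifnot(inherits(outcome, "cea_outcome"))
  readr::write_csv(outcome$trace, path)
  invisible(path)
}
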