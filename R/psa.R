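#' Method-of-moments uncertainty distribution
#'
#' Builds the parametric distribution used in probabilistic sensitivity
#' analysis: beta for probabilities and utilities, gamma for costs, with
#' shape parameters recovered from a mean and standard error by the method
#' of moments. Beta: `nu = mean(1 - mean)/se^2 - 1`, `shape1 = mean * nu`,
#' `shape2 = (1 - mean) * nu` (requires `se^2 < mean(1 - mean)`). Gamma:
#' `shape = (mean/se)^2`, `scale = se^2/mean`.
#'
#' @param mean Distribution mean (in `(0, 1)` for beta, > 0 for gamma).
#' @param se Standard error, > 0.
#' @param family `"beta"` or `"gamma"`.
#' @return A list of class `cea_distribution` with the family, moments and
#'   derived parameters.
#' @export
#' @examples
#' make_distribution(0.5, 0.1, "beta")   # shape1 = shape2 = 12
#' make_distribution(855, 171, "gamma")  # shape 25, scale 34.2
make_distribution <- function(mean, se, family = c("beta", "gamma")) {
  family <- match.arg(family)
  if (!is.finite(se) || se <= 0) {
    rlang::abort("`se` must be positive.", class = "cea_validation_error")
  }
  if (family == "beta") {
    if (!is.finite(mean) || mean <= 0 || mean >= 1) {
      rlang::abort("beta: `mean` must lie strictly inside (0, 1).",
                   class = "cea_validation_error")
    }
    if (se^2 >= mean * (1 - mean)) {
      rlang::abort("beta: requires se^2 < mean * (1 - mean).",
                   class = "cea_validation_error")
    }
    nu <- mean * (1 - mean) / se^2 - 1
    out <- list(family = "beta", mean = mean, se = se,
                shape1 = mean * nu, shape2 = (1 - mean) * nu)
  } else {
    if (!is.finite(mean) || mean <= 0) {
      rlang::abort("gamma: `mean` must be positive.", class = "cea_validation_error")
    }
    out <- list(family = "gamma", mean = mean, se = se,
                shape = (mean / se)^2, scale = se^2 / mean)
  }
  structure(out, class = "cea_distribution")
}

# One random variate given a mean and a relative spread. Beta means use
# se = spread * min(mean, 1 - mean) so that means near either boundary stay
# feasible; gamma means use se = spread * mean. Means exactly on a beta
# boundary (0 or 1) are degenerate and returned unchanged without consuming
# randomness.
draw_beta1 <- function(mean, spread) {
  if (mean <= 0 || mean >= 1) return(mean)
  d <- make_distribution(mean, spread * min(mean, 1 - mean), "beta")
  stats::rbeta(1, d$shape1, d$shape2)
}

draw_gamma1 <- function(mean, spread) {
  if (mean <= 0) return(mean)
  d <- make_distribution(mean, spread * mean, "gamma")
  stats::rgamma(1, shape = d$shape, scale = d$scale)
}

# Single source of truth for one PSA parameter draw. Shared parameters are
# drawn once; strategy-specific parameters per strategy, in configuration
# order. Structural constants (discount rate, ages, WTP, second-session
# success, hospital days) are never drawn. Returns list(settings, strategies).
draw_row <- function(config, spread, seed, draw_success = TRUE) {
  set.seed(as.integer(seed))
  s <- config$settings
  st <- config$strategies

  s$cost_per_hospital_day <- draw_gamma1(s$cost_per_hospital_day, spread)
  s$cost_no_recurrence_per_cycle <- draw_gamma1(s$cost_no_recurrence_per_cycle, spread)
  s$cost_recurrence_per_cycle <- draw_gamma1(s$cost_recurrence_per_cycle, spread)
  s$utility_no_recurrence <- draw_beta1(s$utility_no_recurrence, spread)
  s$utility_hepatic_recurrence <- draw_beta1(s$utility_hepatic_recurrence, spread)
  s$utility_other_recurrence <- draw_beta1(s$utility_other_recurrence, spread)
  s$p_death_hepatic_recurrence <- draw_beta1(s$p_death_hepatic_recurrence, spread)
  s$p_death_other_recurrence <- draw_beta1(s$p_death_other_recurrence, spread)
  p_other_shared <- draw_beta1(st$p_other_recurrence[1], spread)

  st$p_other_recurrence <- rep(p_other_shared, nrow(st))
  for (i in seq_len(nrow(st))) {
    if (draw_success) {
      st$p_success_first[i] <- draw_beta1(st$p_success_first[i], spread)
    }
    st$acute_procedure_cost[i] <- draw_gamma1(st$acute_procedure_cost[i], spread)
    st$qol_first_month[i] <- draw_beta1(st$qol_first_month[i], spread)
    st$mortality_year1[i] <- draw_beta1(st$mortality_year1[i], spread)
    st$p_hepatic_recurrence[i] <- draw_beta1(st$p_hepatic_recurrence[i], spread)
  }
  list(settings = s, strategies = st)
}

#' Draw one random parameter set for probabilistic sensitivity analysis
#'
#' Replaces every uncertain parameter by one draw from its method-of-moments
#' distribution: gamma for costs, beta for probabilities and utilities, with
#' standard error `spread * mean` (gamma) or `spread * min(mean, 1 - mean)`
#' (beta). Shared parameters (hospital per-diem, state costs and utilities,
#' recurrence-state mortality, non-hepatic recurrence) receive a single
#' common draw across strategies; strategy-specific parameters are drawn
#' per strategy. Structural constants — discount rate, ages, WTP,
#' second-session success, hospital days — are not drawn. Deterministic
#' given `seed`.
#'
#' @param config A `cea_config`.
#' @param spread Relative spread of each distribution (default 0.2).
#' @param seed Integer seed.
#' @param draw_success Draw the first-session success probabilities too
#'   (default `TRUE`).
#' @return A validated `cea_config` with drawn parameter values.
#' @export
draw_parameters <- function(config, spread = 0.2, seed, draw_success = TRUE) {
  validate_config(config)
  if (!is.finite(spread) || spread <= 0) {
    rlang::abort("`spread` must be positive.", class = "cea_validation_error")
  }
  d <- draw_row(config, spread, seed, draw_success)
  new_config(d$settings, d$strategies)
}

# Evaluate all PSA iterations for one strategy with iteration-vectorised
# occupancy recursion (each state has at most three outgoing arcs, so the
# full matrix product is unnecessary). Arguments are vectors of length n
# over iterations; shared settings draws arrive the same way.
psa_eval_strategy <- function(p, sh, base_settings, qx) {
  s <- base_settings
  n_iter <- length(p$p_success_first)
  n <- s$age_max - s$age_start
  hcc <- isTRUE(s$half_cycle_correction)
  bg <- isTRUE(s$background_mortality_in_recurrence)

  total <- p$acute_procedure_cost + p$hospital_days * sh$cost_per_hospital_day
  cost <- total * (1 + (1 - p$p_success_first))
  qaly <- numeric(n_iter)

  no <- rep(1, n_iter); hep <- numeric(n_iter); oth <- numeric(n_iter)
  for (t in seq_len(n)) {
    q <- qx[t]
    d_no <- if (t == 1L) p$mortality_year1 else rep(q, n_iter)
    stay <- 1 - d_no - p$p_hepatic_recurrence - sh$p_other_recurrence
    if (any(stay < -1e-12)) {
      rlang::abort("PSA draw: outgoing probability from the recurrence-free state exceeds 1.",
                   class = "cea_validation_error")
    }
    if (bg) {
      d_hep <- 1 - (1 - q) * (1 - sh$p_death_hepatic_recurrence)
      d_oth <- 1 - (1 - q) * (1 - sh$p_death_other_recurrence)
    } else {
      d_hep <- sh$p_death_hepatic_recurrence
      d_oth <- sh$p_death_other_recurrence
    }
    no2 <- no * pmax(stay, 0)
    hep2 <- hep * (1 - d_hep) + no * p$p_hepatic_recurrence
    oth2 <- oth * (1 - d_oth) + no * sh$p_other_recurrence

    m_no <- if (hcc) 0.5 * (no + no2) else no
    m_hep <- if (hcc) 0.5 * (hep + hep2) else hep
    m_oth <- if (hcc) 0.5 * (oth + oth2) else oth

    u_no <- if (t == 1L) {
      p$qol_first_month / 12 + (11 / 12) * sh$utility_no_recurrence
    } else {
      sh$utility_no_recurrence
    }
    disc <- (1 + s$discount_rate)^-(t - 1)
    qaly <- qaly + disc * (m_no * u_no + m_hep * sh$utility_hepatic_recurrence +
                             m_oth * sh$utility_other_recurrence)
    cost <- cost + disc * (m_no * sh$cost_no_recurrence_per_cycle +
                             (m_hep + m_oth) * sh$cost_recurrence_per_cycle)
    no <- no2; hep <- hep2; oth <- oth2
  }
  list(cost = cost, qaly = qaly)
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` random parameter sets (iteration `i` uses seed `seed + i`, so
#' any subset of iterations is reproducible independently) and evaluates
#' the cohort model for every strategy under each draw.
#'
#' @param config A `cea_config`.
#' @param table A `cea_lifetable`.
#' @param n Number of Monte Carlo iterations (the study design uses
#'   30,000).
#' @param seed Integer master seed.
#' @param spread Relative spread of the uncertainty distributions
#'   (default 0.2).
#' @param draw_success Draw first-session success probabilities
#'   (default `TRUE`).
#' @return An object of class `cea_psa`: list with `draws` (tibble
#'   `iteration`, `strategy`, `cost`, `qaly`, ordered by iteration then
#'   strategy), `n`, `seed`, `spread` and the `settings` used.
#' @export
#' @examples
#' psa <- run_psa(base_case_config(), generate_lifetable(), n = 50, seed = 1)
#' glance(psa)
run_psa <- function(config, table, n, seed, spread = 0.2, draw_success = TRUE) {
  validate_config(config)
  stopifnot(n >= 1)
  strat_names <- config$strategies$name
  n_strat <- length(strat_names)

  shared_keys <- c("cost_per_hospital_day", "cost_no_recurrence_per_cycle",
                   "cost_recurrence_per_cycle", "utility_no_recurrence",
                   "utility_hepatic_recurrence", "utility_other_recurrence",
                   "p_death_hepatic_recurrence", "p_death_other_recurrence")
  strat_keys <- c("p_success_first", "acute_procedure_cost", "qol_first_month",
                  "mortality_year1", "p_hepatic_recurrence")

  sh <- lapply(setNames(shared_keys, shared_keys), function(k) numeric(n))
  sh$p_other_recurrence <- numeric(n)
  per <- lapply(setNames(strat_names, strat_names), function(nm) {
    c(lapply(setNames(strat_keys, strat_keys), function(k) numeric(n)),
      list(hospital_days = numeric(n)))
  })
  for (i in seq_len(n)) {
    d <- draw_row(config, spread, seed + i, draw_success)
    for (k in shared_keys) sh[[k]][i] <- d$settings[[k]]
    sh$p_other_recurrence[i] <- d$strategies$p_other_recurrence[1]
    for (j in seq_len(n_strat)) {
      nm <- strat_names[j]
      for (k in strat_keys) per[[nm]][[k]][i] <- d$strategies[[k]][j]
      per[[nm]]$hospital_days[i] <- d$strategies$hospital_days[j]
    }
  }

  qx <- qx_at(table, config$settings$age_start +
                seq_len(config$settings$age_max - config$settings$age_start) - 1L)
  evals <- lapply(strat_names, function(nm) {
    psa_eval_strategy(per[[nm]], sh, config$settings, qx)
  })
  draws <- tibble::tibble(
    iteration = rep(seq_len(n), times = n_strat),
    strategy = rep(strat_names, each = n),
    cost = unlist(lapply(evals, `[[`, "cost")),
    qaly = unlist(lapply(evals, `[[`, "qaly"))
  )
  draws <- dplyr::arrange(draws, .data$iteration, match(.data$strategy, strat_names))
  structure(list(draws = draws, n = n, seed = seed, spread = spread,
                 settings = config$settings),
            class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("<cea_psa> %d iterations, seed %d, spread %.0f%%\n",
              x$n, x$seed, 100 * x$spread))
  print(glance(x))
  invisible(x)
}

#' @export
tidy.cea_psa <- function(x, ...) x$draws

#' @export
glance.cea_psa <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$draws, .data$strategy),
                   mean_cost = mean(.data$cost),
                   mean_qaly = mean(.data$qaly),
                   .groups = "drop")
}

#' Cost-effectiveness acceptability curves
#'
#' For every willingness-to-pay value on a grid, the fraction of PSA
#' iterations in which each strategy attains the maximal net monetary
#' benefit. NMB ties are broken toward the lower-cost strategy, then
#' toward the earlier strategy in configuration order. The fractions
#' partition the iterations, so they sum to 1 at every grid point.
#'
#' @param result A `cea_psa`.
#' @param wtp_grid Numeric WTP grid, USD/QALY (default 0 to 200,000 in
#'   steps of 5,000).
#' @return A tibble of class `cea_ceac` with columns `wtp`, `strategy`,
#'   `probability`.
#' @export
#' @examples
#' psa <- run_psa(base_case_config(), generate_lifetable(), n = 50, seed = 1)
#' ceac(psa, wtp_grid = c(0, 5e4, 1e5))
ceac <- function(result, wtp_grid = seq(0, 2e5, by = 5000)) {
  stopifnot(inherits(result, "cea_psa"), length(wtp_grid) >= 1, result$n >= 1)
  strat_names <- unique(result$draws$strategy)
  k <- length(strat_names)
  costm <- matrix(result$draws$cost[order(match(result$draws$strategy, strat_names),
                                          result$draws$iteration)],
                  ncol = k, dimnames = list(NULL, strat_names))
  qalym <- matrix(result$draws$qaly[order(match(result$draws$strategy, strat_names),
                                          result$draws$iteration)],
                  ncol = k, dimnames = list(NULL, strat_names))

  rows <- lapply(wtp_grid, function(w) {
    nmbm <- w * qalym - costm
    rmax <- do.call(pmax, as.data.frame(nmbm))
    best <- nmbm == rmax
    cmin <- do.call(pmin, as.data.frame(ifelse(best, costm, Inf)))
    pick <- best & (costm == cmin)
    winner <- max.col(pick, ties.method = "first")
    tibble::tibble(wtp = w, strategy = strat_names,
                   probability = tabulate(winner, nbins = k) / nrow(nmbm))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cea_ceac", class(tibble::tibble()))
  out
}

#' Write PSA draws as CSV
#'
#' Columns `iteration`, `strategy`, `cost`, `qaly`; deterministic row order
#' (iteration, then configuration strategy order).
#'
#' @param result A `cea_psa`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_psa <- function(result, path) {
  stopifnot(inherits(result, "cea_psa"))
  readr::write_csv(result$draws, path)
  invisible(path)
}

#' Write acceptability curves as CSV
#'
#' @param curves A `cea_ceac` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ceac <- function(curves, path) {
  stopifnot(inherits(curves, "cea_ceac"))
  readr::write_csv(curves, path)
  invisible(path)
}
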