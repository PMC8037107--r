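#' Shared model settings
#'
#' Economics and health-state parameters shared by all treatment strategies.
#' Defaults are the base case: a 73-year-old cohort followed to age 100 with
#' annual cycles, 3% discounting, a willingness to pay of USD 100,000 per
#' QALY, Medicare-derived hospital per-diem, and the long-term state costs
#' and utilities of the four-state recurrence model.
#'
#' Two conventions of the cycle arithmetic are exposed as switches rather
#' than hard-coded:
#'
#' * `half_cycle_correction` — when `TRUE` (default) each cycle's cost and
#'   QALY reward is accrued on the average of start-of-cycle and
#'   end-of-cycle state membership; when `FALSE`, on start-of-cycle
#'   membership alone.
#' * `background_mortality_in_recurrence` — when `TRUE` the annual death
#'   probability in the recurrence states combines the state-specific
#'   probability with the life-table background as independent competing
#'   risks, `1 - (1 - qx)(1 - q_state)`; when `FALSE` (default) the
#'   state-specific probability is used alone.
#'
#' @param age_start Starting (attained) age of the cohort, years.
#' @param age_max Age at which the model horizon ends, years.
#' @param discount_rate Annual discount rate applied to costs and QALYs.
#' @param wtp Willingness to pay, USD per QALY.
#' @param cost_per_hospital_day USD per inpatient day.
#' @param cost_no_recurrence_per_cycle Long-term cost accrued per annual
#'   cycle spent recurrence-free, USD.
#' @param cost_recurrence_per_cycle Long-term cost accrued per annual cycle
#'   spent in either recurrence state, USD.
#' @param utility_no_recurrence,utility_hepatic_recurrence,utility_other_recurrence,utility_death
#'   State utilities in `[0, 1]`.
#' @param p_death_hepatic_recurrence Annual death probability in the
#'   hepatic-only recurrence state.
#' @param p_death_other_recurrence Annual death probability in the
#'   any-other-recurrence state.
#' @param p_success_second_session Probability that a repeat session after
#'   an incomplete first treatment is complete.
#' @param half_cycle_correction Logical, see Details.
#' @param background_mortality_in_recurrence Logical, see Details.
#'
#' @return A named list of class `cea_settings`.
#' @export
#' @examples
#' model_settings()$wtp
model_settings <- function(age_start = 73,
                           age_max = 100,
                           discount_rate = 0.03,
                           wtp = 1e5,
                           cost_per_hospital_day = 2424,
                           cost_no_recurrence_per_cycle = 855,
                           cost_recurrence_per_cycle = 3935,
                           utility_no_recurrence = 1,
                           utility_hepatic_recurrence = 0.65,
                           utility_other_recurrence = 0.19,
                           utility_death = 0,
                           p_death_hepatic_recurrence = 0.12,
                           p_death_other_recurrence = 0.05,
                           p_success_second_session = 1,
                           half_cycle_correction = TRUE,
                           background_mortality_in_recurrence = FALSE) {
  s <- as.list(environment())
  structure(s, class = "cea_settings")
}

#' Built-in base-case model configuration
#'
#' The complete base-case parameter set: three strategies (surgery, RFA,
#' MWA) with their first-session success probabilities, acute procedure
#' costs, hospital stays, one-month post-treatment utilities, one-year
#' mortality and annual recurrence probabilities, together with the shared
#' [model_settings()].
#'
#' @param settings A `cea_settings` list; defaults to [model_settings()].
#' @return A list of class `cea_config` with elements `settings` (a
#'   `cea_settings` list) and `strategies` (a tibble, one row per strategy).
#' @export
#' @examples
#' cfg <- base_case_config()
#' cfg$strategies
base_case_config <- function(settings = model_settings()) {
  strategies <- tibble::tibble(
    name = c("surgery", "RFA", "MWA"),
    p_success_first = c(0.99, 0.93, 0.97),
    acute_procedure_cost = c(2421, 1493, 1493),
    hospital_days = c(7L, 4L, 4L),
    qol_first_month = c(0.70, 0.95, 0.95),
    mortality_year1 = c(0.0825, 0.06, 0.055),
    p_hepatic_recurrence = c(0.025, 0.077, 0.04),
    p_other_recurrence = c(0.05, 0.05, 0.05)
  )
  new_config(settings, strategies)
}

new_config <- function(settings, strategies) {
  cfg <- structure(
    list(settings = settings, strategies = tibble::as_tibble(strategies)),
    class = "cea_config"
  )
  validate_config(cfg)
}

#' Validate a model configuration
#'
#' Checks every invariant: probabilities and utilities in `[0, 1]`,
#' non-negative costs and hospital days, death utility zero, discount rate
#' in `[0, 1)`, `age_start < age_max`, exactly three distinct strategy
#' names, and for each strategy a total outgoing probability from the
#' recurrence-free state (year-1 mortality plus both recurrence
#' probabilities) of at most 1.
#'
#' @param config A `cea_config` list.
#' @return `config`, invisibly unchanged, if valid; otherwise an error
#'   naming the offending field.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "cea_config")) {
    rlang::abort("`config` must be a `cea_config` object.", class = "cea_validation_error")
  }
  s <- config$settings
  st <- config$strategies

  needed_settings <- names(formals(model_settings))
  missing_s <- setdiff(needed_settings, names(s))
  if (length(missing_s)) {
    rlang::abort(paste0("settings: missing key(s): ", paste(missing_s, collapse = ", ")),
                 class = "cea_schema_error")
  }
  needed_strat <- c("name", "p_success_first", "acute_procedure_cost", "hospital_days",
                    "qol_first_month", "mortality_year1", "p_hepatic_recurrence",
                    "p_other_recurrence")
  missing_f <- setdiff(needed_strat, names(st))
  if (length(missing_f)) {
    rlang::abort(paste0("strategies: missing column(s): ", paste(missing_f, collapse = ", ")),
                 class = "cea_schema_error")
  }

  chk_prob <- function(x, key) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      rlang::abort(sprintf("`%s` must lie in [0, 1].", key), class = "cea_validation_error")
    }
  }
  chk_nonneg <- function(x, key) {
    if (any(!is.finite(x)) || any(x < 0)) {
      rlang::abort(sprintf("`%s` must be non-negative.", key), class = "cea_validation_error")
    }
  }

  for (key in c("utility_no_recurrence", "utility_hepatic_recurrence",
                "utility_other_recurrence", "utility_death",
                "p_death_hepatic_recurrence", "p_death_other_recurrence",
                "p_success_second_session")) {
    chk_prob(s[[key]], key)
  }
  if (s$utility_death != 0) {
    rlang::abort("`utility_death` must be 0.", class = "cea_validation_error")
  }
  if (!is.finite(s$discount_rate) || s$discount_rate < 0 || s$discount_rate >= 1) {
    rlang::abort("`discount_rate` must lie in [0, 1).", class = "cea_validation_error")
  }
  if (s$age_start >= s$age_max) {
    rlang::abort("`age_start` must be below `age_max`.", class = "cea_validation_error")
  }
  for (key in c("wtp", "cost_per_hospital_day", "cost_no_recurrence_per_cycle",
                "cost_recurrence_per_cycle")) {
    chk_nonneg(s[[key]], key)
  }

  if (nrow(st) != 3L || anyDuplicated(st$name)) {
    rlang::abort("`strategies` must hold exactly three distinct strategy names.",
                 class = "cea_validation_error")
  }
  for (key in c("p_success_first", "qol_first_month", "mortality_year1",
                "p_hepatic_recurrence", "p_other_recurrence")) {
    chk_prob(st[[key]], key)
  }
  chk_nonneg(st$acute_procedure_cost, "acute_procedure_cost")
  chk_nonneg(st$hospital_days, "hospital_days")

  out_sum <- st$mortality_year1 + st$p_hepatic_recurrence + st$p_other_recurrence
  if (any(out_sum > 1)) {
    bad <- st$name[out_sum > 1][1]
    rlang::abort(
      sprintf("strategy '%s': mortality + recurrence probabilities exceed 1 (%.4f).",
              bad, max(out_sum)),
      class = "cea_validation_error"
    )
  }
  invisible(config)
}

#' Total treatment cost per strategy
#'
#' Acute procedure cost plus hospital stay: `acute_procedure_cost +
#' hospital_days * cost_per_hospital_day`. Reproduces the calculated total
#' treatment costs of the base case (USD 19,389 for surgery, USD 11,189 for
#' RFA and MWA).
#'
#' @param strategies A strategy tibble (as in `cea_config$strategies`) or a
#'   full `cea_config`.
#' @param settings A `cea_settings` list; taken from `strategies` when a
#'   `cea_config` is given.
#' @return A tibble with columns `name` and `total_cost` (USD).
#' @export
#' @examples
#' total_treatment_cost(base_case_config())
total_treatment_cost <- function(strategies, settings = NULL) {
  if (inherits(strategies, "cea_config")) {
    settings <- strategies$settings
    strategies <- strategies$strategies
  }
  if (is.null(settings)) {
    rlang::abort("`settings` must be supplied when `strategies` is a bare table.")
  }
  tibble::tibble(
    name = strategies$name,
    total_cost = strategies$acute_procedure_cost +
      strategies$hospital_days * settings$cost_per_hospital_day
  )
}

#' Read a model configuration from YAML or JSON
#'
#' The file must carry two top-level keys, `settings` and `strategies`,
#' whose fields mirror [model_settings()] and the columns of
#' `base_case_config()$strategies`. A bundled example encoding the base
#' case ships as `system.file("extdata", "base_case.yaml", package =
#' "ablatecea")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `cea_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("config file not found: %s", path), class = "cea_input_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (key in c("settings", "strategies")) {
    if (is.null(raw[[key]])) {
      rlang::abort(sprintf("config file: missing key '%s'.", key), class = "cea_schema_error")
    }
  }
  defaults <- model_settings()
  unknown <- setdiff(names(raw$settings), names(defaults))
  if (length(unknown)) {
    rlang::abort(paste0("settings: unknown key(s): ", paste(unknown, collapse = ", ")),
                 class = "cea_schema_error")
  }
  settings <- structure(utils::modifyList(unclass(defaults), raw$settings),
                        class = "cea_settings")
  strategies <- if (is.data.frame(raw$strategies)) {
    tibble::as_tibble(raw$strategies)
  } else {
    dplyr::bind_rows(lapply(raw$strategies, tibble::as_tibble))
  }
  new_config(settings, strategies)
}

#' Write a model configuration to YAML or JSON
#'
#' @param config A `cea_config`.
#' @param path Output path; format chosen by extension (`.json` else YAML).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  x <- list(
    settings = unclass(config$settings),
    strategies = lapply(seq_len(nrow(config$strategies)),
                        function(i) as.list(config$strategies[i, ]))
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

#' @export
print.cea_config <- function(x, ...) {
  s <- x$settings
  cat("<cea_config>\n")
  cat(sprintf("  ages %d-%d, discount %.1f%%, WTP %s/QALY\n",
              s$age_start, s$age_max, 100 * s$discount_rate,
              format(s$wtp, big.mark = ",")))
  cat(sprintf("  conventions: half-cycle correction %s, background mortality in recurrence %s\n",
              if (s$half_cycle_correction) "on" else "off",
              if (s$background_mortality_in_recurrence) "on" else "off"))
  print(x$strategies)
  invisible(x)
}
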