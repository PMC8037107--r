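# Life tables built in code for deterministic engine checks.

flat_lifetable <- function(q, ages = 0:100) {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(age = ages, qx = q), path)
  on.exit(unlink(path))
  read_lifetable(path)
}

zero_lifetable <- function() flat_lifetable(0)

# One-strategy settings tweak helper: returns base config with settings
# fields overridden.
tweak_config <- function(config = base_case_config(), ...) {
  over <- list(...)
  config$settings[names(over)] <- over
  validate_config(config)
  config
}

# Independent closed-form oracle for the no-recurrence constant-hazard
# cohort: utility 1 after the first cycle, first cycle blends one month at
# qol1. Start-of-cycle accrual (no half-cycle correction), discounting
# (1 + r)^-(t - 1), death probability q every cycle (including cycle 1).
annuity_qaly <- function(q, r, n, qol1 = 1) {
  blend <- qol1 / 12 + 11 / 12
  surv <- (1 - q)^(0:(n - 1))        # alive at start of cycle t
  disc <- (1 + r)^-(0:(n - 1))
  u <- c(blend, rep(1, n - 1))
  sum(surv * disc * u)
}
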