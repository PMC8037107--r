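#' Read an annual life table
#'
#' Reads a two-column CSV (`age,qx`, header required, one row per integer
#' age) giving the one-year death probability `qx` conditional on being
#' alive at exact age `age`. Ages must be contiguous, every `qx` in
#' `[0, 1]`, and coverage must include at least ages 60 through 100 so the
#' model horizon is always answerable.
#'
#' Queries above the table's last age return 1 (certain death), which keeps
#' the model horizon finite.
#'
#' @param path Path to the CSV file.
#' @return A tibble of class `cea_lifetable` with columns `age` and `qx`.
#' @seealso [qx_at()], [generate_lifetable()], [us_lifetable()]
#' @export
read_lifetable <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("life table not found: %s", path), class = "cea_input_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    age = readr::col_integer(), qx = readr::col_double()
  ))
  new_lifetable(df)
}

new_lifetable <- function(df) {
  if (!all(c("age", "qx") %in% names(df))) {
    rlang::abort("life table needs columns `age` and `qx`.", class = "cea_schema_error")
  }
  df <- dplyr::arrange(tibble::as_tibble(df[c("age", "qx")]), .data$age)
  if (nrow(df) < 2L || any(diff(df$age) != 1L)) {
    rlang::abort("life table ages must be contiguous integers.", class = "cea_validation_error")
  }
  if (any(!is.finite(df$qx)) || any(df$qx < 0) || any(df$qx > 1)) {
    rlang::abort("life table `qx` values must lie in [0, 1].", class = "cea_validation_error")
  }
  if (min(df$age) > 60 || max(df$age) < 100) {
    rlang::abort("life table must cover at least ages 60 through 100.",
                 class = "cea_validation_error")
  }
  class(df) <- c("cea_lifetable", class(tibble::tibble()))
  df
}

#' Annual death probability at an attained age
#'
#' @param table A `cea_lifetable`.
#' @param age Integer age(s) in years; must not fall below the table's
#'   first age. Ages beyond the last tabulated age return 1.
#' @return Numeric vector of one-year death probabilities.
#' @export
#' @examples
#' lt <- generate_lifetable()
#' qx_at(lt, 73)
qx_at <- function(table, age) {
  stopifnot(inherits(table, "cea_lifetable"))
  if (any(age < min(table$age))) {
    rlang::abort(sprintf("age below the table's first age (%d).", min(table$age)),
                 class = "cea_input_error")
  }
  idx <- match(age, table$age)
  out <- table$qx[idx]
  out[is.na(idx)] <- 1
  out
}

#' Write a life table CSV
#'
#' Writes the same `age,qx` dialect that [read_lifetable()] consumes.
#'
#' @param table A `cea_lifetable`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lifetable <- function(table, path) {
  stopifnot(inherits(table, "cea_lifetable"))
  readr::write_csv(table, path)
  invisible(path)
}

#' Bundled synthetic 2014-style US life table
#'
#' Loads the life table shipped with the package. The file is *synthetic*:
#' no machine-readable 2014 US period life table is bundled, so the table
#' is generated from the package's Gompertz hazard with parameters
#' calibrated so remaining life expectancy at age 73 is about 13 years —
#' the ballpark of the 2014 US all-sex period table. Substitute a real
#' national table via [read_lifetable()] for setting-specific analyses.
#'
#' @return A `cea_lifetable` covering ages 0 through 100.
#' @export
us_lifetable <- function() {
  read_lifetable(system.file("extdata", "lifetable_us2014_synthetic.csv",
                             package = "ablatecea", mustWork = TRUE))
}
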