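## Shared helpers: code syntax, age/decade/window conventions, schema checks.

# level-3 ICD-10 code: chapter letter + two digits, e.g. "E66", "F32"
is_icd3 <- function(code) {
  grepl("^[A-Z][0-9]{2}$", code)
}

#' Age decades used for stratification
#'
#' The analysis stratifies patients into seven decades of life, 10-19 through
#' 70-79; patients anchored outside this range are excluded from the cohort.
#'
#' @return Character vector of the seven decade labels.
#' @export
age_decades <- function() {
  sprintf("%d-%d", seq(10L, 70L, 10L), seq(19L, 79L, 10L))
}

decade_of_age <- function(age) {
  idx <- age %/% 10L
  out <- rep(NA_character_, length(age))
  ok <- !is.na(age) & idx >= 1L & idx <= 7L
  out[ok] <- sprintf("%d-%d", 10L * idx[ok], 10L * idx[ok] + 9L)
  out
}

#' Two-year calendar windows of the observation period
#'
#' @param start_year,end_year First and last calendar year covered (defaults
#'   2003 and 2014, the post-washout observation period).
#' @return Character vector of window labels, e.g. `"2003-04"`.
#' @export
calendar_windows <- function(start_year = 2003L, end_year = 2014L) {
  lo <- seq(as.integer(start_year), as.integer(end_year), by = 2L)
  sprintf("%d-%02d", lo, (lo + 1L) %% 100L)
}

window_of_date <- function(date, start_year = 2003L) {
  yr <- as.integer(format(date, "%Y"))
  lo <- start_year + 2L * ((yr - start_year) %/% 2L)
  sprintf("%d-%02d", lo, (lo + 1L) %% 100L)
}

# Age in completed years at `date` for a patient born in `birth_year`,
# under a fixed mid-year (July 1) birthday convention: the registry records
# the birth year only, so exact ages are unknowable; mid-year minimises the
# expected error and is applied identically in the generator and the cohort
# module.
age_at <- function(date, birth_year) {
  yr <- as.integer(format(date, "%Y"))
  before_birthday <- format(date, "%m-%d") < "07-01"
  yr - as.integer(birth_year) - as.integer(before_birthday)
}

registry_columns <- function() {
  c("patient_id", "sex", "birth_year", "stay_id",
    "admission_date", "release_date", "code")
}

check_registry <- function(events, arg = "events") {
  if (!is.data.frame(events)) {
    abort(sprintf("`%s` must be a data frame of diagnosis events.", arg))
  }
  missing <- setdiff(registry_columns(), names(events))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  arg, paste(missing, collapse = ", ")))
  }
  invisible(events)
}

# uniform integer day offsets in [0, span]; returns Date
runif_dates <- function(n, from, to) {
  span <- as.numeric(to - from)
  from + floor(runif(n) * (span + 1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
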