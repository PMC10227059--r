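## Cohort preparation: chapter filtering, washout exclusion, first
## occurrences, and anchor-based (age decade x calendar window) stratification.

#' Keep only diagnoses from selected ICD-10 chapters
#'
#' The analysis retains chapters A through N; chapters coding pregnancy,
#' perinatal conditions, malformations, unspecific findings, external causes
#' and health-service contacts (O-Z) are dropped. Row order is preserved.
#'
#' @param events Registry event tibble.
#' @param chapters Chapter letters to retain.
#' @return The filtered event tibble.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   patient_id = "P1", sex = "female", birth_year = 1980L, stay_id = "S1",
#'   admission_date = as.Date("2005-01-01"), release_date = as.Date("2005-01-03"),
#'   code = c("E66", "F32", "Z99", "O80")
#' )
#' filter_chapters(ev)$code
filter_chapters <- function(events, chapters = LETTERS[1:14]) {
  check_registry(events)
  bad <- which(!is_icd3(events$code))
  if (length(bad) > 0) {
    abort(sprintf("malformed diagnosis code(s) at row(s): %s",
                  paste(utils::head(bad, 5L), collapse = ", ")))
  }
  events[substr(events$code, 1L, 1L) %in% chapters, , drop = FALSE]
}

#' Apply the washout exclusion
#'
#' Removes — entirely, all-or-nothing — every patient with at least one
#' admission during the washout era, so the retained cohort had no inpatient
#' contact for the full washout span and enters the observation period with a
#' comparable baseline health status. Remaining events are restricted to the
#' observation period following the washout.
#'
#' @param events Registry event tibble.
#' @param washout_start,washout_end Washout span (defaults 1997-01-01 to
#'   2002-12-31).
#' @param observe_end Last date of the observation period retained
#'   (default 2014-12-31).
#' @return The event tibble restricted to washout-free patients and to
#'   admissions in `(washout_end, observe_end]`. The number of removed
#'   patients is attached as attribute `"n_washed_out"`.
#' @export
apply_washout <- function(events,
                          washout_start = as.Date("1997-01-01"),
                          washout_end = as.Date("2002-12-31"),
                          observe_end = as.Date("2014-12-31")) {
  check_registry(events)
  in_washout <- events$admission_date >= washout_start &
    events$admission_date <= washout_end
  washed <- unique(events$patient_id[in_washout])
  out <- events[!(events$patient_id %in% washed) &
                  events$admission_date > washout_end &
                  events$admission_date <= observe_end, , drop = FALSE]
  attr(out, "n_washed_out") <- length(washed)
  out
}

#' First occurrence of every diagnosis per patient
#'
#' One row per (patient, code) with the earliest admission date among stays
#' carrying the code; ties across same-date stays are broken by the smallest
#' `stay_id`. Idempotent: re-running on its own output is a no-op.
#'
#' @param events Registry event tibble (post-washout).
#' @return A tibble with columns `patient_id`, `code`, `first_date`,
#'   `first_stay_id`.
#' @export
first_occurrences <- function(events) {
  check_registry(events)
  o <- order(events$patient_id, events$code, events$admission_date,
             events$stay_id)
  ev <- events[o, , drop = FALSE]
  keep <- !duplicated(paste(ev$patient_id, ev$code, sep = "\r"))
  tibble(
    patient_id = ev$patient_id[keep],
    code = ev$code[keep],
    first_date = ev$admission_date[keep],
    first_stay_id = ev$stay_id[keep]
  )
}

#' Per-patient demographic and utilisation profile
#'
#' @param events Registry event tibble.
#' @return One row per patient: `patient_id`, `sex`, `birth_year`,
#'   `first_admission`, `n_stays`, `hospital_days` (inclusive
#'   release - admission + 1 summed over stays), `n_diagnoses` (distinct
#'   codes).
#' @export
patient_profiles <- function(events) {
  check_registry(events)
  if (any(is.na(events$birth_year))) {
    bad <- unique(events$patient_id[is.na(events$birth_year)])
    abort(sprintf("missing birth_year for patient(s): %s",
                  paste(utils::head(bad, 5L), collapse = ", ")))
  }
  # vectorized aggregation (this sits on the hot path of simulation studies)
  keep <- !duplicated(paste(events$patient_id, events$stay_id, sep = "\r"))
  sp <- events$patient_id[keep]
  adm <- events$admission_date[keep]
  rel <- events$release_date[keep]
  pid_f <- factor(sp)
  lev <- levels(pid_f)
  o <- order(sp, adm)
  first_of_pat <- !duplicated(sp[o])
  first_admission <- adm[o][first_of_pat]
  names(first_admission) <- sp[o][first_of_pat]
  days <- rowsum(as.numeric(rel - adm) + 1, pid_f)
  keep_code <- !duplicated(paste(events$patient_id, events$code,
                                 sep = "\r"))
  n_diag <- tabulate(factor(events$patient_id[keep_code], levels = lev),
                     nbins = length(lev))
  first_row <- !duplicated(events$patient_id)
  demo_pid <- events$patient_id[first_row]
  idx <- match(demo_pid, lev)
  tibble(
    patient_id = demo_pid,
    sex = events$sex[first_row],
    birth_year = events$birth_year[first_row],
    first_admission = unname(first_admission[demo_pid]),
    n_stays = tabulate(pid_f, nbins = length(lev))[idx],
    hospital_days = as.numeric(days[idx, 1L]),
    n_diagnoses = n_diag[idx]
  )
}

#' Assign each patient to a single (age decade, calendar window) stratum
#'
#' Each patient is anchored once: at the first occurrence of the exposure
#' code for exposed patients, at the first admission otherwise. The age
#' decade is the decade of life at the anchor date (mid-year birthday
#' convention) and the window is the 2-year calendar bin containing the
#' anchor. Anchoring once makes the strata disjoint, as required for valid
#' Mantel-Haenszel pooling; patients anchored outside decades 10-79 are
#' excluded and logged.
#'
#' @param firsts Output of [first_occurrences()].
#' @param profiles Output of [patient_profiles()].
#' @param exposure_code Index diagnosis code (default `"E66"`).
#' @param window_start_year First year of the observation period.
#' @return A tibble with one row per retained patient: `patient_id`,
#'   `exposed`, `anchor_date`, `age_decade`, `window`, `sex`. Excluded
#'   patients are recorded in attribute `"excluded"` (`patient_id`, `reason`)
#'   and the anchoring policy in attribute `"policy"`.
#' @export
assign_strata <- function(firsts, profiles, exposure_code = "E66",
                          window_start_year = 2003L) {
  exp_first <- firsts %>%
    filter(.data$code == exposure_code) %>%
    select("patient_id", exposure_date = "first_date")
  out <- profiles %>%
    left_join(exp_first, by = "patient_id") %>%
    mutate(
      exposed = !is.na(.data$exposure_date),
      anchor_date = dplyr::coalesce(.data$exposure_date,
                                    .data$first_admission),
      age_anchor = age_at(.data$anchor_date, .data$birth_year),
      age_decade = decade_of_age(.data$age_anchor),
      window = window_of_date(.data$anchor_date, window_start_year)
    )
  excluded <- out %>%
    filter(is.na(.data$age_decade)) %>%
    mutate(reason = sprintf("anchor age %d outside 10-79", .data$age_anchor)) %>%
    select("patient_id", "reason")
  res <- out %>%
    filter(!is.na(.data$age_decade)) %>%
    select("patient_id", "sex", "exposed", "anchor_date", "age_decade",
           "window")
  attr(res, "excluded") <- excluded
  attr(res, "policy") <- paste(
    "anchor=exposure_first_occurrence_else_first_admission",
    "age=completed_years_midyear_birthday",
    sep = ";"
  )
  res
}
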