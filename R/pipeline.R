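## End-to-end orchestration: cohort preparation, association screen,
## time-order analysis, sex and sensitivity runs, characteristics table and
## report bundle with a metadata sidecar.

#' Configure a full analysis run
#'
#' @param exposure_code Index diagnosis code.
#' @param comorbidity_codes Codes screened against the index diagnosis.
#' @param min_occurrence,or_threshold,alpha Screening thresholds.
#' @param gap_edges Ascending day thresholds for the time-order gap classes.
#' @param conf_level Confidence level for pooled odds ratios.
#' @param sensitivity_codes Codes triggering patient removal in the
#'   sensitivity analysis.
#' @param washout_start,washout_end,observe_end Cohort period boundaries.
#' @param seed Optional integer recorded in run metadata (and used by the
#'   `simulate` CLI subcommand).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(exposure_code = "E66",
                       comorbidity_codes = c("F32", "F33", "F41"),
                       min_occurrence = 100,
                       or_threshold = 1.5,
                       alpha = 0.01,
                       gap_edges = c(360L, 1080L),
                       conf_level = 0.95,
                       sensitivity_codes = c("E11", "I10", "I25"),
                       washout_start = as.Date("1997-01-01"),
                       washout_end = as.Date("2002-12-31"),
                       observe_end = as.Date("2014-12-31"),
                       seed = NULL) {
  if (min_occurrence <= 0 || or_threshold <= 0 || alpha <= 0) {
    abort("thresholds must be positive.")
  }
  if (is.unsorted(gap_edges, strictly = TRUE) || any(gap_edges <= 0)) {
    abort("gap_edges must be strictly ascending positive day counts.")
  }
  if (!is_icd3(exposure_code) || any(!is_icd3(comorbidity_codes))) {
    abort("codes must be level-3 ICD-10 strings.")
  }
  structure(
    list(
      exposure_code = exposure_code,
      comorbidity_codes = comorbidity_codes,
      min_occurrence = min_occurrence,
      or_threshold = or_threshold,
      alpha = alpha,
      gap_edges = as.integer(gap_edges),
      conf_level = conf_level,
      sensitivity_codes = sensitivity_codes,
      washout_start = as.Date(washout_start),
      washout_end = as.Date(washout_end),
      observe_end = as.Date(observe_end),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Field names mirror [run_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (fld in c("washout_start", "washout_end", "observe_end")) {
    if (!is.null(raw[[fld]])) raw[[fld]] <- as.Date(raw[[fld]])
  }
  do.call(run_config, raw)
}

#' Cohort characteristics table
#'
#' Per exposure status and sex (plus a pooled `total` row per status):
#' subject counts, mean and SD of age at anchor, stays per patient, hospital
#' days (release - admission + 1, summed over stays), distinct diagnoses per
#' patient, and co-diagnosis percentages for a configured code list. Empty
#' groups are emitted with a zero count and missing statistics.
#'
#' @param events Registry event tibble (post-washout).
#' @param exposure_code Index diagnosis code.
#' @param codes Codes whose co-diagnosis percentage is reported.
#' @param strata Optional precomputed [assign_strata()] output.
#' @return A tibble with one row per (exposure status, sex group).
#' @export
summarize_table1 <- function(events, exposure_code = "E66",
                             codes = character(0), strata = NULL) {
  firsts <- first_occurrences(events)
  profiles <- patient_profiles(events)
  if (is.null(strata)) {
    strata <- assign_strata(firsts, profiles, exposure_code)
  }
  base <- strata %>%
    left_join(profiles %>%
                select("patient_id", "birth_year", "n_stays",
                       "hospital_days", "n_diagnoses"),
              by = "patient_id") %>%
    mutate(age_anchor = age_at(.data$anchor_date, .data$birth_year))
  for (cd in codes) {
    base[[paste0("has_", cd)]] <- base$patient_id %in%
      firsts$patient_id[firsts$code == cd]
  }
  one_group <- function(df, status, sexgrp) {
    row <- tibble(
      exposure = if (status) "exposed" else "unexposed",
      sex_group = sexgrp,
      n_subjects = nrow(df),
      age_mean = if (nrow(df)) mean(df$age_anchor) else NA_real_,
      age_sd = if (nrow(df) > 1) stats::sd(df$age_anchor) else NA_real_,
      stays_mean = if (nrow(df)) mean(df$n_stays) else NA_real_,
      stays_sd = if (nrow(df) > 1) stats::sd(df$n_stays) else NA_real_,
      hospital_days_mean = if (nrow(df)) mean(df$hospital_days) else NA_real_,
      hospital_days_sd = if (nrow(df) > 1) stats::sd(df$hospital_days)
                         else NA_real_,
      diagnoses_mean = if (nrow(df)) mean(df$n_diagnoses) else NA_real_,
      diagnoses_sd = if (nrow(df) > 1) stats::sd(df$n_diagnoses) else NA_real_
    )
    for (cd in codes) {
      row[[paste0("pct_", cd)]] <-
        if (nrow(df)) 100 * mean(df[[paste0("has_", cd)]]) else NA_real_
    }
    row
  }
  groups <- tidyr::expand_grid(status = c(TRUE, FALSE),
                               sexgrp = c("total", "female", "male"))
  purrr::pmap(groups, function(status, sexgrp) {
    df <- base %>% filter(.data$exposed == status)
    if (sexgrp != "total") df <- df %>% filter(.data$sex == sexgrp)
    one_group(df, status, sexgrp)
  }) %>%
    bind_rows()
}

#' Run the complete comorbidity analysis
#'
#' Orchestrates chapter filtering, washout exclusion, first occurrences,
#' stratification, the characteristics table, the association screen, the
#' time-order analysis (overall and by sex), sex-stratified screens, the
#' sex-specific odds ratios among the exposed, and the somatic-exclusion
#' sensitivity screen. Record counts at every filter step are collected in
#' the run metadata so each reported number is recomputable from the
#' persisted intermediates.
#'
#' @param events Raw registry event tibble (e.g. from [generate_registry()]
#'   or [read_registry()]).
#' @param config A [run_config()].
#' @return An object of class `comorbidity_report`: a list with elements
#'   `table1`, `screen`, `tor`, `sex_screens`, `sex_or`,
#'   `sensitivity_screen`, and `meta`.
#' @export
run_full_analysis <- function(events, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  check_registry(events)
  meta <- list(
    seed = config$seed,
    thresholds = list(min_occurrence = config$min_occurrence,
                      or_threshold = config$or_threshold,
                      alpha = config$alpha),
    gap_edges = config$gap_edges,
    n_events_in = nrow(events),
    n_patients_in = dplyr::n_distinct(events$patient_id)
  )

  events <- filter_chapters(events)
  meta$n_events_chapters <- nrow(events)
  events <- apply_washout(events, config$washout_start, config$washout_end,
                          config$observe_end)
  meta$n_washed_out <- attr(events, "n_washed_out")
  meta$n_patients_cohort <- dplyr::n_distinct(events$patient_id)

  firsts <- first_occurrences(events)
  profiles <- patient_profiles(events)
  strata <- assign_strata(firsts, profiles, config$exposure_code)
  meta$n_age_excluded <- nrow(attr(strata, "excluded"))
  meta$n_patients_analyzed <- nrow(strata)
  meta$policies <- attr(strata, "policy")

  table1 <- summarize_table1(events, config$exposure_code,
                             codes = config$comorbidity_codes,
                             strata = strata)

  screen <- screen_comorbidities(
    firsts, strata,
    exposure_code = config$exposure_code,
    comorbidity_codes = config$comorbidity_codes,
    min_occurrence = config$min_occurrence,
    or_threshold = config$or_threshold,
    alpha = config$alpha,
    conf_level = config$conf_level
  )
  meta$m_bonferroni <- screen$m
  meta$n_pairs_tested <- nrow(screen$results %>%
                                filter(.data$age_decade != "all",
                                       !.data$filtered))
  meta$n_pairs_filtered <- nrow(screen$results %>%
                                  filter(.data$age_decade != "all",
                                         .data$filtered))

  tor <- purrr::map(config$comorbidity_codes, function(cd) {
    op <- ordered_pairs(firsts, config$exposure_code, cd,
                        profiles = profiles)
    if (nrow(op) == 0) return(NULL)
    bind_rows(
      compute_tor(op, by = "gap_class", edges = config$gap_edges) %>%
        mutate(sex = "total", .before = 1L),
      compute_tor(op, by = "gap_class", by_sex = TRUE,
                  edges = config$gap_edges)
    )
  }) %>% bind_rows()

  sex_screens <- purrr::map(c("female", "male"), function(sx) {
    tryCatch(
      sex_stratified_run(firsts, strata, sx,
                         exposure_code = config$exposure_code,
                         comorbidity_codes = config$comorbidity_codes,
                         min_occurrence = config$min_occurrence,
                         or_threshold = config$or_threshold,
                         alpha = config$alpha,
                         conf_level = config$conf_level)$results,
      error = function(e) NULL
    )
  }) %>% bind_rows()

  sex_or <- tidyr::expand_grid(code = config$comorbidity_codes,
                               decade = c("all", age_decades())) %>%
    purrr::pmap(function(code, decade) {
      tryCatch(sex_specific_or(firsts, strata, code, decade,
                               conf_level = config$conf_level),
               error = function(e) NULL)
    }) %>%
    bind_rows()

  sens_events <- sensitivity_exclude(events, config$sensitivity_codes)
  meta$n_sensitivity_excluded <- attr(sens_events, "n_excluded")
  sensitivity_screen <- tryCatch({
    sf <- first_occurrences(sens_events)
    sp <- patient_profiles(sens_events)
    ss <- assign_strata(sf, sp, config$exposure_code)
    scr <- screen_comorbidities(
      sf, ss,
      exposure_code = config$exposure_code,
      comorbidity_codes = config$comorbidity_codes,
      min_occurrence = config$min_occurrence,
      or_threshold = config$or_threshold,
      alpha = config$alpha,
      conf_level = config$conf_level
    )
    scr$results %>% mutate(analysis = "sensitivity", .before = 1L)
  }, error = function(e) NULL)

  structure(
    list(table1 = table1, screen = screen, tor = tor,
         sex_screens = sex_screens, sex_or = sex_or,
         sensitivity_screen = sensitivity_screen, meta = meta),
    class = "comorbidity_report"
  )
}

#' Write a report bundle to a directory
#'
#' Persists every result table as CSV plus a JSON metadata sidecar recording
#' the seed, thresholds, Bonferroni family size, policy strings and the
#' record counts at every filter step.
#'
#' @param report A `comorbidity_report` from [run_full_analysis()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "comorbidity_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$table1, file.path(dir, "table1.csv"))
  readr::write_csv(report$screen$results, file.path(dir, "associations.csv"))
  if (nrow(report$tor) > 0) {
    readr::write_csv(report$tor, file.path(dir, "tor.csv"))
  }
  if (!is.null(report$sex_screens) && nrow(report$sex_screens) > 0) {
    readr::write_csv(report$sex_screens,
                     file.path(dir, "sex_associations.csv"))
  }
  if (!is.null(report$sex_or) && nrow(report$sex_or) > 0) {
    readr::write_csv(report$sex_or, file.path(dir, "sex_or.csv"))
  }
  if (!is.null(report$sensitivity_screen)) {
    readr::write_csv(report$sensitivity_screen,
                     file.path(dir, "sensitivity_associations.csv"))
  }
  meta <- report$meta
  meta$m_bonferroni <- report$screen$m
  meta$screen_policies <- report$screen$policies
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

#' @export
print.comorbidity_report <- function(x, ...) {
  cat("<comorbidity_report>\n")
  cat(sprintf("  cohort: %d patients analyzed (%d washed out, %d age-excluded)\n",
              x$meta$n_patients_analyzed, x$meta$n_washed_out,
              x$meta$n_age_excluded))
  cat(sprintf("  association tests: %d in family, %d filtered\n",
              x$meta$m_bonferroni, x$meta$n_pairs_filtered))
  sig <- x$screen$results %>%
    filter(.data$significant, .data$age_decade == "all")
  if (nrow(sig) > 0) {
    cat("  significant pooled associations:\n")
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("    %s-%s OR %.2f [%.2f-%.2f]\n", sig$code_a[i],
                  sig$code_b[i], sig$or_mh[i], sig$ci_low[i], sig$ci_high[i]))
    }
  }
  invisible(x)
}
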