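## Sex-stratified screening, sex-specific odds ratios among the exposed, and
## the somatic-exclusion sensitivity analysis.

#' Run the association screen within one sex
#'
#' Identical pipeline to [screen_comorbidities()], restricted to patients of
#' one sex; results carry a `sex` tag. Stratification, occurrence filter and
#' the Bonferroni family are computed within the restricted cohort.
#'
#' @param firsts Output of [first_occurrences()].
#' @param strata Output of [assign_strata()] (carries `sex`).
#' @param sex `"female"` or `"male"`.
#' @inheritParams screen_comorbidities
#' @return A `comorbidity_screen` whose results have a `sex` column.
#' @export
sex_stratified_run <- function(firsts, strata, sex,
                               exposure_code = "E66", comorbidity_codes,
                               min_occurrence = 100, or_threshold = 1.5,
                               alpha = 0.01, conf_level = 0.95) {
  if (!sex %in% c("female", "male")) abort('`sex` must be "female" or "male".')
  if (length(unique(strata$sex)) < 2L) {
    abort("cohort has a single sex level; a sex-stratified run is meaningless.")
  }
  sub <- strata %>% filter(.data$sex == .env$sex)
  if (nrow(sub) == 0) abort(sprintf("no patients with sex = %s.", sex))
  attr(sub, "policy") <- attr(strata, "policy")
  scr <- screen_comorbidities(
    firsts %>% semi_join(sub, by = "patient_id"), sub,
    exposure_code = exposure_code, comorbidity_codes = comorbidity_codes,
    min_occurrence = min_occurrence, or_threshold = or_threshold,
    alpha = alpha, conf_level = conf_level
  )
  scr$results <- scr$results %>% mutate(sex = .env$sex, .before = 1L)
  scr$sex <- sex
  scr
}

#' Sex-specific odds ratio within the exposed cohort
#'
#' Among exposed patients of one age decade, cross-tabulates sex against
#' presence of a comorbidity per calendar window (female in the numerator)
#' and pools the per-window tables with the Mantel-Haenszel estimator; the
#' p-value comes from the CMH test on the same series. An odds ratio above 1
#' means female exposed patients carry the comorbidity more often than male
#' exposed patients.
#'
#' @param firsts Output of [first_occurrences()].
#' @param strata Output of [assign_strata()].
#' @param comorbidity A level-3 ICD-10 code.
#' @param age_decade One decade label (see [age_decades()]), or `"all"` to
#'   pool every decade.
#' @param conf_level Confidence level.
#' @return A one-row tibble: `code`, `age_decade`, `or_female_vs_male`,
#'   `ci_low`, `ci_high`, `p_raw`, `n_female`, `n_male`, `flags`.
#' @export
sex_specific_or <- function(firsts, strata, comorbidity, age_decade = "all",
                            conf_level = 0.95) {
  exposed <- strata %>% filter(.data$exposed)
  if (age_decade != "all") {
    exposed <- exposed %>% filter(.data$age_decade == .env$age_decade)
  }
  if (nrow(exposed) == 0) abort("no exposed patients in this decade.")
  has_c <- exposed$patient_id %in%
    firsts$patient_id[firsts$code == comorbidity]
  is_f <- exposed$sex == "female"
  cell <- factor(2L * (!is_f) + (!has_c), levels = 0:3)
  counts <- table(exposed$window, cell)
  series <- tibble(
    window = rownames(counts),
    a = as.integer(counts[, 1L]), b = as.integer(counts[, 2L]),
    c = as.integer(counts[, 3L]), d = as.integer(counts[, 4L])
  )
  est <- mantel_haenszel_or(series, conf_level = conf_level)
  tst <- cmh_test(series)
  tibble(
    code = comorbidity,
    age_decade = age_decade,
    or_female_vs_male = est$or_mh,
    ci_low = est$ci_low,
    ci_high = est$ci_high,
    p_raw = tst$p_raw,
    n_female = sum(is_f),
    n_male = sum(!is_f),
    flags = paste(est$flag, tst$flag, sep = ";")
  )
}

#' Remove patients carrying any of a set of somatic diagnoses
#'
#' Sensitivity analysis: every patient ever carrying one of the excluded
#' codes during the observation window is removed entirely (patient-level,
#' all-or-nothing, idempotent); the downstream screen then proceeds on the
#' reduced registry. The default set removes diabetes (E11), hypertension
#' (I10) and coronary artery disease (I25), the classic somatic risk factors
#' whose removal probes whether psychiatric links persist without them.
#'
#' @param events Registry event tibble.
#' @param excluded_codes Codes triggering patient removal.
#' @return The reduced event tibble; the number of removed patients is
#'   attached as attribute `"n_excluded"`.
#' @export
sensitivity_exclude <- function(events,
                                excluded_codes = c("E11", "I10", "I25")) {
  check_registry(events)
  if (length(excluded_codes) == 0) {
    warn("empty exclusion set; returning events unchanged.")
    attr(events, "n_excluded") <- 0L
    return(events)
  }
  drop_pat <- unique(events$patient_id[events$code %in% excluded_codes])
  out <- events[!(events$patient_id %in% drop_pat), , drop = FALSE]
  attr(out, "n_excluded") <- length(drop_pat)
  out
}
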