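## Configuration for the synthetic registry generator.

#' Build a baseline prevalence table
#'
#' Expands per-code prevalences into the full (code, age decade, sex) grid the
#' generator consumes. Prevalences are probabilities that a patient ever
#' receives the code during the observation period, conditional on age decade
#' at anchor and sex.
#'
#' @param codes Character vector of level-3 ICD-10 codes.
#' @param prev Numeric vector of prevalences, recycled along `codes`.
#' @return A tibble with columns `code`, `age_decade`, `sex`, `prev`.
#' @seealso [prevalence_gradient()] for age-increasing prevalences.
#' @export
#' @examples
#' prevalence_table(c("E66", "F32"), c(0.05, 0.04))
prevalence_table <- function(codes, prev) {
  prev <- rep_len(prev, length(codes))
  tidyr::expand_grid(
    code = codes,
    age_decade = age_decades(),
    sex = c("female", "male")
  ) %>%
    mutate(prev = .env$prev[match(.data$code, .env$codes)])
}

#' Build an age-increasing prevalence table for one code
#'
#' Linear interpolation from `from` in decade 10-19 to `to` in decade 70-79,
#' identical for both sexes. Used to construct confounded scenarios in which
#' prevalence rises with age.
#'
#' @param code A level-3 ICD-10 code.
#' @param from,to Prevalence in the youngest and oldest decade.
#' @return A tibble with columns `code`, `age_decade`, `sex`, `prev`.
#' @export
prevalence_gradient <- function(code, from, to) {
  p <- seq(from, to, length.out = 7L)
  tidyr::expand_grid(age_decade = age_decades(), sex = c("female", "male")) %>%
    mutate(code = code, prev = rep(p, each = 2L)) %>%
    select("code", "age_decade", "sex", "prev")
}

# odds-scale inflation: p1 such that odds(p1) = theta * odds(p0)
inflate_odds <- function(p0, theta) {
  o <- theta * p0 / (1 - p0)
  o / (1 + o)
}

#' Configure the synthetic registry generator
#'
#' Defines every knob of the synthetic longitudinal inpatient registry:
#' cohort size, observation period, washout behaviour, per-stratum baseline
#' prevalences, the injected exposure-comorbidity odds multiplier `theta`,
#' the injected time-order bias `rho`, same-stay probability and the
#' inter-diagnosis gap mixture. Identical configurations (including `seed`)
#' generate identical registries.
#'
#' Defaults emulate the structure of a national hospital-stay registry:
#' exposure (obesity, E66) prevalence around 5%, a comorbidity (F32) around
#' 4%, about a quarter of dual diagnoses coded at a single stay, and the
#' remaining gaps spread evenly over the three delayed classes.
#'
#' @param n_patients Number of patients to generate.
#' @param theta Odds multiplier (>= 0) applied to each comorbidity's odds given
#'   exposure, constant across (age decade, calendar window) strata so the
#'   Mantel-Haenszel common-odds-ratio assumption holds by construction.
#'   Either a scalar or a named vector `c(female = , male = )`.
#' @param rho Direction bias (>= 0): the target ratio of exposure-first to
#'   comorbidity-first orderings among dual-diagnosed patients with distinct
#'   diagnosis dates; `P(exposure first) = rho / (1 + rho)`.
#' @param n_patients,period_start,period_end,observe_start Cohort size and
#'   calendar span; stays before `observe_start` only occur for washout
#'   patients.
#' @param washout_fraction Probability a patient has at least one stay during
#'   the washout era (before `observe_start`); such patients are removed by
#'   [apply_washout()].
#' @param mean_stays Target mean number of stays per patient (>= 1).
#' @param baseline_prevalence Tibble (`code`, `age_decade`, `sex`, `prev`) of
#'   ever-diagnosis probabilities. Must cover `exposure_code` and every
#'   comorbidity code; additional codes are generated without any injected
#'   association (useful for sensitivity-exclusion codes or out-of-scope
#'   chapters). `NULL` builds a flat default for `exposure_code` (0.05) and
#'   the comorbidity codes (0.04).
#' @param exposure_code Index diagnosis code (default `"E66"`, obesity).
#' @param comorbidity_codes Codes receiving the `theta` injection.
#' @param p_same_stay Probability a dual diagnosis is coded at one stay.
#' @param gap_breaks,gap_weights,gap_max Mixture of inter-diagnosis gaps for
#'   dual diagnoses at distinct stays: class k spans
#'   `(breaks[k-1], breaks[k]]` days with weight `gap_weights[k]`; the last
#'   class spans `(max(gap_breaks), gap_max]`. Defaults target the four
#'   canonical classes (same stay, <=360 d, 361-1080 d, >1080 d) with equal
#'   weight on the delayed classes.
#' @param filler_codes Codes attached to background stays that carry none of
#'   the tracked diagnoses.
#' @param sex_ratio Probability a patient is female.
#' @param seed Integer seed; the generator derives one substream per
#'   generation phase from it, so enlarging `n_patients` leaves earlier
#'   patients' draws untouched.
#' @return A validated object of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_patients = 500, theta = 2, rho = 2, seed = 1)
#' reg <- generate_registry(cfg)
generator_config <- function(n_patients,
                             period_start = as.Date("1997-01-01"),
                             period_end = as.Date("2014-12-31"),
                             observe_start = as.Date("2003-01-01"),
                             washout_fraction = 0.25,
                             mean_stays = 2.8,
                             baseline_prevalence = NULL,
                             exposure_code = "E66",
                             comorbidity_codes = "F32",
                             theta = 1,
                             rho = 1,
                             p_same_stay = 0.25,
                             gap_breaks = c(360L, 1080L),
                             gap_weights = c(1, 1, 1) / 3,
                             gap_max = 3240L,
                             filler_codes = c("J06", "K52", "M54"),
                             sex_ratio = 0.5,
                             seed = 1L) {
  if (is.null(baseline_prevalence)) {
    baseline_prevalence <- bind_rows(
      prevalence_table(exposure_code, 0.05),
      prevalence_table(comorbidity_codes, 0.04)
    )
  }
  cfg <- structure(
    list(
      n_patients = as.integer(n_patients),
      period_start = as.Date(period_start),
      period_end = as.Date(period_end),
      observe_start = as.Date(observe_start),
      washout_fraction = washout_fraction,
      mean_stays = mean_stays,
      baseline_prevalence = as_tibble(baseline_prevalence),
      exposure_code = exposure_code,
      comorbidity_codes = comorbidity_codes,
      theta = theta,
      rho = rho,
      p_same_stay = p_same_stay,
      gap_breaks = as.integer(gap_breaks),
      gap_weights = gap_weights,
      gap_max = as.integer(gap_max),
      filler_codes = filler_codes,
      sex_ratio = sex_ratio,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
  validate_generator_config(cfg)
}

theta_for_sex <- function(theta, sex) {
  if (length(theta) == 1L && is.null(names(theta))) {
    rep(unname(theta), length(sex))
  } else {
    unname(theta[sex])
  }
}

validate_generator_config <- function(cfg) {
  probs <- c(washout = cfg$washout_fraction, same_stay = cfg$p_same_stay,
             sex_ratio = cfg$sex_ratio)
  if (any(probs < 0 | probs > 1)) {
    abort("washout_fraction, p_same_stay and sex_ratio must lie in [0, 1].")
  }
  if (cfg$n_patients < 1L) abort("n_patients must be a positive integer.")
  if (cfg$mean_stays < 1) abort("mean_stays must be >= 1.")
  if (any(!is.finite(cfg$theta)) || any(cfg$theta < 0)) {
    abort("theta must be finite and >= 0.")
  }
  if (length(cfg$theta) > 1L &&
      !setequal(names(cfg$theta), c("female", "male"))) {
    abort("a vector theta must be named c(female = , male = ).")
  }
  if (!is.finite(cfg$rho) || cfg$rho < 0) abort("rho must be finite and >= 0.")
  if (!(cfg$period_start <= cfg$observe_start &&
        cfg$observe_start <= cfg$period_end)) {
    abort("need period_start <= observe_start <= period_end.")
  }
  if (is.unsorted(cfg$gap_breaks, strictly = TRUE) ||
      any(cfg$gap_breaks <= 0) || cfg$gap_max <= max(cfg$gap_breaks)) {
    abort("gap_breaks must be strictly ascending positive days, below gap_max.")
  }
  if (length(cfg$gap_weights) != length(cfg$gap_breaks) + 1L ||
      any(cfg$gap_weights < 0) || sum(cfg$gap_weights) <= 0) {
    abort("gap_weights must be non-negative with one weight per gap class.")
  }
  bp <- cfg$baseline_prevalence
  need <- c("code", "age_decade", "sex", "prev")
  if (!all(need %in% names(bp))) {
    abort("baseline_prevalence needs columns code, age_decade, sex, prev.")
  }
  if (any(!is_icd3(bp$code))) {
    abort("baseline_prevalence codes must be level-3 ICD-10 strings.")
  }
  if (any(bp$prev < 0 | bp$prev >= 1)) {
    abort("baseline prevalences must lie in [0, 1).")
  }
  tracked <- c(cfg$exposure_code, cfg$comorbidity_codes)
  covered <- bp %>%
    filter(.data$code %in% tracked) %>%
    count(.data$code) %>%
    filter(.data$n == 14L) %>%
    pull("code")
  if (!all(tracked %in% covered)) {
    abort(sprintf(
      "baseline_prevalence must cover all 7 decades x 2 sexes for: %s",
      paste(setdiff(tracked, covered), collapse = ", ")
    ))
  }
  # odds inflation must stay strictly below 1 in every exposed stratum
  com <- bp %>% filter(.data$code %in% cfg$comorbidity_codes)
  th <- theta_for_sex(cfg$theta, com$sex)
  p1 <- inflate_odds(com$prev, th)
  bad <- which(!is.finite(p1) | p1 >= 1 - 1e-12)
  if (length(bad) > 0) {
    b <- com[bad[1], ]
    abort(sprintf(
      "theta-inflated prevalence reaches 1 in stratum (code=%s, decade=%s, sex=%s).",
      b$code, b$age_decade, b$sex
    ))
  }
  cfg
}

#' Derive an age-confounded scenario from a configuration
#'
#' Returns a copy of `config` in which both the exposure prevalence and every
#' comorbidity prevalence increase with age decade while `theta` is unchanged.
#' Because older patients are then more likely to carry both diagnoses for
#' reasons unrelated to `theta`, the crude (unstratified) odds ratio is biased
#' upwards, while the age-stratified Mantel-Haenszel estimate still targets
#' `theta` — the canonical demonstration that stratified pooling adjusts for
#' confounding.
#'
#' @param config A [generator_config()].
#' @param exposure_range,comorbidity_range Prevalence in the youngest and
#'   oldest decade for the exposure and each comorbidity code.
#' @return A `generator_config` differing from `config` only in its
#'   prevalence map.
#' @export
confounded_scenario <- function(config,
                                exposure_range = c(0.03, 0.15),
                                comorbidity_range = c(0.02, 0.14)) {
  stopifnot(inherits(config, "generator_config"))
  keep <- config$baseline_prevalence %>%
    filter(!.data$code %in% c(config$exposure_code, config$comorbidity_codes))
  grad <- bind_rows(
    prevalence_gradient(config$exposure_code,
                        exposure_range[1], exposure_range[2]),
    purrr::map(config$comorbidity_codes, prevalence_gradient,
               from = comorbidity_range[1], to = comorbidity_range[2])
  )
  config$baseline_prevalence <- bind_rows(grad, keep)
  validate_generator_config(config)
}

#' Read a generator configuration from a YAML file
#'
#' The file mirrors [generator_config()] argument names; `baseline_prevalence`
#' may be given as a simple `code: prevalence` map (expanded flat across
#' strata) or as a list of records with `code`, `age_decade`, `sex`, `prev`.
#'
#' @param path Path to a YAML file.
#' @return A validated `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$baseline_prevalence) &&
      !is.null(names(raw$baseline_prevalence)) &&
      all(vapply(raw$baseline_prevalence, is.numeric, logical(1)))) {
    raw$baseline_prevalence <- prevalence_table(
      names(raw$baseline_prevalence),
      unlist(raw$baseline_prevalence)
    )
  } else if (!is.null(raw$baseline_prevalence)) {
    raw$baseline_prevalence <- bind_rows(lapply(raw$baseline_prevalence,
                                                as_tibble))
  }
  for (fld in c("period_start", "period_end", "observe_start")) {
    if (!is.null(raw[[fld]])) raw[[fld]] <- as.Date(raw[[fld]])
  }
  if (!is.null(raw$theta)) raw$theta <- unlist(raw$theta)
  do.call(generator_config, raw)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  patients: %d, period %s..%s (observation from %s)\n",
              x$n_patients, x$period_start, x$period_end, x$observe_start))
  cat(sprintf("  exposure %s vs {%s}; theta = %s, rho = %.3g\n",
              x$exposure_code, paste(x$comorbidity_codes, collapse = ", "),
              paste(format(x$theta, digits = 3), collapse = "/"), x$rho))
  cat(sprintf("  washout %.0f%%, mean stays %.2f, same-stay %.0f%%, seed %d\n",
              100 * x$washout_fraction, x$mean_stays, 100 * x$p_same_stay,
              x$seed))
  invisible(x)
}
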