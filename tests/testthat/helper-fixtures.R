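# Fixture builders shared across test files. All fixtures are built in code.

# One diagnosis event row with sensible defaults.
event_row <- function(patient_id, code, admission,
                      stay_id = paste0(patient_id, "-", admission),
                      sex = "female", birth_year = 1970L,
                      release = as.Date(admission) + 3) {
  tibble::tibble(
    patient_id = patient_id, sex = sex, birth_year = as.integer(birth_year),
    stay_id = stay_id, admission_date = as.Date(admission),
    release_date = as.Date(release), code = code
  )
}

make_events <- function(...) dplyr::bind_rows(...)

# first-occurrence + stratum fixtures for hand-built association tests:
# patients all anchored in one decade/window unless stated otherwise.
make_firsts <- function(patient_id, code, first_date,
                        first_stay_id = paste0(patient_id, "-", code)) {
  tibble::tibble(patient_id = patient_id, code = code,
                 first_date = as.Date(first_date),
                 first_stay_id = first_stay_id)
}

make_strata <- function(patient_id, exposed = FALSE, sex = "female",
                        age_decade = "40-49", window = "2007-08",
                        anchor_date = as.Date("2007-06-01")) {
  tibble::tibble(patient_id = patient_id, sex = sex, exposed = exposed,
                 anchor_date = anchor_date, age_decade = age_decade,
                 window = window)
}

# A registry with dual diagnoses laid out explicitly: `spec` is a tibble with
# columns patient_id, date_a, date_b (NA = code absent), same_stay.
pair_registry <- function(spec, code_a = "E66", code_b = "F32") {
  rows <- list()
  for (i in seq_len(nrow(spec))) {
    p <- spec$patient_id[i]
    if (!is.na(spec$date_a[i])) {
      rows[[length(rows) + 1]] <- event_row(p, code_a, spec$date_a[i])
    }
    if (!is.na(spec$date_b[i])) {
      sid <- if (isTRUE(spec$same_stay[i])) {
        paste0(p, "-", spec$date_a[i])
      } else {
        paste0(p, "-", spec$date_b[i])
      }
      rows[[length(rows) + 1]] <-
        event_row(p, code_b, spec$date_b[i], stay_id = sid)
    }
  }
  dplyr::bind_rows(rows)
}

# Independent formula transcriptions used as oracles (plain loops, kept free
# of any package internals).
mh_oracle <- function(tab) {
  R <- 0; S <- 0
  for (i in seq_len(nrow(tab))) {
    n <- tab$a[i] + tab$b[i] + tab$c[i] + tab$d[i]
    R <- R + tab$a[i] * tab$d[i] / n
    S <- S + tab$b[i] * tab$c[i] / n
  }
  sPR <- 0; sMix <- 0; sQS <- 0
  for (i in seq_len(nrow(tab))) {
    n <- tab$a[i] + tab$b[i] + tab$c[i] + tab$d[i]
    P <- (tab$a[i] + tab$d[i]) / n
    Q <- (tab$b[i] + tab$c[i]) / n
    Ri <- tab$a[i] * tab$d[i] / n
    Si <- tab$b[i] * tab$c[i] / n
    sPR <- sPR + P * Ri
    sMix <- sMix + P * Si + Q * Ri
    sQS <- sQS + Q * Si
  }
  v <- sPR / (2 * R^2) + sMix / (2 * R * S) + sQS / (2 * S^2)
  list(or = R / S,
       ci = exp(log(R / S) + c(-1, 1) * qnorm(0.975) * sqrt(v)))
}

cmh_oracle <- function(tab) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(tab))) {
    a <- tab$a[i]; b <- tab$b[i]; cc <- tab$c[i]; d <- tab$d[i]
    n <- a + b + cc + d
    if (n <= 1 || (a + b) == 0 || (cc + d) == 0 ||
        (a + cc) == 0 || (b + d) == 0) next
    num <- num + a - (a + b) * (a + cc) / n
    den <- den + (a + b) * (cc + d) * (a + cc) * (b + d) / (n^2 * (n - 1))
  }
  stat <- num^2 / den
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

# full pipeline on a generated registry down to one pair's contingency series
run_pair_pipeline <- function(cfg, code_a = "E66", code_b = "F32") {
  reg <- generate_registry(cfg)
  ev <- apply_washout(filter_chapters(reg))
  f <- first_occurrences(ev)
  s <- assign_strata(f, patient_profiles(ev), code_a)
  list(events = ev, firsts = f, strata = s,
       series = build_contingency_series(f, s, code_a, code_b))
}

# high-prevalence configuration used for time-order calibration runs: dense
# dual diagnoses so a small cohort yields many ordered pairs
tor_config <- function(n, rho, seed) {
  generator_config(
    n_patients = n, rho = rho, seed = seed,
    baseline_prevalence = dplyr::bind_rows(
      prevalence_table("E66", 0.45), prevalence_table("F32", 0.5)
    ),
    p_same_stay = 0.2, washout_fraction = 0.1
  )
}
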