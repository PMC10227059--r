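## Synthetic longitudinal inpatient registry with known injected effects.
##
## Design notes (constraints the code must honour):
##  * theta is injected on the odds scale per (age decade, sex) stratum, and
##    prevalences are constant across calendar windows, so the Mantel-Haenszel
##    common-odds-ratio assumption holds exactly by construction.
##  * The exposure's first occurrence date (the cohort anchor) is drawn
##    independently of dual status and direction; comorbidity dates are placed
##    at anchor +/- gap. This keeps the anchor's calendar-window distribution
##    identical for all exposed patients, so window membership carries no
##    information about comorbidity status and stratified estimates stay
##    unbiased for theta.
##  * One substream per generation phase (and per draw kind within a code):
##    every draw is a single vectorized call ordered by patient, so growing
##    n_patients appends draws without perturbing earlier patients.

#' Generate a synthetic diagnosis-event registry
#'
#' Produces one row per (patient, stay, diagnosis), mirroring the structure of
#' a national hospital-stay registry: opaque patient and stay ids, sex, birth
#' year, admission/release dates and a level-3 ICD-10 code. The exposure code
#' and each comorbidity code are assigned so that within every
#' (age decade, sex) stratum the comorbidity odds given exposure are
#' `theta` times the baseline odds, and so that among dual-diagnosed patients
#' with distinct diagnosis dates the probability that the exposure comes first
#' is `rho / (1 + rho)`.
#'
#' @param config A [generator_config()].
#' @return A tibble of diagnosis events with columns `patient_id`, `sex`,
#'   `birth_year`, `stay_id`, `admission_date`, `release_date`, `code`,
#'   ordered by patient, date and stay. The per-patient ground truth
#'   (exposure, per-code presence, ordering draws) is attached as the
#'   `"truth"` attribute for validation studies.
#' @export
#' @examples
#' reg <- generate_registry(generator_config(n_patients = 200, seed = 42))
#' head(reg)
generate_registry <- function(config) {
  cfg <- validate_generator_config(config)
  n <- cfg$n_patients
  bp <- cfg$baseline_prevalence
  other_codes <- setdiff(unique(bp$code),
                         c(cfg$exposure_code, cfg$comorbidity_codes))
  n_com <- length(cfg$comorbidity_codes)
  n_oth <- length(other_codes)

  set.seed(cfg$seed)
  pool <- sample.int(.Machine$integer.max - 1L,
                     16L + 5L * n_com + max(n_oth, 0L))
  ps <- function(k) pool[k]

  ## --- patient-level attributes -------------------------------------------
  set.seed(ps(1L)); sex <- ifelse(runif(n) < cfg$sex_ratio, "female", "male")
  set.seed(ps(2L)); dec_idx <- 1L + as.integer(floor(runif(n) * 7))
  set.seed(ps(3L)); age <- 10L * dec_idx + as.integer(floor(runif(n) * 10))
  decade <- sprintf("%d-%d", 10L * dec_idx, 10L * dec_idx + 9L)
  set.seed(ps(4L)); anchor <- runif_dates(n, cfg$observe_start, cfg$period_end)
  washout_possible <- cfg$observe_start > cfg$period_start
  set.seed(ps(5L))
  wflag <- washout_possible & runif(n) < cfg$washout_fraction
  set.seed(ps(6L))
  wdate <- if (washout_possible) {
    runif_dates(n, cfg$period_start, cfg$observe_start - 1)
  } else {
    rep(cfg$period_start, n)
  }

  lookup <- setNames(bp$prev, paste(bp$code, bp$age_decade, bp$sex, sep = "|"))
  p_exp <- unname(lookup[paste(cfg$exposure_code, decade, sex, sep = "|")])
  set.seed(ps(7L)); exposed <- runif(n) < p_exp

  birth_year <- as.integer(format(anchor, "%Y")) - age -
    as.integer(format(anchor, "%m-%d") < "07-01")

  pid <- seq_len(n)
  rows_pid <- integer(0); rows_date <- as.Date(character(0))
  rows_code <- character(0)
  add_rows <- function(p, d, code) {
    rows_pid <<- c(rows_pid, p)
    rows_date <<- c(rows_date, d)
    rows_code <<- c(rows_code, rep_len(code, length(p)))
  }

  add_rows(pid[exposed], anchor[exposed], cfg$exposure_code)

  ## --- comorbidity codes: presence, ordering, gaps ------------------------
  lo <- c(1L, cfg$gap_breaks + 1L)
  hi <- c(cfg$gap_breaks, cfg$gap_max)
  wts <- cumsum(cfg$gap_weights) / sum(cfg$gap_weights)
  th <- theta_for_sex(cfg$theta, sex)
  p_first <- cfg$rho / (1 + cfg$rho)

  truth <- tibble(
    patient_id = sprintf("P%07d", pid),
    sex = sex, birth_year = birth_year, age_decade = decade,
    anchor_date = anchor, washout = wflag, exposed = exposed
  )

  for (j in seq_len(n_com)) {
    code_j <- cfg$comorbidity_codes[j]
    base <- 16L + 5L * (j - 1L)
    p0 <- unname(lookup[paste(code_j, decade, sex, sep = "|")])
    p1 <- inflate_odds(p0, th)
    set.seed(ps(base + 1L)); present <- runif(n) < ifelse(exposed, p1, p0)
    set.seed(ps(base + 2L)); same <- runif(n) < cfg$p_same_stay
    set.seed(ps(base + 3L)); efirst <- runif(n) < p_first
    set.seed(ps(base + 4L)); cls <- findInterval(runif(n), wts,
                                                 rightmost.closed = TRUE) + 1L
    cls <- pmin(cls, length(lo))
    set.seed(ps(base + 5L))
    gap <- lo[cls] + as.integer(floor(runif(n) * (hi[cls] - lo[cls] + 1L)))

    date_c <- anchor
    ordered <- present & exposed & !same
    fwd <- ordered & efirst
    bwd <- ordered & !efirst
    date_c[fwd] <- pmin(anchor[fwd] + gap[fwd], cfg$period_end)
    date_c[bwd] <- pmax(anchor[bwd] - gap[bwd], cfg$observe_start)
    add_rows(pid[present], date_c[present], code_j)

    truth[[paste0("present_", code_j)]] <- present
    truth[[paste0("same_stay_", code_j)]] <- present & exposed & same
    truth[[paste0("exposure_first_", code_j)]] <- fwd
  }

  ## --- untracked codes (no injected association) --------------------------
  for (j in seq_len(n_oth)) {
    code_j <- other_codes[j]
    p0 <- unname(lookup[paste(code_j, decade, sex, sep = "|")])
    set.seed(ps(16L + 5L * n_com + j)); present <- runif(n) < p0
    add_rows(pid[present], anchor[present], code_j)
  }

  ## --- entry stay at the anchor date for every patient --------------------
  # guarantees the anchor admission exists, so the unexposed anchor (first
  # admission) coincides with the drawn anchor date and window membership is
  # independent of diagnosis status
  set.seed(ps(13L))
  entry_code <- cfg$filler_codes[1L + floor(runif(n) *
                                              length(cfg$filler_codes))]
  add_rows(pid, anchor, NA_character_)
  rows_code[is.na(rows_code)] <- entry_code

  ## --- background stays, washout stays ------------------------------------
  dx_min <- rep(cfg$period_end, n)
  keep <- order(rows_pid, rows_date)
  rows_pid <- rows_pid[keep]; rows_date <- rows_date[keep]
  rows_code <- rows_code[keep]
  firsts_idx <- !duplicated(rows_pid)
  dx_min[rows_pid[firsts_idx]] <- rows_date[firsts_idx]
  n_dx_stays <- tabulate(rows_pid[!duplicated(paste(rows_pid, rows_date))],
                         nbins = n)

  lambda <- pmax(cfg$mean_stays - n_dx_stays - as.numeric(wflag), 0)
  set.seed(ps(8L)); n_extra <- rpois(n, lambda)
  idx <- rep.int(pid, n_extra)
  set.seed(ps(9L))
  span <- as.numeric(cfg$period_end - dx_min[idx])
  edate <- dx_min[idx] + floor(runif(length(idx)) * (span + 1))
  set.seed(ps(10L))
  ecode <- cfg$filler_codes[1L + floor(runif(length(idx)) *
                                         length(cfg$filler_codes))]
  add_rows(idx, edate, NA_character_)
  rows_code[is.na(rows_code)] <- ecode

  if (any(wflag)) {
    set.seed(ps(11L))
    wcode <- cfg$filler_codes[1L + floor(runif(n) *
                                           length(cfg$filler_codes))]
    add_rows(pid[wflag], wdate[wflag], NA_character_)
    rows_code[is.na(rows_code)] <- wcode[wflag]
  }

  ## --- assemble stays and the event table ---------------------------------
  o <- order(rows_pid, rows_date, rows_code)
  rows_pid <- rows_pid[o]; rows_date <- rows_date[o]; rows_code <- rows_code[o]
  new_pat <- c(TRUE, rows_pid[-1L] != rows_pid[-length(rows_pid)])
  new_stay <- new_pat | c(TRUE, rows_date[-1L] != rows_date[-length(rows_date)])
  stay_g <- cumsum(new_stay)
  # within-patient stay sequence for stable, sortable ids
  pat_first_stay <- stay_g[new_pat]
  offs <- rep.int(pat_first_stay - 1L,
                  diff(c(which(new_pat), length(rows_pid) + 1L)))
  stay_within <- stay_g - offs

  n_stays <- max(stay_g)
  set.seed(ps(12L)); los <- 1L + rpois(n_stays, 4.5)
  stay_adm <- rows_date[new_stay]
  stay_rel <- pmin(stay_adm + los - 1L, cfg$period_end)

  events <- tibble(
    patient_id = sprintf("P%07d", rows_pid),
    sex = sex[rows_pid],
    birth_year = birth_year[rows_pid],
    stay_id = sprintf("S%07d-%03d", rows_pid, stay_within),
    admission_date = rows_date,
    release_date = stay_rel[stay_g],
    code = rows_code
  )
  attr(events, "truth") <- truth
  events
}

#' Write or read a registry as CSV
#'
#' Plain-text interchange format: ISO-8601 dates, one row per
#' (patient, stay, diagnosis), header
#' `patient_id,sex,birth_year,stay_id,admission_date,release_date,code`.
#'
#' @param events A registry event tibble.
#' @param path File path.
#' @return `write_registry()` returns `events` invisibly; `read_registry()`
#'   returns the event tibble.
#' @export
write_registry <- function(events, path) {
  check_registry(events)
  readr::write_csv(events[registry_columns()], path)
  invisible(events)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  events <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      sex = readr::col_character(),
      birth_year = readr::col_integer(),
      stay_id = readr::col_character(),
      admission_date = readr::col_date(),
      release_date = readr::col_date(),
      code = readr::col_character()
    )
  )
  check_registry(events)
  events
}
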