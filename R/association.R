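## Stratified association screening: per-window 2x2 series, Mantel-Haenszel
## pooled odds ratio with Robins-Breslow-Greenland confidence interval,
## Cochran-Mantel-Haenszel test, occurrence filter and Bonferroni calls.

#' Build the per-window 2x2 series for a diagnosis pair
#'
#' Cross-tabulates presence of `code_a` against presence of `code_b` over the
#' patients anchored in each (age decade, calendar window) cell. Presence
#' means any first occurrence during the observation period; the window
#' stratification adjusts for calendar-period confounding, it does not
#' restrict when the co-diagnosis may occur. Cells without patients are
#' omitted.
#'
#' @param firsts Output of [first_occurrences()].
#' @param strata Output of [assign_strata()].
#' @param code_a,code_b The diagnosis pair; `a` counts patients with both,
#'   `b` with `code_a` only, `c` with `code_b` only, `d` with neither.
#' @return A tibble with columns `age_decade`, `window`, `a`, `b`, `c`, `d`.
#' @export
build_contingency_series <- function(firsts, strata, code_a, code_b) {
  if (identical(code_a, code_b)) {
    abort("code_a and code_b must differ.")
  }
  has_a <- strata$patient_id %in%
    firsts$patient_id[firsts$code == code_a]
  has_b <- strata$patient_id %in%
    firsts$patient_id[firsts$code == code_b]
  cell <- factor(2L * (!has_a) + (!has_b), levels = 0:3)  # a, b, c, d
  strat_key <- paste(strata$age_decade, strata$window, sep = "\r")
  counts <- table(strat_key, cell)
  keys <- rownames(counts)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  tibble(
    age_decade = vapply(parts, `[`, character(1), 1L),
    window = vapply(parts, `[`, character(1), 2L),
    a = as.integer(counts[, 1L]),
    b = as.integer(counts[, 2L]),
    c = as.integer(counts[, 3L]),
    d = as.integer(counts[, 4L])
  ) %>%
    arrange(.data$age_decade, .data$window)
}

#' Mantel-Haenszel pooled odds ratio with RBG confidence interval
#'
#' Pools the per-stratum 2x2 tables into the Mantel-Haenszel common odds
#' ratio `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)` and builds a normal-theory
#' confidence interval for its log from the Robins-Breslow-Greenland variance
#' estimator, which remains consistent both with few large strata and with
#' many sparse ones. If the denominator (or numerator) sum is zero the
#' estimate is undefined and a sentinel is returned instead of an error.
#'
#' @param series Tibble with integer columns `a`, `b`, `c`, `d`, one row per
#'   stratum.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `or_mh`, `ci_low`, `ci_high`, `flag`
#'   (`"ok"`, `"undefined"`).
#' @export
#' @examples
#' mantel_haenszel_or(tibble::tibble(a = 20, b = 10, c = 10, d = 20))
mantel_haenszel_or <- function(series, conf_level = 0.95) {
  if (nrow(series) == 0) abort("empty contingency series.")
  a <- as.numeric(series$a); b <- as.numeric(series$b)
  cc <- as.numeric(series$c); d <- as.numeric(series$d)
  n <- a + b + cc + d
  ok <- n > 0
  a <- a[ok]; b <- b[ok]; cc <- cc[ok]; d <- d[ok]; n <- n[ok]
  R_i <- a * d / n
  S_i <- b * cc / n
  R <- sum(R_i); S <- sum(S_i)
  if (R <= 0 || S <= 0) {
    return(tibble(or_mh = if (S <= 0 && R > 0) Inf else NA_real_,
                  ci_low = NA_real_, ci_high = NA_real_,
                  flag = "undefined"))
  }
  P_i <- (a + d) / n
  Q_i <- (b + cc) / n
  v <- sum(P_i * R_i) / (2 * R^2) +
    sum(P_i * S_i + Q_i * R_i) / (2 * R * S) +
    sum(Q_i * S_i) / (2 * S^2)
  or <- R / S
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    or_mh = or,
    ci_low = exp(log(or) - z * sqrt(v)),
    ci_high = exp(log(or) + z * sqrt(v)),
    flag = "ok"
  )
}

#' Cochran-Mantel-Haenszel test of conditional association
#'
#' Chi-square statistic (1 df, no continuity correction)
#' `(sum a_i - sum E_i)^2 / sum V_i`, with `E_i` the hypergeometric
#' expectation of the exposed-with-outcome cell and `V_i` its hypergeometric
#' variance. Degenerate strata (`n_i <= 1` or a zero margin) contribute
#' nothing and are flagged; if every stratum is degenerate the p-value is 1.
#'
#' @param series Tibble with integer columns `a`, `b`, `c`, `d`.
#' @return A one-row tibble: `statistic`, `p_raw`, `df`, `n_degenerate`,
#'   `flag` (`"ok"` or `"degenerate"`).
#' @export
cmh_test <- function(series) {
  if (nrow(series) == 0) abort("empty contingency series.")
  a <- as.numeric(series$a); b <- as.numeric(series$b)
  cc <- as.numeric(series$c); d <- as.numeric(series$d)
  n <- a + b + cc + d
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  usable <- n > 1 & r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  n_degenerate <- sum(!usable)
  if (!any(usable)) {
    return(tibble(statistic = NA_real_, p_raw = 1, df = 1L,
                  n_degenerate = n_degenerate, flag = "degenerate"))
  }
  E <- (r1 * c1 / n)[usable]
  V <- (r1 * r2 * c1 * c2 / (n^2 * (n - 1)))[usable]
  stat <- (sum(a[usable]) - sum(E))^2 / sum(V)
  tibble(
    statistic = stat,
    p_raw = pchisq(stat, df = 1, lower.tail = FALSE),
    df = 1L,
    n_degenerate = n_degenerate,
    flag = if (n_degenerate > 0) "degenerate" else "ok"
  )
}

#' Apply the occurrence filter and Bonferroni significance rule
#'
#' Pairs whose co-occurrence count falls below `min_occurrence` are marked
#' `filtered` and excluded from the Bonferroni family; for the remaining `m`
#' tests `p_corr = min(1, m * p_raw)` and a pair is significant when
#' `or_mh > or_threshold`, `p_corr < alpha` and the occurrence filter is
#' passed.
#'
#' @param results Tibble of draft association results with columns `or_mh`,
#'   `p_raw`, `n_cooccur`.
#' @param m Size of the Bonferroni family; defaults to the number of rows
#'   surviving the occurrence filter.
#' @param min_occurrence Minimum co-occurrence count (default 100).
#' @param or_threshold Minimum pooled odds ratio (default 1.5).
#' @param alpha Corrected significance level (default 0.01).
#' @return `results` with added columns `filtered`, `p_corr`, `significant`
#'   and the applied `m` as attribute `"m"`.
#' @export
screen_associations <- function(results, m = NULL, min_occurrence = 100,
                                or_threshold = 1.5, alpha = 0.01) {
  stopifnot(all(c("or_mh", "p_raw", "n_cooccur") %in% names(results)))
  filtered <- results$n_cooccur < min_occurrence
  if (is.null(m)) m <- sum(!filtered)
  if (m <= 0) abort("Bonferroni family size m must be positive.")
  out <- results %>%
    mutate(
      filtered = filtered,
      p_corr = pmin(1, m * .data$p_raw),
      significant = !filtered &
        !is.na(.data$or_mh) & .data$or_mh > or_threshold &
        .data$p_corr < alpha
    )
  attr(out, "m") <- m
  out
}

#' Screen comorbidities of an index diagnosis
#'
#' Runs the full association screen: for every comorbidity code and every age
#' decade (plus a pooled `"all"` row spanning every stratum), builds the
#' per-window 2x2 series, computes the Mantel-Haenszel pooled odds ratio with
#' its confidence interval and the CMH p-value, then applies the occurrence
#' filter and the Bonferroni significance rule with a single family across
#' all (pair, decade) tests.
#'
#' @param firsts Output of [first_occurrences()].
#' @param strata Output of [assign_strata()].
#' @param exposure_code Index diagnosis code.
#' @param comorbidity_codes Codes to screen against the index diagnosis.
#' @param min_occurrence,or_threshold,alpha Screening thresholds.
#' @param conf_level Confidence level for the pooled OR.
#' @return An object of class `comorbidity_screen`: a list with `results`
#'   (tibble, one row per pair x decade plus the pooled row), `m`,
#'   `thresholds`, `policies` and cohort counts. Use [tidy()] for the result
#'   tibble, [glance()] for the one-row summary and [autoplot()] for a forest
#'   plot.
#' @export
screen_comorbidities <- function(firsts, strata, exposure_code = "E66",
                                 comorbidity_codes,
                                 min_occurrence = 100, or_threshold = 1.5,
                                 alpha = 0.01, conf_level = 0.95) {
  comorbidity_codes <- setdiff(comorbidity_codes, exposure_code)
  if (length(comorbidity_codes) == 0) {
    abort("no comorbidity codes to screen.")
  }
  one_series <- function(code_b) {
    ser <- build_contingency_series(firsts, strata, exposure_code, code_b)
    per_decade <- ser %>%
      tidyr::nest(tables = -"age_decade") %>%
      mutate(code_b = code_b)
    pooled <- tibble(age_decade = "all",
                     tables = list(ser %>% select(-"age_decade")),
                     code_b = code_b)
    bind_rows(per_decade, pooled)
  }
  drafts <- purrr::map(comorbidity_codes, one_series) %>%
    bind_rows() %>%
    mutate(
      est = purrr::map(.data$tables,
                       ~ rename(mantel_haenszel_or(.x, conf_level),
                                est_flag = "flag")),
      tst = purrr::map(.data$tables,
                       ~ rename(cmh_test(.x), test_flag = "flag")),
      n_cooccur = purrr::map_int(.data$tables, ~ sum(.x$a)),
      n_exposed = purrr::map_int(.data$tables, ~ sum(.x$a + .x$b)),
      n_unexposed = purrr::map_int(.data$tables, ~ sum(.x$c + .x$d))
    ) %>%
    tidyr::unnest(c("est", "tst"), names_sep = NULL) %>%
    mutate(
      code_a = exposure_code,
      rate_exposed_pct = 100 * .data$n_cooccur / pmax(.data$n_exposed, 1L),
      rate_unexposed_pct = 100 *
        purrr::map_int(.data$tables, ~ sum(.x$c)) /
        pmax(.data$n_unexposed, 1L),
      flags = paste(.data$est_flag, .data$test_flag, sep = ";")
    )

  decade_rows <- drafts %>% filter(.data$age_decade != "all")
  m <- sum(decade_rows$n_cooccur >= min_occurrence)
  if (m <= 0) {
    abort("no (pair, decade) test survives the occurrence filter.")
  }
  results <- screen_associations(drafts, m = m,
                                 min_occurrence = min_occurrence,
                                 or_threshold = or_threshold,
                                 alpha = alpha) %>%
    select("code_a", "code_b", "age_decade", "or_mh", "ci_low", "ci_high",
           "statistic", "p_raw", "p_corr", "n_cooccur",
           "rate_exposed_pct", "rate_unexposed_pct", "filtered",
           "significant", "flags") %>%
    arrange(.data$code_b, .data$age_decade)

  structure(
    list(
      results = results,
      m = m,
      thresholds = list(min_occurrence = min_occurrence,
                        or_threshold = or_threshold, alpha = alpha,
                        conf_level = conf_level),
      policies = list(
        bonferroni_family = "pair_by_decade_after_occurrence_filter",
        stratum_policy = attr(strata, "policy") %||% NA_character_
      ),
      n_patients = nrow(strata),
      n_exposed = sum(strata$exposed)
    ),
    class = "comorbidity_screen"
  )
}

#' @export
print.comorbidity_screen <- function(x, ...) {
  cat("<comorbidity_screen>\n")
  cat(sprintf("  %d patients (%d exposed); %d tests in Bonferroni family\n",
              x$n_patients, x$n_exposed, x$m))
  cat(sprintf("  thresholds: OR > %.2f, p_corr < %.3g, co-occurrence >= %d\n",
              x$thresholds$or_threshold, x$thresholds$alpha,
              x$thresholds$min_occurrence))
  sig <- x$results %>% filter(.data$significant)
  cat(sprintf("  significant pair x decade cells: %d\n", nrow(sig)))
  print(utils::head(x$results, 10))
  invisible(x)
}
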