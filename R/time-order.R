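## Time-order directionality: gap classes, time-order ratio (TOR), exact
## binomial sign test.

#' Ordered diagnosis pairs for dual-diagnosed patients
#'
#' For every patient carrying both codes, records the two first-occurrence
#' dates, whether they were coded during one hospital stay, the absolute gap
#' in days and the direction (`A_first`, `B_first`, `tie`). Same-stay and
#' same-date pairs are ties: a direction cannot be read off them.
#'
#' @param firsts Output of [first_occurrences()].
#' @param code_a,code_b The diagnosis pair (conventionally the index
#'   diagnosis as `code_a`).
#' @param profiles Optional [patient_profiles()] output; when given, `sex` is
#'   carried along for sex-stratified summaries.
#' @return A tibble with one row per dual-diagnosed patient: `patient_id`,
#'   `code_a`, `code_b`, `date_a`, `date_b`, `same_stay`, `gap_days`,
#'   `direction` (+ `sex` when `profiles` is supplied).
#' @export
ordered_pairs <- function(firsts, code_a, code_b, profiles = NULL) {
  if (identical(code_a, code_b)) abort("code_a and code_b must differ.")
  fa <- firsts %>% filter(.data$code == code_a) %>%
    select("patient_id", date_a = "first_date", stay_a = "first_stay_id")
  fb <- firsts %>% filter(.data$code == code_b) %>%
    select("patient_id", date_b = "first_date", stay_b = "first_stay_id")
  out <- dplyr::inner_join(fa, fb, by = "patient_id") %>%
    mutate(
      code_a = code_a,
      code_b = code_b,
      same_stay = .data$stay_a == .data$stay_b,
      gap_days = abs(as.integer(.data$date_b - .data$date_a)),
      direction = dplyr::case_when(
        same_stay | gap_days == 0L ~ "tie",
        date_a < date_b ~ "A_first",
        TRUE ~ "B_first"
      )
    ) %>%
    select("patient_id", "code_a", "code_b", "date_a", "date_b",
           "same_stay", "gap_days", "direction")
  if (!is.null(profiles)) {
    out <- out %>%
      left_join(profiles %>% select("patient_id", "sex"), by = "patient_id")
  }
  out
}

#' Classify inter-diagnosis gaps into delay classes
#'
#' Four canonical classes: both diagnoses at one stay (`same_stay`), gap of
#' at most about one year (360 days, `lt_1y`), more than one and at most
#' three years (`1y_to_3y`, with 3 years operationalised as 1080 = 3 x 360
#' days), and beyond three years (`gt_3y`). Boundary days fall into the lower
#' class. Alternative windowings (e.g. five-year edges) are supported by
#' passing a different ascending `edges` vector, which relabels classes
#' generically.
#'
#' @param gap_days Integer vector of absolute gaps in days.
#' @param same_stay Logical vector: both codes at one stay.
#' @param edges Ascending day thresholds separating the delayed classes.
#' @return A factor with levels `same_stay` followed by the delay classes.
#' @export
#' @examples
#' classify_gap(c(100, 360, 361, 1200), c(FALSE, FALSE, FALSE, FALSE))
classify_gap <- function(gap_days, same_stay,
                         edges = c(360L, 1080L)) {
  if (any(gap_days < 0, na.rm = TRUE)) abort("gap_days must be non-negative.")
  if (is.unsorted(edges, strictly = TRUE) || any(edges <= 0)) {
    abort("edges must be strictly ascending positive day counts.")
  }
  labels <- if (identical(as.integer(edges), c(360L, 1080L))) {
    c("lt_1y", "1y_to_3y", "gt_3y")
  } else {
    c(sprintf("le_%dd", edges), sprintf("gt_%dd", edges[length(edges)]))
  }
  idx <- findInterval(gap_days, edges + 1L) + 1L  # boundary to lower class
  cls <- ifelse(same_stay, "same_stay", labels[idx])
  factor(cls, levels = c("same_stay", labels))
}

#' Exact binomial sign test for directional counts
#'
#' Tests the null that A-first and B-first counts stem from a binomial
#' distribution with success probability one half, i.e. that neither
#' diagnosis tends to come first. Two-sided by doubling the smaller exact
#' tail: `p = min(1, 2 * min(P(X <= k), P(X >= k)))` with `k` the A-first
#' count over `n = k + n_b_first` trials.
#'
#' @param n_a_first,n_b_first Non-negative directional counts (vectors are
#'   recycled pairwise); their sum must be at least 1.
#' @return Numeric vector of exact two-sided p-values.
#' @export
#' @examples
#' binomial_sign_test(10, 0)   # 2 * 0.5^10
#' binomial_sign_test(5, 5)    # 1
binomial_sign_test <- function(n_a_first, n_b_first) {
  k <- as.numeric(n_a_first); nb <- as.numeric(n_b_first)
  if (any(k < 0 | nb < 0)) abort("directional counts must be non-negative.")
  n <- k + nb
  if (any(n < 1)) abort("need at least one directed pair.")
  lower <- pbinom(k, n, 0.5)
  upper <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Time-order ratios per gap class
#'
#' For each gap class (and optionally each sex), counts A-first, B-first and
#' tied patients, computes the time-order ratio
#' `TOR = n_a_first / n_b_first`, the exact binomial sign test p-value, and
#' each class's share of all dual-diagnosed patients. `TOR > 1` means
#' diagnosis A tends to come first, `TOR < 1` the opposite; ties are counted
#' and reported but enter neither the ratio nor the test. A `TOR` of 2 means
#' twice as many patients received A first as received B first; a `TOR` of
#' 0.5 the reverse.
#'
#' @param pairs Output of [ordered_pairs()] (columns `direction`,
#'   `same_stay`, `gap_days`; plus `sex` if `by_sex`).
#' @param by Grouping: `"gap_class"` (default) for per-class rows, `NULL`
#'   for a single overall row.
#' @param by_sex Additionally stratify by sex.
#' @param edges Gap class edges passed to [classify_gap()].
#' @return A tibble of class `tor_result`: `code_a`, `code_b`
#'   (when present in `pairs`), grouping columns, `n_a_first`, `n_b_first`,
#'   `n_tie`, `tor` (NA sentinel when `n_b_first` is 0), `p_binomial` (NA
#'   when no directed pairs), `group_share_pct`.
#' @export
compute_tor <- function(pairs, by = "gap_class", by_sex = FALSE,
                        edges = c(360L, 1080L)) {
  grp <- character(0)
  if (!is.null(by) && identical(by, "gap_class")) {
    pairs <- pairs %>%
      mutate(gap_class = classify_gap(.data$gap_days, .data$same_stay,
                                      edges = edges))
    grp <- "gap_class"
  } else if (!is.null(by)) {
    abort('`by` must be "gap_class" or NULL.')
  }
  if (by_sex) {
    if (!"sex" %in% names(pairs)) {
      abort("by_sex = TRUE requires a `sex` column (pass `profiles` to ordered_pairs()).")
    }
    grp <- c("sex", grp)
  }
  share_base <- if (by_sex) c("sex") else character(0)

  counts <- pairs %>%
    group_by(dplyr::across(dplyr::all_of(grp)), .drop = FALSE) %>%
    summarise(
      n_a_first = sum(.data$direction == "A_first"),
      n_b_first = sum(.data$direction == "B_first"),
      n_tie = sum(.data$direction == "tie"),
      .groups = "drop"
    )
  if (length(share_base) > 0) {
    counts <- counts %>%
      group_by(dplyr::across(dplyr::all_of(share_base))) %>%
      mutate(group_share_pct =
               100 * (.data$n_a_first + .data$n_b_first + .data$n_tie) /
               sum(.data$n_a_first + .data$n_b_first + .data$n_tie)) %>%
      ungroup()
  } else {
    total <- sum(counts$n_a_first + counts$n_b_first + counts$n_tie)
    counts <- counts %>%
      mutate(group_share_pct =
               100 * (.data$n_a_first + .data$n_b_first + .data$n_tie) /
               total)
  }
  out <- counts %>%
    mutate(
      tor = ifelse(.data$n_b_first > 0,
                   .data$n_a_first / .data$n_b_first, NA_real_),
      p_binomial = {
        k <- .data$n_a_first; nb <- .data$n_b_first
        p <- rep(NA_real_, length(k))
        has <- k + nb >= 1
        if (any(has)) p[has] <- binomial_sign_test(k[has], nb[has])
        p
      }
    ) %>%
    select(dplyr::all_of(grp), "n_a_first", "n_b_first", "n_tie", "tor",
           "p_binomial", "group_share_pct")
  if (all(c("code_a", "code_b") %in% names(pairs)) && nrow(pairs) > 0) {
    out <- out %>%
      mutate(code_a = pairs$code_a[1], code_b = pairs$code_b[1],
             .before = 1L)
  }
  class(out) <- c("tor_result", class(out))
  attr(out, "edges") <- edges
  out
}
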