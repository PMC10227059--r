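## tidy()/glance() methods and ggplot2 autoplot() methods for result objects.

#' Tidy a comorbidity screen
#'
#' @param x A `comorbidity_screen` from [screen_comorbidities()].
#' @param ... Unused.
#' @return The per-(pair, decade) result tibble.
#' @export
tidy.comorbidity_screen <- function(x, ...) {
  x$results
}

#' One-row summary of a comorbidity screen
#'
#' @param x A `comorbidity_screen`.
#' @param ... Unused.
#' @return A one-row tibble: cohort sizes, Bonferroni family size,
#'   thresholds, and counts of tested / filtered / significant cells.
#' @export
glance.comorbidity_screen <- function(x, ...) {
  decade <- x$results %>% filter(.data$age_decade != "all")
  tibble(
    n_patients = x$n_patients,
    n_exposed = x$n_exposed,
    m = x$m,
    n_tested = sum(!decade$filtered),
    n_filtered = sum(decade$filtered),
    n_significant = sum(decade$significant),
    min_occurrence = x$thresholds$min_occurrence,
    or_threshold = x$thresholds$or_threshold,
    alpha = x$thresholds$alpha
  )
}

#' Forest plot of pooled odds ratios by age decade
#'
#' @param object A `comorbidity_screen`.
#' @param ... Unused.
#' @return A ggplot: one panel per comorbidity code, pooled OR with its
#'   confidence interval per age decade; unfiltered significant cells are
#'   highlighted, the OR threshold and the null line are drawn.
#' @export
autoplot.comorbidity_screen <- function(object, ...) {
  df <- object$results %>%
    filter(.data$age_decade != "all", !.data$filtered,
           is.finite(.data$or_mh))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_decade, y = .data$or_mh)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_hline(yintercept = object$thresholds$or_threshold,
                        linetype = "dotted", colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high,
                   colour = .data$significant)
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$code_b)) +
    ggplot2::labs(
      x = "age decade at anchor", y = "Mantel-Haenszel pooled OR (log scale)",
      colour = "significant",
      title = sprintf("Comorbidity screen of %s",
                      object$results$code_a[1])
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot time-order ratios by gap class
#'
#' @param object A `tor_result` from [compute_tor()].
#' @param ... Unused.
#' @return A ggplot of TOR per gap class (log scale, null line at 1),
#'   annotated with conventional significance stars from the exact binomial
#'   sign test (uncorrected).
#' @export
autoplot.tor_result <- function(object, ...) {
  df <- as_tibble(object) %>%
    filter(!is.na(.data$tor)) %>%
    mutate(stars = dplyr::case_when(
      .data$p_binomial < 0.001 ~ "***",
      .data$p_binomial < 0.01 ~ "**",
      .data$p_binomial < 0.05 ~ "*",
      TRUE ~ ""
    ))
  aes_fill <- if ("sex" %in% names(df)) {
    ggplot2::aes(x = .data$gap_class, y = .data$tor, fill = .data$sex)
  } else {
    ggplot2::aes(x = .data$gap_class, y = .data$tor)
  }
  p <- ggplot2::ggplot(df, aes_fill) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), vjust = -0.3,
                       position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "gap between first diagnoses",
                  y = "time-order ratio (A first / B first, log scale)") +
    ggplot2::theme_minimal()
  if (all(c("code_a", "code_b") %in% names(df)) && nrow(df) > 0) {
    p <- p + ggplot2::ggtitle(sprintf("%s → %s", df$code_a[1],
                                      df$code_b[1]))
  }
  p
}
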