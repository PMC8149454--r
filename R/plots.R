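#' @import ggplot2
NULL

#' Plot relative quantification across tissues
#'
#' Bars of RQ per tissue with the confidence interval as error bars, one
#' facet per gene — the usual presentation of a qPCR tissue panel.
#'
#' @param results a [delta_delta_ct()] (or [normalize_to_max_tissue()])
#'   result.
#' @return a ggplot.
#' @export
plot_rq <- function(results) {
  check_columns(results, c("gene", "tissue", "rq"), "`results`")
  ggplot(results, aes(x = .data$tissue, y = .data$rq)) +
    geom_col(fill = "grey35") +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                  width = 0.25, na.rm = TRUE) +
    facet_wrap(vars(.data$gene), scales = "free_y") +
    labs(x = NULL, y = "relative quantification (RQ)") +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot the genomic category split of annotated peaks
#'
#' @param annotated an [annotate_peaks()] result.
#' @return a ggplot of category fractions.
#' @export
plot_peak_categories <- function(annotated) {
  check_columns(annotated, "category", "`annotated`")
  counts <- count(annotated, .data$category) |>
    mutate(fraction = .data$n / sum(.data$n))
  ggplot(counts, aes(x = .data$category, y = .data$fraction)) +
    geom_col(fill = "steelblue") +
    geom_text(aes(label = sprintf("%.1f%%", 100 * .data$fraction)),
              vjust = -0.3, size = 3) +
    labs(x = NULL, y = "fraction of consensus peaks") +
    theme_bw()
}

#' Plot a motif-enrichment profile
#'
#' Bonferroni-adjusted significance (-log10 p) per motif and peak class.
#'
#' @param profile an [enrichment_profile()] result.
#' @param alpha significance reference line.
#' @return a ggplot.
#' @export
plot_enrichment <- function(profile, alpha = 0.05) {
  check_columns(profile, c("motif_id", "peak_class", "p_adjusted"),
                "`profile`")
  ggplot(profile, aes(x = .data$motif_id, y = -log10(pmax(.data$p_adjusted, 1e-300)),
                      fill = .data$peak_class)) +
    geom_col(position = "dodge") +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    labs(x = NULL, y = expression(-log[10] ~ "adjusted p"), fill = "class") +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot dose-response relative activities
#'
#' Per-group points with group means, ordered by dose.
#'
#' @param activities tibble with `group` and `relative_activity`.
#' @param dose_order group labels in increasing dose order.
#' @return a ggplot.
#' @export
plot_dose_response <- function(activities, dose_order = NULL) {
  check_columns(activities, c("group", "relative_activity"), "`activities`")
  if (!is.null(dose_order)) {
    activities <- mutate(activities,
                         group = factor(.data$group, levels = dose_order))
  }
  ggplot(activities, aes(x = .data$group, y = .data$relative_activity)) +
    geom_violin(fill = "grey90", colour = NA) +
    geom_jitter(width = 0.08, size = 1.5) +
    stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                 colour = "firebrick") +
    labs(x = NULL, y = "relative luciferase activity") +
    theme_bw()
}

#' Plot a synergy test
#'
#' Histogram of the pooled-sum values with the percentile interval and the
#' observed combined-group mean.
#'
#' @param object a `synergy_test`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot synergy_test
#' @export
autoplot.synergy_test <- function(object, ...) {
  pool_tbl <- tibble(value = object$pool$values)
  ggplot(pool_tbl, aes(x = .data$value)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    geom_vline(xintercept = c(object$pool$ci_low, object$pool$ci_high),
               linetype = "dashed") +
    geom_vline(xintercept = object$observed_mean, colour = "firebrick",
               linewidth = 1) +
    labs(
      x = "pooled sum of single-effector activities",
      y = "count",
      title = sprintf("observed mean %.2f, bootstrap p = %.3g",
                      object$observed_mean, object$p_value)
    ) +
    theme_bw()
}
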