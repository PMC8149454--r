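#' @title ChIP-qPCR fold enrichment
#' @description Fold enrichment by the signal-over-background method:
#'   per replicate, the input-normalized specific-antibody signal divided by
#'   the input-normalized mock (IgG) signal, with significance from a
#'   one-sided one-sample t test of the mean fold enrichment against 1.
#' @name chip
NULL

#' Per-replicate ChIP-qPCR fold enrichment
#'
#' For each replicate of a target site, signal = eff^-(Ct_IP - Ct_input')
#' for the specific antibody and for the mock, where Ct_input' is the input
#' Ct corrected for the input dilution (Ct_input - log_eff of the dilution
#' factor); fold enrichment is the specific/mock signal ratio.
#'
#' @param table tibble: `site`, `antibody` (`"specific"` / `"mock_igg"`),
#'   `fraction` (`"ip"` / `"input"`), `replicate`, `ct`.
#' @param site target site to evaluate (default: the only site present).
#' @param input_dilution_factor fold dilution of the input fraction.
#' @param efficiency amplification efficiency per cycle (2 = perfect
#'   doubling).
#' @return tibble: `site`, `replicate`, `fold_enrichment`.
#' @export
fold_enrichment <- function(table, site = NULL, input_dilution_factor = 1,
                            efficiency = 2) {
  check_columns(table, c("site", "antibody", "fraction", "replicate", "ct"),
                "`table`")
  if (any(table$ct <= 0 | is.na(table$ct))) abort("Ct values must be positive.")
  if (efficiency <= 1) abort("`efficiency` must exceed 1.")
  if (is.null(site)) {
    site <- unique(table$site)
    if (length(site) != 1) abort("multiple sites present; name one with `site`.")
  }
  tab <- filter(table, .data$site == !!site)
  if (nrow(tab) == 0) abort(paste0("no rows for site '", site, "'."))
  wide <- tab |>
    select("antibody", "fraction", "replicate", "ct") |>
    pivot_wider(names_from = c("antibody", "fraction"), values_from = "ct")
  need <- c("specific_ip", "specific_input", "mock_igg_ip", "mock_igg_input")
  missing <- setdiff(need, names(wide))
  if (length(missing) > 0) {
    abort(paste0("site '", site, "' is missing ",
                 paste(gsub("_(ip|input)$", " \\1", missing), collapse = ", "),
                 " rows."))
  }
  gaps <- filter(wide, dplyr::if_any(dplyr::all_of(need), is.na))
  if (nrow(gaps) > 0) {
    abort(paste0("site '", site, "', replicate ", gaps$replicate[[1]],
                 " is missing an ip/input or mock row."))
  }
  adj <- log(input_dilution_factor, base = efficiency)
  wide |>
    mutate(
      signal_specific = efficiency^(-(.data$specific_ip - (.data$specific_input - adj))),
      signal_mock = efficiency^(-(.data$mock_igg_ip - (.data$mock_igg_input - adj))),
      fold_enrichment = .data$signal_specific / .data$signal_mock,
      site = site
    ) |>
    select("site", "replicate", "fold_enrichment") |>
    arrange(.data$replicate)
}

#' One-sided significance of mean fold enrichment against 1
#'
#' One-sample t test of the replicate fold enrichments with null mean 1,
#' upper-tailed (enrichment above mock).
#'
#' @param fe_values numeric vector of per-replicate fold enrichments
#'   (>= 2 values with nonzero variance).
#' @return one-row tibble: `mean_fe`, `t`, `df`, `p`.
#' @examples
#' enrichment_significance(c(1.5, 2.0, 2.5))
#' @export
enrichment_significance <- function(fe_values) {
  if (length(fe_values) < 2) abort("need at least 2 fold-enrichment values.")
  if (stats::sd(fe_values) == 0) abort("fold enrichments have zero variance.")
  tt <- stats::t.test(fe_values, mu = 1, alternative = "greater")
  tibble(mean_fe = mean(fe_values), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value)
}

#' Fold enrichment with significance for one ChIP-qPCR site
#'
#' Convenience wrapper: [fold_enrichment()] followed by
#' [enrichment_significance()].
#'
#' @inheritParams fold_enrichment
#' @return object of class `chip_enrichment`: list with `site`,
#'   `replicates` (per-replicate tibble) and `summary` (one-row tibble with
#'   `mean_fe`, `t`, `df`, `p`).
#' @export
chip_test <- function(table, site = NULL, input_dilution_factor = 1,
                      efficiency = 2) {
  fe <- fold_enrichment(table, site, input_dilution_factor, efficiency)
  structure(
    list(site = fe$site[[1]], replicates = fe,
         summary = enrichment_significance(fe$fold_enrichment)),
    class = "chip_enrichment"
  )
}

#' @export
print.chip_enrichment <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<chip_enrichment> %s: mean FE %.3f (n = %d), t = %.3f, one-sided p = %.4g\n",
              x$site, s$mean_fe, nrow(x$replicates), s$t, s$p))
  invisible(x)
}
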