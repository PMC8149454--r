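#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a synergy test
#'
#' @param x a `synergy_test` from [synergy_bootstrap_p()].
#' @param ... unused.
#' @return one-row tibble: `observed_mean`, `pool_mean`, `ci_low`,
#'   `ci_high`, `confidence`, `p_value`, `n_boot`.
#' @method tidy synergy_test
#' @export
tidy.synergy_test <- function(x, ...) {
  tibble(
    observed_mean = x$observed_mean,
    pool_mean = mean(x$pool$values),
    ci_low = x$pool$ci_low, ci_high = x$pool$ci_high,
    confidence = x$pool$confidence,
    p_value = x$p_value, n_boot = x$n_boot
  )
}

#' @rdname tidy.synergy_test
#' @method glance synergy_test
#' @export
glance.synergy_test <- function(x, ...) tidy(x, ...)

#' Tidy a pooled-sum null
#'
#' @param x a [pooled_sum_null()] object.
#' @param ... unused.
#' @return one-row tibble: `n`, `mean`, `ci_low`, `ci_high`, `confidence`.
#' @method tidy sum_pool
#' @export
tidy.sum_pool <- function(x, ...) {
  tibble(n = length(x$values), mean = mean(x$values),
         ci_low = x$ci_low, ci_high = x$ci_high, confidence = x$confidence)
}

#' Tidy a ChIP enrichment result
#'
#' @param x a [chip_test()] result.
#' @param ... unused.
#' @return the per-replicate fold-enrichment tibble.
#' @method tidy chip_enrichment
#' @export
tidy.chip_enrichment <- function(x, ...) x$replicates

#' @rdname tidy.chip_enrichment
#' @return for `glance`: one-row tibble `site`, `mean_fe`, `t`, `df`, `p`.
#' @method glance chip_enrichment
#' @export
glance.chip_enrichment <- function(x, ...) {
  mutate(x$summary, site = x$site, .before = 1)
}

#' Tidy an organ-enrichment result
#'
#' @param x an [enriched_genes()] result.
#' @param ... unused.
#' @return the per-comparison tibble (`gene`, `focal`, `other`, `log2fc`,
#'   `p`, `qualifies`).
#' @method tidy organ_enrichment
#' @export
tidy.organ_enrichment <- function(x, ...) x$comparisons

#' @rdname tidy.organ_enrichment
#' @return for `glance`: one-row tibble `n_enriched`, `alpha`, `mode`.
#' @method glance organ_enrichment
#' @export
glance.organ_enrichment <- function(x, ...) {
  tibble(n_enriched = length(x$genes), alpha = x$alpha, mode = x$mode)
}

#' Tidy a scan threshold
#'
#' @param x a [calibrate_threshold()] result.
#' @param ... unused.
#' @return one-row tibble: `pwm_id`, `fpr`, `threshold`, `n_background`.
#' @method tidy scan_threshold
#' @export
tidy.scan_threshold <- function(x, ...) {
  tibble(pwm_id = x$pwm_id, fpr = x$fpr, threshold = x$threshold,
         n_background = x$n_background)
}

#' Tidy a PWM into long form
#'
#' @param x a [pwm()].
#' @param ... unused.
#' @return tibble: `position`, `base`, `probability`.
#' @method tidy pwm
#' @export
tidy.pwm <- function(x, ...) {
  as_tibble(x$matrix) |>
    mutate(position = dplyr::row_number(), .before = 1) |>
    pivot_longer(-"position", names_to = "base", values_to = "probability")
}
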