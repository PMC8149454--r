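#' @title Dual-luciferase statistics and the pooled-sum synergy test
#' @description Firefly/Renilla well measurements are normalized so the
#'   blank-effector control group has mean relative activity exactly 1.00;
#'   dose responses are compared between adjacent dose groups by two-sided
#'   Student t tests with Holm correction; and co-transfection synergy is
#'   tested against the pool of all pairwise sums of the two single-effector
#'   groups' activities, with significance from bootstrap resampling of that
#'   sum pool.
#' @name reporter
NULL

#' Relative luciferase activity
#'
#' Per well, the firefly/Renilla ratio is divided by the mean ratio of the
#' control group, so the control group's mean relative activity is exactly
#' 1.00.
#'
#' @param table tibble: `group`, `bio_replicate`, `tech_replicate`,
#'   `firefly`, `renilla` (Renilla must be positive).
#' @param control_group label of the blank-effector control.
#' @return `table` with added `ratio` and `relative_activity` columns.
#' @export
relative_activity <- function(table, control_group) {
  check_columns(table, c("group", "bio_replicate", "tech_replicate",
                         "firefly", "renilla"), "`table`")
  if (any(table$renilla <= 0 | is.na(table$renilla))) {
    abort("Renilla readings must be positive.")
  }
  ctrl <- table$group == control_group
  if (!any(ctrl)) abort(paste0("control group '", control_group, "' has no wells."))
  table <- mutate(as_tibble(table), ratio = .data$firefly / .data$renilla)
  mutate(table, relative_activity = .data$ratio / mean(.data$ratio[ctrl]))
}

#' Average technical replicates into biological replicates
#'
#' @param activities a [relative_activity()] result.
#' @return tibble: `group`, `bio_replicate`, `relative_activity` (mean over
#'   technical replicates).
#' @export
collapse_tech_reps <- function(activities) {
  check_columns(activities, c("group", "bio_replicate", "relative_activity"),
                "`activities`")
  activities |>
    group_by(.data$group, .data$bio_replicate) |>
    summarise(relative_activity = mean(.data$relative_activity),
              .groups = "drop")
}

#' Adjacent-dose Student t tests with Holm correction
#'
#' Two-sided pooled-variance Student t tests between each adjacent pair of
#' dose groups, Holm-adjusted across the pairs. A pair where both groups
#' have zero variance is flagged (`degenerate = TRUE`) and excluded from
#' adjustment.
#'
#' @param activities tibble with `group` and `relative_activity` (one row
#'   per biological replicate; use [collapse_tech_reps()] first for
#'   technical-replicate designs).
#' @param dose_order group labels in increasing dose order; defaults to
#'   factor levels or order of appearance.
#' @return tibble: `group_low`, `group_high`, `t`, `df`, `p`, `p_adj`,
#'   `degenerate`.
#' @export
dose_response_tests <- function(activities, dose_order = NULL) {
  check_columns(activities, c("group", "relative_activity"), "`activities`")
  if (is.null(dose_order)) {
    dose_order <- if (is.factor(activities$group)) levels(activities$group)
      else unique(activities$group)
  }
  if (length(dose_order) < 2) abort("need at least two dose groups.")
  vals <- map(dose_order, ~ activities$relative_activity[activities$group == .x])
  if (any(lengths(vals) < 2)) abort("each dose group needs >= 2 values.")
  res <- map(seq_len(length(dose_order) - 1L), function(i) {
    x <- vals[[i]]; y <- vals[[i + 1L]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(tibble(group_low = dose_order[[i]], group_high = dose_order[[i + 1L]],
                    t = NA_real_, df = NA_real_, p = NA_real_, degenerate = TRUE))
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    tibble(group_low = dose_order[[i]], group_high = dose_order[[i + 1L]],
           t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, degenerate = FALSE)
  }) |> list_rbind()
  mutate(res, p_adj = stats::p.adjust(.data$p, method = "holm"),
         .after = "p")
}

#' Pooled-sum null distribution for two effector groups
#'
#' Forms every pairwise sum of the two groups' relative activities — the
#' null distribution of a combined-effector activity under additivity of
#' the measured single-effector activities — and its central percentile
#' interval (linear-interpolation empirical quantiles).
#'
#' @param group_a,group_b numeric vectors of relative activities.
#' @param confidence central interval mass.
#' @return object of class `sum_pool`: `values` (length
#'   `length(group_a) * length(group_b)`), `ci_low`, `ci_high`,
#'   `confidence`.
#' @export
pooled_sum_null <- function(group_a, group_b, confidence = 0.95) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both effector groups must be non-empty.")
  }
  check_probability(confidence, "confidence")
  values <- as.vector(outer(group_a, group_b, "+"))
  ci <- unname(stats::quantile(values, c((1 - confidence) / 2,
                                         1 - (1 - confidence) / 2), type = 7))
  structure(list(values = values, ci_low = ci[[1]], ci_high = ci[[2]],
                 confidence = confidence),
            class = "sum_pool")
}

#' @export
print.sum_pool <- function(x, ...) {
  cat(sprintf("<sum_pool> %d pairwise sums, mean %.3f, %.0f%% CI [%.3f, %.3f]\n",
              length(x$values), mean(x$values), 100 * x$confidence,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Bootstrap synergy test against a pooled-sum null
#'
#' Tests whether the combined-effector group's mean relative activity is
#' higher than expected from the sum of the individual effector activities.
#' Each bootstrap iteration resamples `length(combined_group)` values with
#' replacement from the sum pool and records their mean; the one-sided
#' p value is `(1 + #\{boot mean >= observed mean\}) / (n_boot + 1)`.
#'
#' @param pool a [pooled_sum_null()] object.
#' @param combined_group relative activities of the co-transfected group.
#' @param n_boot bootstrap iterations.
#' @param seed optional integer; fixed seed gives a bit-identical p value.
#' @return object of class `synergy_test`: `observed_mean`, `pool`,
#'   `p_value`, `n_boot`, `seed`, `boot_means` summary quantiles.
#' @export
synergy_bootstrap_p <- function(pool, combined_group, n_boot = 100000,
                                seed = NULL) {
  stopifnot(inherits(pool, "sum_pool"))
  if (length(pool$values) == 0) abort("empty sum pool.")
  if (length(combined_group) == 0) abort("`combined_group` must be non-empty.")
  if (n_boot < 1) abort("`n_boot` must be at least 1.")
  m <- length(combined_group)
  observed <- mean(combined_group)
  boot_means <- with_seed(seed, {
    out <- numeric(n_boot)
    # draw in chunks to bound memory for large n_boot
    chunk <- max(1L, min(n_boot, as.integer(2e6 / m)))
    done <- 0L
    while (done < n_boot) {
      k <- min(chunk, n_boot - done)
      draws <- matrix(sample(pool$values, k * m, replace = TRUE), nrow = m)
      out[(done + 1L):(done + k)] <- colMeans(draws)
      done <- done + k
    }
    out
  })
  p <- (1 + sum(boot_means >= observed)) / (n_boot + 1)
  structure(
    list(observed_mean = observed, pool = pool, p_value = p,
         n_boot = as.integer(n_boot), seed = seed,
         boot_quantiles = stats::quantile(boot_means, c(0.025, 0.5, 0.975))),
    class = "synergy_test"
  )
}

#' @export
print.synergy_test <- function(x, ...) {
  cat(sprintf(paste0("<synergy_test> observed mean %.3f vs pooled-sum %.0f%% CI ",
                     "[%.3f, %.3f]\n  one-sided bootstrap p = %.4g (n_boot = %d)\n"),
              x$observed_mean, 100 * x$pool$confidence, x$pool$ci_low,
              x$pool$ci_high, x$p_value, x$n_boot))
  invisible(x)
}

#' End-to-end synergy analysis of a luciferase table
#'
#' Normalizes the table with [relative_activity()], averages technical into
#' biological replicates, builds the pooled-sum null from the two
#' single-effector groups and runs the bootstrap synergy test on the
#' combined group.
#'
#' @param table luciferase measurement tibble (see [relative_activity()]).
#' @param control_group,group_a,group_b,combined group labels.
#' @param confidence pooled-sum interval mass.
#' @param n_boot,seed bootstrap settings (see [synergy_bootstrap_p()]).
#' @return a `synergy_test` object; its `activities` element holds the
#'   per-biological-replicate relative activities.
#' @export
luciferase_synergy <- function(table, control_group, group_a, group_b,
                               combined, confidence = 0.95, n_boot = 100000,
                               seed = NULL) {
  acts <- collapse_tech_reps(relative_activity(table, control_group))
  pull_group <- function(g) {
    v <- acts$relative_activity[acts$group == g]
    if (length(v) == 0) abort(paste0("group '", g, "' has no wells."))
    v
  }
  pool <- pooled_sum_null(pull_group(group_a), pull_group(group_b), confidence)
  res <- synergy_bootstrap_p(pool, pull_group(combined), n_boot, seed)
  res$activities <- acts
  res
}
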