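#' @title Motif enrichment in peak classes
#' @description Over-representation of a motif in a peak class relative to
#'   background sequence is tested at the sequence level: a peak or
#'   background sequence counts as a hit when it contains at least one
#'   passing motif site. The test is the one-sided Fisher exact
#'   (hypergeometric upper tail) probability of at least the observed number
#'   of hit peaks, and p values are Bonferroni-corrected across all
#'   motif-by-class tests of a profile.
#' @name enrichment
NULL

#' One-sided Fisher exact enrichment test
#'
#' Probability, under the pooled-proportion null, that the class contains at
#' least `hits_in_class` hit sequences — the hypergeometric upper tail of
#' the 2x2 table (class vs background, hit vs no hit).
#'
#' @param hits_in_class,class_size hit count and total size of the class.
#' @param hits_in_background,background_size same for the background.
#' @return raw one-sided p value.
#' @examples
#' enrichment_test(8, 10, 2, 10)  # = 2126/184756
#' @export
enrichment_test <- function(hits_in_class, class_size,
                            hits_in_background, background_size) {
  counts <- c(hits_in_class, class_size, hits_in_background, background_size)
  if (any(counts < 0) || anyNA(counts)) abort("counts must be non-negative.")
  if (class_size == 0) abort("`class_size` must be positive.")
  if (hits_in_class > class_size || hits_in_background > background_size) {
    abort("hit counts cannot exceed the corresponding totals.")
  }
  k <- hits_in_class + hits_in_background
  # P(X >= hits_in_class), X ~ Hypergeometric(total hits k, draws class_size)
  stats::phyper(hits_in_class - 1, k,
                class_size + background_size - k, class_size,
                lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' Multiplies each p value by the number of tests and caps at 1; order is
#' preserved.
#'
#' @param p_values numeric vector of raw p values in \[0, 1\].
#' @return adjusted p values.
#' @export
bonferroni <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p values must lie in [0, 1].")
  }
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Motif enrichment profile across peak classes
#'
#' For each motif, calibrates a scan threshold on the background at the
#' given false-positive rate, counts sequences containing at least one
#' passing site in each peak class and in the background, tests each class
#' against the background with [enrichment_test()], and applies
#' [bonferroni()] across every motif-by-class test performed in the call.
#'
#' @param motifs list of [pwm()] objects (or a single one).
#' @param classes named list of region sets (each a tibble with
#'   `region_id`/`sequence`, a named character vector, or `DNAStringSet`),
#'   e.g. `list(promoter = ..., enhancer = ...)`. Classes must be disjoint
#'   region sets.
#' @param background a [background_model()].
#' @param fpr calibration false-positive rate.
#' @return tibble: `motif_id`, `peak_class`, `hits_in_class`, `class_size`,
#'   `hits_in_background`, `background_size`, `threshold`, `p_raw`,
#'   `p_adjusted`.
#' @export
enrichment_profile <- function(motifs, classes, background, fpr = 0.01) {
  if (inherits(motifs, "pwm")) motifs <- list(motifs)
  stopifnot(inherits(background, "background_model"))
  if (is.null(names(classes)) || any(!nzchar(names(classes)))) {
    abort("`classes` must be a named list of region sets.")
  }
  class_tbls <- map(classes, as_region_tbl)
  ids <- unlist(map(class_tbls, "region_id"))
  if (anyDuplicated(ids)) abort("peak classes must be disjoint region sets.")

  rows <- list_rbind(map(motifs, function(m) {
    thr <- calibrate_threshold(m, background, fpr = fpr)
    bg_hit <- sum(max_scan_score(m, background$sequences, background) >= thr$threshold)
    list_rbind(imap(class_tbls, function(tbl, cls) {
      n_hit <- scan_regions(m, tbl, thr, background, passing_only = TRUE) |>
        distinct(.data$region_id) |>
        nrow()
      tibble(
        motif_id = m$id, peak_class = cls,
        hits_in_class = n_hit, class_size = nrow(tbl),
        hits_in_background = bg_hit,
        background_size = length(background$sequences),
        threshold = thr$threshold,
        p_raw = enrichment_test(n_hit, nrow(tbl), bg_hit,
                                length(background$sequences))
      )
    }))
  }))
  mutate(rows, p_adjusted = bonferroni(.data$p_raw))
}
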