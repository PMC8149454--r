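#' @title Log-odds scoring and FPR-calibrated motif scanning
#' @description Core scan machinery: windows are scored as
#'   `sum_i log2(P_pwm(base_i) / P_bg(base_i))`; a pass/fail score threshold
#'   is calibrated so that a chosen fraction (the false-positive rate) of
#'   background sequences would contain at least one passing site; scanning
#'   evaluates every offset on both strands.
#' @name scanning
NULL

# log-odds matrices for both strands. Reverse-strand scores are obtained by
# scoring the forward sequence with the reverse-complemented PWM against the
# complement-swapped background frequencies. A 5th column of zeros absorbs N.
.logodds_pair <- function(pwm, freqs) {
  fwd <- log2(sweep(pwm$matrix, 2, freqs[DNA_BASES4], "/"))
  rc <- pwm_revcomp(pwm)
  rev_freqs <- freqs[c("T", "G", "C", "A")]
  names(rev_freqs) <- DNA_BASES4
  rev <- log2(sweep(rc$matrix, 2, rev_freqs, "/"))
  fwd <- unname(cbind(fwd, 0))
  rev <- unname(cbind(rev, 0))
  list(fwd = fwd, rev = rev)
}

.encode_seq <- function(seq) {
  codes <- match(strsplit(toupper(seq), "")[[1]], c(DNA_BASES4, "N"))
  if (anyNA(codes)) abort("sequence contains characters outside A/C/G/T/N.")
  codes
}

# per-offset scores of one sequence under one log-odds matrix (L x 5)
.scores_one_strand <- function(lo, codes) {
  L <- nrow(lo)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  offs <- seq_len(n)
  for (j in seq_len(L)) s <- s + lo[j, codes[offs + j - 1L]]
  s
}

#' Score a single window against a PWM
#'
#' Returns the log-odds score in bits of a window whose length equals the
#' motif width: `sum_i log2(P_pwm(base_i at i) / P_bg(base_i))`. N bases
#' contribute 0 bits (neutral).
#'
#' @param pwm a [pwm()].
#' @param window DNA string of length `length(pwm)`.
#' @param background a [background_model()] (its `freqs` are used), or a
#'   4-vector of base frequencies; default uniform.
#' @return score in bits.
#' @examples
#' p <- pwm(matrix(0.25, 6, 4))
#' score_window(p, "ACGTAC")  # uniform motif on uniform background: 0 bits
#' @export
score_window <- function(pwm, window, background = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  freqs <- .bg_freqs(background)
  codes <- .encode_seq(window)
  if (length(codes) != nrow(pwm$matrix)) {
    abort(paste0("window length ", length(codes), " does not match motif width ",
                 nrow(pwm$matrix), "."))
  }
  lo <- cbind(log2(sweep(pwm$matrix, 2, freqs[DNA_BASES4], "/")), 0)
  sum(lo[cbind(seq_along(codes), codes)])
}

.bg_freqs <- function(background) {
  if (is.null(background)) {
    stats::setNames(rep(0.25, 4), DNA_BASES4)
  } else if (inherits(background, "background_model")) {
    background$freqs
  } else if (is.numeric(background) && length(background) == 4) {
    stats::setNames(as.numeric(background) / sum(background), DNA_BASES4)
  } else {
    abort("`background` must be a background_model, 4 frequencies, or NULL.")
  }
}

#' Per-sequence maximum scan score
#'
#' The best log-odds score over every offset and both strands of each
#' sequence — the statistic whose background distribution calibrates the
#' scan threshold.
#'
#' @param pwm a [pwm()].
#' @param sequences character vector or `DNAStringSet`.
#' @param background frequencies for scoring (see [score_window()]).
#' @return numeric vector, one value per sequence (`-Inf` for sequences
#'   shorter than the motif).
#' @export
max_scan_score <- function(pwm, sequences, background = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  if (inherits(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  lo <- .logodds_pair(pwm, .bg_freqs(background))
  vapply(sequences, function(s) {
    codes <- .encode_seq(s)
    max(c(.scores_one_strand(lo$fwd, codes),
          .scores_one_strand(lo$rev, codes), -Inf))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Calibrate a scan threshold at a target false-positive rate
#'
#' Scores every background sequence's per-sequence maximum (both strands,
#' all offsets) and sets the threshold at the empirical `1 - fpr` quantile
#' of that distribution, using the inclusive lower empirical quantile
#' (ascending sort, index `ceiling((1 - fpr) * n)`). A held-out background
#' sequence then contains a passing site with probability approximately
#' `fpr`.
#'
#' @param pwm a [pwm()].
#' @param background a [background_model()] whose sequences are all at least
#'   as long as the motif.
#' @param fpr target per-sequence false-positive rate in (0, 1].
#' @return object of class `scan_threshold`: `pwm_id`, `fpr`, `threshold`
#'   (bits), `n_background`.
#' @export
calibrate_threshold <- function(pwm, background, fpr = 0.01) {
  stopifnot(inherits(pwm, "pwm"), inherits(background, "background_model"))
  check_probability(fpr, "fpr")
  if (length(background$sequences) < 1) abort("empty background.")
  if (any(nchar(background$sequences) < nrow(pwm$matrix))) {
    abort("every background sequence must be at least as long as the motif.")
  }
  maxima <- max_scan_score(pwm, background$sequences, background)
  n <- length(maxima)
  idx <- max(1L, as.integer(ceiling((1 - fpr) * n)))
  structure(
    list(pwm_id = pwm$id, fpr = fpr, threshold = sort(maxima)[idx],
         n_background = n),
    class = "scan_threshold"
  )
}

#' @export
print.scan_threshold <- function(x, ...) {
  cat(sprintf("<scan_threshold> %s: %.3f bits (fpr %.3g, n_background %d)\n",
              x$pwm_id, x$threshold, x$fpr, x$n_background))
  invisible(x)
}

#' Scan regions for motif occurrences
#'
#' Evaluates every offset of every region on both strands. At each offset the
#' better-scoring strand is reported (ties, within 1e-9 bits, go to the
#' forward strand), and
#' `passed` flags scores at or above the calibrated threshold. Regions
#' shorter than the motif yield no rows.
#'
#' @param pwm a [pwm()].
#' @param regions tibble with columns `region_id` and `sequence`, a named
#'   character vector, or a named `DNAStringSet`.
#' @param threshold a [calibrate_threshold()] result for this PWM, or a
#'   number of bits.
#' @param background frequencies for scoring (see [score_window()]).
#' @param passing_only drop rows with `passed = FALSE`.
#' @return tibble: `pwm_id`, `region_id`, `offset` (0-based), `strand`,
#'   `score` (bits), `passed`; ordered by region (input order) then offset.
#' @export
scan_regions <- function(pwm, regions, threshold, background = NULL,
                         passing_only = FALSE) {
  stopifnot(inherits(pwm, "pwm"))
  regions <- as_region_tbl(regions)
  if (inherits(threshold, "scan_threshold")) {
    if (!identical(threshold$pwm_id, pwm$id)) {
      abort(paste0("threshold was calibrated for '", threshold$pwm_id,
                   "', not '", pwm$id, "'."))
    }
    cut <- threshold$threshold
  } else if (is.numeric(threshold) && length(threshold) == 1L) {
    cut <- threshold
  } else {
    abort("`threshold` must be a scan_threshold or a single number of bits.")
  }
  lo <- .logodds_pair(pwm, .bg_freqs(background))
  out <- map2(regions$region_id, regions$sequence, function(id, s) {
    codes <- .encode_seq(s)
    f <- .scores_one_strand(lo$fwd, codes)
    if (length(f) == 0) return(NULL)
    r <- .scores_one_strand(lo$rev, codes)
    # strand ties (within numerical noise, e.g. palindromic windows) are
    # reported on the forward strand for deterministic output
    take_rev <- r > f + 1e-9
    score <- ifelse(take_rev, r, f)
    tibble(
      pwm_id = pwm$id, region_id = id, offset = seq_along(f) - 1L,
      strand = ifelse(take_rev, "-", "+"),
      score = score, passed = score >= cut
    )
  })
  out <- list_rbind(out)
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(pwm_id = character(), region_id = character(),
                  offset = integer(), strand = character(),
                  score = numeric(), passed = logical())
  }
  if (passing_only) out <- filter(out, .data$passed)
  out
}

#' Coerce sequences to the region-table form used by the scanner
#' @param regions tibble with `region_id`/`sequence` columns, a named
#'   character vector, or a `DNAStringSet`.
#' @return tibble with columns `region_id`, `sequence`.
#' @export
as_region_tbl <- function(regions) {
  if (inherits(regions, "DNAStringSet")) {
    regions <- stats::setNames(as.character(regions), names(regions))
  }
  if (is.character(regions)) {
    ids <- names(regions)
    if (is.null(ids)) ids <- paste0("region_", seq_along(regions))
    regions <- tibble(region_id = ids, sequence = unname(regions))
  }
  check_columns(regions, c("region_id", "sequence"), "`regions`")
  mutate(as_tibble(regions), sequence = toupper(.data$sequence))
}
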