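#' Background sequence model for motif scanning
#'
#' Bundles the background nucleotide frequencies used in log-odds scoring
#' with a set of background sequences used for empirical threshold
#' calibration.
#'
#' @param sequences character vector (or `DNAStringSet`) of background
#'   sequences over A/C/G/T/N; names become sequence ids.
#' @param freqs background frequencies as a named numeric vector
#'   (A, C, G, T) summing to 1; by default estimated from `sequences`.
#' @param origin how the background was obtained: sampled to mimic genomic
#'   composition, i.i.d. uniform, or supplied by the user.
#' @return object of class `background_model` with elements `freqs`,
#'   `sequences`, `origin`.
#' @seealso [random_background()], [genomic_background()]
#' @export
background_model <- function(sequences, freqs = NULL,
                             origin = c("supplied", "random_genomic", "iid_uniform")) {
  origin <- match.arg(origin)
  if (inherits(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0 || any(!nzchar(sequences))) {
    abort("background sequences must be non-empty.")
  }
  if (any(grepl("[^ACGTN]", sequences))) {
    abort("background sequences may only contain A, C, G, T, N.")
  }
  if (is.null(freqs)) freqs <- base_frequencies(sequences)
  if (length(freqs) != 4 || anyNA(freqs) || any(freqs <= 0) ||
      abs(sum(freqs) - 1) > 1e-6) {
    abort("`freqs` must be 4 positive probabilities summing to 1.")
  }
  freqs <- stats::setNames(as.numeric(freqs) / sum(freqs), DNA_BASES4)
  structure(list(freqs = freqs, sequences = sequences, origin = origin),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat("<background_model> ", length(x$sequences), " sequences (",
      x$origin, ")\n", sep = "")
  cat("freqs:", paste(sprintf("%s=%.3f", names(x$freqs), x$freqs), collapse = " "), "\n")
  invisible(x)
}

#' Observed A/C/G/T frequencies of a sequence set
#' @param sequences character vector or `DNAStringSet`; N bases are ignored.
#' @return named numeric vector summing to 1.
#' @export
base_frequencies <- function(sequences) {
  if (!inherits(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  }
  counts <- colSums(Biostrings::letterFrequency(sequences, DNA_BASES4))
  if (sum(counts) == 0) abort("sequences contain no A/C/G/T bases.")
  counts / sum(counts)
}

#' Generate i.i.d. background sequences
#'
#' Draws `n` sequences of the given length with independent bases at the
#' supplied frequencies (uniform by default).
#'
#' @param n number of sequences.
#' @param length sequence length (nt).
#' @param freqs base frequencies (A, C, G, T).
#' @param seed optional integer for reproducibility.
#' @return a [background_model()] with origin `"iid_uniform"` (or
#'   `"supplied"` when non-uniform frequencies are given).
#' @export
random_background <- function(n, length, freqs = rep(0.25, 4), seed = NULL) {
  stopifnot(n >= 1, length >= 1)
  freqs <- as.numeric(freqs) / sum(freqs)
  seqs <- with_seed(seed, {
    draws <- sample(DNA_BASES4, n * length, replace = TRUE, prob = freqs)
    vapply(seq_len(n), function(i) {
      paste(draws[((i - 1) * length + 1):(i * length)], collapse = "")
    }, character(1))
  })
  origin <- if (max(abs(freqs - 0.25)) < 1e-12) "iid_uniform" else "supplied"
  background_model(seqs, freqs = freqs, origin = origin)
}

#' Generate background sequences matching a genome's composition
#'
#' Emulates random genomic background by drawing i.i.d. sequences at the
#' genome's observed mononucleotide frequencies.
#'
#' @param genome `DNAStringSet` or character vector of genome sequences.
#' @param n,length number and length of background sequences.
#' @param seed optional integer for reproducibility.
#' @return a [background_model()] with origin `"random_genomic"`.
#' @export
genomic_background <- function(genome, n, length, seed = NULL) {
  freqs <- base_frequencies(genome)
  bg <- random_background(n, length, freqs = freqs, seed = seed)
  bg$origin <- "random_genomic"
  bg
}
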