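#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_chr map_lgl map2 imap pmap list_rbind
#' @importFrom tidyr pivot_longer pivot_wider unnest nest expand_grid
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

# complement lookup including N
.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a DNA string
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single number or NULL.")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# assert that `df` has the named columns, with a readable error
check_columns <- function(df, cols, what = "input") {
  if (!is.data.frame(df)) abort(paste0(what, " must be a data frame."))
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      what, " is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

check_probability <- function(x, name, allow_zero = FALSE, allow_one = TRUE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    abort(paste0("`", name, "` must be a probability in ",
                 if (allow_zero) "[" else "(", "0,1",
                 if (allow_one) "]" else ")", "."))
  }
  invisible(x)
}
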