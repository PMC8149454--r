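#' Construct a position weight matrix (PWM)
#'
#' A PWM models a transcription-factor binding site as per-position nucleotide
#' probabilities. Rows are motif positions, columns are the bases A, C, G, T.
#' On construction a pseudocount is added to every entry and each row is
#' renormalized, so all probabilities are strictly positive and each position
#' sums to one — this keeps log-odds scores finite for bases unseen in the
#' source alignments.
#'
#' @param matrix numeric matrix with L >= 4 rows and 4 columns (A, C, G, T
#'   order); each row must be non-negative with positive sum.
#' @param id motif identifier.
#' @param source_ids character vector of identifiers the motif was derived
#'   from (e.g. the database motifs averaged into a consensus).
#' @param pseudocount probability added to every entry before renormalization.
#' @return An object of class `pwm`: a list with elements `id`, `source_ids`,
#'   `matrix` (regularized), and `pseudocount`.
#' @examples
#' m <- matrix(rep(c(0.7, 0.1, 0.1, 0.1), 5), ncol = 4, byrow = TRUE)
#' pwm(m, id = "poly_A")
#' @export
pwm <- function(matrix, id = "motif", source_ids = id, pseudocount = 1e-3) {
  if (!is.matrix(matrix) || !is.numeric(matrix) || ncol(matrix) != 4) {
    abort("`matrix` must be a numeric matrix with 4 columns (A,C,G,T).")
  }
  if (nrow(matrix) < 4) abort("a PWM needs at least 4 positions.")
  if (anyNA(matrix) || any(matrix < 0)) {
    abort("PWM entries must be non-negative and non-missing.")
  }
  if (any(rowSums(matrix) <= 0)) {
    abort("invalid motif: a position has zero total probability.")
  }
  check_probability(pseudocount, "pseudocount", allow_zero = TRUE)
  mat <- matrix / rowSums(matrix)
  mat <- (mat + pseudocount) / (1 + 4 * pseudocount)
  dimnames(mat) <- list(NULL, DNA_BASES4)
  structure(
    list(id = as.character(id), source_ids = as.character(source_ids),
         matrix = mat, pseudocount = pseudocount),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$id, " (", nrow(x$matrix), " positions)\n", sep = "")
  cat("consensus:", pwm_consensus(x), "\n")
  if (!identical(x$source_ids, x$id)) {
    cat("sources:  ", paste(x$source_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.pwm <- function(x) nrow(x$matrix)

#' Most probable base at each motif position
#' @param x a [pwm()].
#' @return single character string of length `length(x)`.
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(DNA_BASES4[max.col(x$matrix, ties.method = "first")], collapse = "")
}

#' Reverse complement of a PWM
#' @param x a [pwm()].
#' @return a `pwm` for the opposite strand: positions reversed, A/T and C/G
#'   probabilities swapped.
#' @export
pwm_revcomp <- function(x) {
  stopifnot(inherits(x, "pwm"))
  mat <- x$matrix[rev(seq_len(nrow(x$matrix))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(mat) <- DNA_BASES4
  out <- x
  out$matrix <- mat
  out
}

# ---------------------------------------------------------------------------
# Motif file I/O: MEME minimal format and a plain probability-table format
# (one "# id" header line per motif, then one row of 4 tab-separated
# probabilities per position).

#' Read PWMs from a motif file
#'
#' Supports the MEME minimal motif format (`MOTIF` /
#' `letter-probability matrix` blocks) and a plain probability-table dialect:
#' a `# id` header line followed by one row of four whitespace-separated
#' probabilities (A, C, G, T) per motif position.
#'
#' @param path motif file.
#' @param format `"auto"` detects MEME files by their `MEME version` /
#'   `MOTIF` lines.
#' @param pseudocount passed to [pwm()]; every motif is regularized on read.
#' @return list of [pwm()] objects, in file order.
#' @examples
#' meme <- system.file("extdata", "taat_core_synthetic.meme",
#'                     package = "atacreg")
#' taat <- read_pwms(meme)[[1]]
#' pwm_consensus(taat)
#' @export
read_pwms <- function(path, format = c("auto", "meme", "probability_table"),
                      pseudocount = 1e-3) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^\\s*MOTIF\\b", lines))) "meme" else "probability_table"
  }
  if (format == "meme") .parse_meme(lines, pseudocount) else .parse_prob_table(lines, pseudocount)
}

.parse_matrix_rows <- function(lines, line_nos, pseudocount, id, source_ids = id) {
  rows <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 4 || anyNA(vals)) {
      abort(paste0("malformed matrix row at line ", line_nos[[i]],
                   ": expected 4 probabilities, got '", lines[[i]], "'"))
    }
    if (any(vals < 0) || any(vals > 1)) {
      abort(paste0("probabilities out of [0,1] at line ", line_nos[[i]]))
    }
    vals
  })
  mat <- do.call(rbind, rows)
  if (any(rowSums(mat) <= 0)) {
    abort(paste0("invalid motif '", id, "': a position sums to 0."))
  }
  pwm(mat, id = id, source_ids = source_ids, pseudocount = pseudocount)
}

.parse_meme <- function(lines, pseudocount) {
  motif_at <- grep("^\\s*MOTIF\\b", lines)
  if (length(motif_at) == 0) abort("no MOTIF records found in MEME file.")
  bounds <- c(motif_at, length(lines) + 1L)
  lapply(seq_along(motif_at), function(k) {
    block <- seq(motif_at[[k]], bounds[[k + 1L]] - 1L)
    header <- strsplit(trimws(lines[[motif_at[[k]]]]), "\\s+")[[1]]
    id <- if (length(header) >= 2) header[[2]] else paste0("motif_", k)
    lpm <- grep("letter-probability matrix", lines[block])
    if (length(lpm) == 0) {
      abort(paste0("MOTIF ", id, ": missing letter-probability matrix header."))
    }
    start <- block[[1]] + lpm[[1]]
    body <- integer(0)
    i <- start
    while (i <= max(block) &&
           grepl("^\\s*[0-9.eE+-]", lines[[i]]) && nzchar(trimws(lines[[i]]))) {
      body <- c(body, i)
      i <- i + 1L
    }
    if (length(body) == 0) abort(paste0("MOTIF ", id, ": empty matrix."))
    .parse_matrix_rows(lines[body], body, pseudocount, id)
  })
}

.parse_prob_table <- function(lines, pseudocount) {
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  is_header <- grepl("^\\s*#", lines[idx])
  if (!any(is_header)) abort("probability table has no '# id' header line.")
  starts <- idx[is_header]
  bounds <- c(starts, length(lines) + 1L)
  lapply(seq_along(starts), function(k) {
    id <- trimws(sub("^\\s*#\\s*", "", lines[[starts[[k]]]]))
    body <- idx[idx > starts[[k]] & idx < bounds[[k + 1L]] & !grepl("^\\s*#", lines[idx])]
    if (length(body) == 0) abort(paste0("motif '", id, "' has no matrix rows."))
    .parse_matrix_rows(lines[body], body, pseudocount, id)
  })
}

#' Write PWMs to a motif file
#'
#' @param pwms a `pwm` or list of them.
#' @param path output file.
#' @param format MEME minimal or plain probability table (see [read_pwms()]).
#' @return `path`, invisibly.
#' @export
write_pwms <- function(pwms, path, format = c("meme", "probability_table")) {
  format <- match.arg(format)
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  fmt_mat <- function(m) apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = "\t"))
  lines <- if (format == "meme") {
    c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
      "Background letter frequencies", "A 0.25 C 0.25 G 0.25 T 0.25", "",
      unlist(lapply(pwms, function(p) c(
        paste("MOTIF", p$id),
        sprintf("letter-probability matrix: alength= 4 w= %d", nrow(p$matrix)),
        fmt_mat(p$matrix), ""
      ))))
  } else {
    unlist(lapply(pwms, function(p) c(paste("#", p$id), fmt_mat(p$matrix))))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Similarity and clustering

# Pearson correlation of the flattened 4 x k probability blocks; constant
# blocks (e.g. two uniform motifs) fall back to exact-match semantics.
.block_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(if (max(abs(x - y)) < 1e-12) 1 else 0)
  }
  stats::cor(x, y)
}

#' Best-alignment similarity between two PWMs
#'
#' Slides one motif across the other in both orientations and returns the
#' maximum Pearson correlation of the overlapping probability columns,
#' requiring at least `min_overlap` overlapping positions. The offset is the
#' position of `b`'s first column relative to `a`'s first column in the best
#' alignment; orientation `"reverse"` means `b` matched as its reverse
#' complement. The measure is symmetric in its arguments.
#'
#' @param a,b [pwm()] objects.
#' @param min_overlap minimum overlapping positions for a valid alignment.
#' @return one-row tibble: `similarity` (in \[-1, 1\]), `offset`,
#'   `orientation` (`"forward"` or `"reverse"`).
#' @export
pwm_similarity <- function(a, b, min_overlap = 6) {
  stopifnot(inherits(a, "pwm"), inherits(b, "pwm"))
  la <- nrow(a$matrix); lb <- nrow(b$matrix)
  if (min(la, lb) < min_overlap) {
    abort(paste0("motifs are too short for the required overlap of ",
                 min_overlap, " positions."))
  }
  best <- list(similarity = -Inf, offset = 0L, orientation = "forward")
  for (orient in c("forward", "reverse")) {
    bm <- if (orient == "forward") b$matrix else pwm_revcomp(b)$matrix
    for (d in seq(-(lb - min_overlap), la - min_overlap)) {
      ia <- max(1L, 1L + d):min(la, lb + d)
      ib <- ia - d
      s <- .block_cor(as.vector(t(a$matrix[ia, , drop = FALSE])),
                      as.vector(t(bm[ib, , drop = FALSE])))
      if (s > best$similarity) {
        best <- list(similarity = s, offset = as.integer(d), orientation = orient)
      }
    }
  }
  tibble(similarity = best$similarity, offset = best$offset,
         orientation = best$orientation)
}

#' Greedy clustering of PWMs into averaged consensus motifs
#'
#' Motifs are taken in input order; each joins the best-matching existing
#' cluster whose current average it resembles at similarity >=
#' `sim_threshold` (per [pwm_similarity()]), otherwise it seeds a new
#' cluster. A cluster's consensus is the position-wise mean of its members'
#' probability matrices, members aligned at their best offset and
#' orientation against the running average and the mean renormalized.
#' Singleton clusters pass their input motif through unchanged.
#'
#' @param pwms list of [pwm()] objects.
#' @param sim_threshold similarity required to join a cluster.
#' @param min_overlap passed to [pwm_similarity()].
#' @return list with `motifs` (list of consensus `pwm`s; averaged clusters
#'   are named `<id1>+...`) and `membership`, a tibble
#'   (`pwm_id`, `cluster`, `cluster_id`) partitioning the inputs.
#' @export
cluster_pwms <- function(pwms, sim_threshold = 0.8, min_overlap = 6) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (length(pwms) == 0) abort("need at least one PWM.")
  stopifnot(all(map_lgl(pwms, inherits, "pwm")))

  # each cluster: list(members = list(list(mat, offset)), avg = pwm, ids)
  clusters <- list()
  assignment <- integer(length(pwms))
  for (i in seq_along(pwms)) {
    p <- pwms[[i]]
    sims <- map_dbl(clusters, function(cl) pwm_similarity(p, cl$avg, min_overlap)$similarity)
    j <- if (length(sims) && max(sims) >= sim_threshold) which.max(sims) else 0L
    if (j == 0L) {
      clusters[[length(clusters) + 1L]] <- list(
        members = list(list(mat = p$matrix, offset = 0L)),
        avg = p, ids = p$id, seed = p
      )
      assignment[[i]] <- length(clusters)
    } else {
      aln <- pwm_similarity(clusters[[j]]$avg, p, min_overlap)
      mat <- if (aln$orientation == "forward") p$matrix else pwm_revcomp(p)$matrix
      cl <- clusters[[j]]
      # aln$offset is relative to the running average's first column, i.e.
      # the smallest member offset in the cluster frame
      frame_lo <- min(map_dbl(cl$members, "offset"))
      cl$members[[length(cl$members) + 1L]] <-
        list(mat = mat, offset = as.integer(frame_lo + aln$offset))
      cl$ids <- c(cl$ids, p$id)
      cl$avg <- .average_members(cl$members, id = paste(cl$ids, collapse = "+"),
                                 source_ids = cl$ids,
                                 pseudocount = cl$seed$pseudocount)
      clusters[[j]] <- cl
      assignment[[i]] <- j
    }
  }

  motifs <- map(clusters, function(cl) {
    if (length(cl$members) == 1L) cl$seed else cl$avg
  })
  membership <- tibble(
    pwm_id = map_chr(pwms, "id"),
    cluster = assignment,
    cluster_id = map_chr(motifs, "id")[assignment]
  )
  list(motifs = motifs, membership = membership)
}

# position-wise mean over member matrices placed at their stored offsets in
# the cluster frame; positions covered by fewer members average over those
# members only.
.average_members <- function(members, id, source_ids, pseudocount) {
  lo <- min(map_dbl(members, "offset")) + 1
  hi <- max(map_dbl(members, function(m) m$offset + nrow(m$mat)))
  L <- as.integer(hi - lo + 1)
  acc <- matrix(0, L, 4)
  n <- matrix(0, L, 4)
  for (m in members) {
    rows <- (m$offset + 1 - lo + 1):(m$offset + nrow(m$mat) - lo + 1)
    acc[rows, ] <- acc[rows, ] + m$mat
    n[rows, ] <- n[rows, ] + 1
  }
  # members are already regularized, so the mean only needs renormalizing;
  # re-adding the pseudocount here would bias the average of identical inputs
  out <- pwm(acc / n, id = id, source_ids = source_ids, pseudocount = 0)
  out$pseudocount <- pseudocount
  out
}
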