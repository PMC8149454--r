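# Independent oracles, deliberately written with plain loops and base R so
# they share no code path with the package implementation.

# reverse complement without Biostrings
rc_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# per-window log-odds score by explicit per-position table lookup
oracle_score <- function(mat, window, freqs = rep(0.25, 4)) {
  names(freqs) <- c("A", "C", "G", "T")
  chars <- strsplit(window, "")[[1]]
  total <- 0
  for (i in seq_along(chars)) {
    b <- chars[[i]]
    if (b == "N") next
    total <- total + log2(mat[i, b] / freqs[[b]])
  }
  unname(total)
}

# enumerate every (offset, strand): score the forward substring and the
# reverse complement of the substring, report the better strand per offset
# (ties to forward)
oracle_scan <- function(mat, seq, freqs = rep(0.25, 4)) {
  L <- nrow(mat)
  n <- nchar(seq)
  out <- NULL
  for (off in 0:(n - L)) {
    win <- substr(seq, off + 1, off + L)
    sf <- oracle_score(mat, win, freqs)
    sr <- oracle_score(mat, rc_chr(win), freqs)
    strand <- if (sr > sf + 1e-9) "-" else "+" # ties go forward
    out <- rbind(out, data.frame(offset = off, strand = strand,
                                 score = max(sf, sr)))
  }
  out
}

# hypergeometric upper tail by direct enumeration with choose()
oracle_hyper_tail <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  N <- n1 + n2
  j <- k1:min(n1, K)
  sum(choose(n1, j) * choose(n2, K - j)) / choose(N, K)
}

# reciprocal best hits by a double loop over all query/subject pairs
oracle_rbh <- function(ab, ba, cutoff) {
  best_of <- function(tab, q) {
    rows <- tab[tab$query == q & tab$evalue <= cutoff, , drop = FALSE]
    if (nrow(rows) == 0) return(NA_character_)
    rows <- rows[order(-rows$bitscore, rows$evalue, rows$subject), , drop = FALSE]
    rows$subject[[1]]
  }
  pairs <- NULL
  for (a in unique(ab$query)) {
    b <- best_of(ab, a)
    if (is.na(b)) next
    if (identical(best_of(ba, b), a)) {
      pairs <- rbind(pairs, data.frame(a_gene = a, b_gene = b))
    }
  }
  if (is.null(pairs)) data.frame(a_gene = character(), b_gene = character())
  else pairs[order(pairs$a_gene), , drop = FALSE]
}

# consensus intervals by brute force on one chromosome: every pairwise
# intersection, then merge by sweeping, then length filter
oracle_consensus <- function(rep1, rep2, min_length) {
  inter <- NULL
  for (i in seq_len(nrow(rep1))) {
    for (j in seq_len(nrow(rep2))) {
      s <- max(rep1$start[[i]], rep2$start[[j]])
      e <- min(rep1$end[[i]], rep2$end[[j]])
      if (s < e) inter <- rbind(inter, data.frame(start = s, end = e))
    }
  }
  if (is.null(inter)) return(data.frame(start = integer(), end = integer()))
  inter <- inter[order(inter$start, inter$end), , drop = FALSE]
  merged <- inter[1, , drop = FALSE]
  if (nrow(inter) > 1) {
    for (k in 2:nrow(inter)) {
      last <- nrow(merged)
      if (inter$start[[k]] <= merged$end[[last]]) {
        merged$end[[last]] <- max(merged$end[[last]], inter$end[[k]])
      } else {
        merged <- rbind(merged, inter[k, ])
      }
    }
  }
  merged[merged$end - merged$start >= min_length, , drop = FALSE]
}

# pooled-variance two-sample t statistic from the textbook formula
oracle_pooled_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# random interval table on one chromosome
random_intervals <- function(n, max_pos = 5000, max_len = 300) {
  start <- sample.int(max_pos, n)
  tibble::tibble(chrom = "chr1", start = start,
                 end = start + sample.int(max_len, n, replace = TRUE))
}
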