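#' @title Expression quantification and orthology rules
#' @description qPCR relative quantification by the 2^-ddCt method with a
#'   reference gene and calibrator tissue, the figure-style renormalization
#'   to the highest-expressing tissue, selection of organ-enriched genes by
#'   a conjunction of one-sided comparisons, and reciprocal-best-hit
#'   orthologue pairing from tabular similarity hits.
#' @name expression
NULL

#' Relative quantification by 2^-ddCt
#'
#' Per replicate, dCt = Ct(target) - Ct(reference); per tissue,
#' ddCt = mean dCt(tissue) - mean dCt(calibrator) and RQ = 2^-ddCt, so the
#' calibrator tissue has RQ = 1. The 95% confidence interval is a
#' t-interval on the tissue's mean dCt (df = n - 1), transformed through
#' 2^-x with the ends swapped so `ci_low <= ci_high`.
#'
#' @param ct_table tibble: `gene`, `tissue`, `replicate`, `ct` (cycles,
#'   positive). Must contain the reference gene for every (tissue,
#'   replicate) of the target.
#' @param gene target gene to quantify.
#' @param calibrator_tissue tissue whose mean dCt anchors RQ = 1.
#' @param reference_gene internal-control gene (e.g. an EF1a housekeeper).
#' @param conf confidence level for the interval.
#' @return tibble: `gene`, `tissue`, `rq`, `ci_low`, `ci_high`,
#'   `n_replicates`. Single-replicate tissues have `NA` interval bounds.
#' @export
delta_delta_ct <- function(ct_table, gene, calibrator_tissue, reference_gene,
                           conf = 0.95) {
  check_columns(ct_table, c("gene", "tissue", "replicate", "ct"), "`ct_table`")
  if (any(ct_table$ct <= 0 | is.na(ct_table$ct))) abort("Ct values must be positive.")
  tgt <- filter(ct_table, .data$gene == !!gene)
  ref <- filter(ct_table, .data$gene == !!reference_gene)
  if (nrow(tgt) == 0) abort(paste0("no rows for target gene '", gene, "'."))
  if (nrow(ref) == 0) abort(paste0("no rows for reference gene '", reference_gene, "'."))
  dct <- inner_join(
    select(tgt, "tissue", "replicate", ct_target = "ct"),
    select(ref, "tissue", "replicate", ct_ref = "ct"),
    by = c("tissue", "replicate")
  )
  missing_ref <- anti_join(tgt, ref, by = c("tissue", "replicate"))
  if (nrow(missing_ref) > 0) {
    abort(paste0("missing reference-gene Ct for tissue '",
                 missing_ref$tissue[[1]], "', replicate ",
                 missing_ref$replicate[[1]], "."))
  }
  dct <- mutate(dct, dct = .data$ct_target - .data$ct_ref)
  per_tissue <- summarise(group_by(dct, .data$tissue),
    mean_dct = mean(.data$dct),
    sd_dct = stats::sd(.data$dct),
    n_replicates = dplyr::n(), .groups = "drop")
  if (!calibrator_tissue %in% per_tissue$tissue) {
    abort(paste0("calibrator tissue '", calibrator_tissue, "' not present."))
  }
  cal <- per_tissue$mean_dct[per_tissue$tissue == calibrator_tissue]
  per_tissue |>
    mutate(
      ddct = .data$mean_dct - cal,
      # sd_dct is NA for single-replicate tissues, so `half` (and the CI)
      # comes out NA there without special-casing the t quantile
      half = stats::qt(1 - (1 - conf) / 2, pmax(.data$n_replicates - 1, 1)) *
        .data$sd_dct / sqrt(.data$n_replicates),
      gene = gene,
      rq = 2^(-.data$ddct),
      ci_low = 2^(-(.data$ddct + .data$half)),
      ci_high = 2^(-(.data$ddct - .data$half))
    ) |>
    select("gene", "tissue", "rq", "ci_low", "ci_high", "n_replicates")
}

#' Renormalize RQs to the highest-expressing tissue
#'
#' Divides every RQ and interval bound (within each gene) by the maximum
#' tissue RQ, so the highest-expressing tissue sits at 1.0 and between-
#' tissue ratios are unchanged — the usual presentation for tissue panels.
#'
#' @param results a [delta_delta_ct()] result (possibly several genes
#'   row-bound).
#' @return same shape, rescaled per gene.
#' @export
normalize_to_max_tissue <- function(results) {
  check_columns(results, c("gene", "tissue", "rq"), "`results`")
  if (all(results$rq == 0)) abort("all RQ values are zero.")
  results |>
    group_by(.data$gene) |>
    mutate(across(any_of(c("rq", "ci_low", "ci_high")), ~ .x / max(.data$rq))) |>
    ungroup()
}

#' Select organ-enriched genes
#'
#' A gene is enriched when, for every non-focal organ, BOTH focal samples
#' show higher mean expression with a one-sided p below `alpha` — a
#' conjunction over all (focal sample, other organ) comparisons. The
#' internal test is a one-sided Welch t on log2(x + 1) abundances;
#' externally computed differential-expression results can be supplied
#' instead via `de_table`.
#'
#' @param mat numeric matrix, genes x samples (counts or FPKM,
#'   non-negative), with row and column names.
#' @param sample_info tibble mapping `sample` to `organ`; not needed when
#'   `de_table` is supplied.
#' @param focal_organs the two focal organ labels (e.g. digestive gland and
#'   hepatopancreas).
#' @param alpha per-comparison significance level (raw p by default).
#' @param mode `"pairwise"` compares each focal organ to each other organ
#'   separately; `"pooled"` compares against all other organs pooled.
#' @param adjust `"none"` (raw p, the default) or `"BH"`
#'   (Benjamini-Hochberg across genes within each comparison).
#' @param de_table optional externally computed comparisons: tibble
#'   `gene`, `focal`, `other`, `log2fc`, `p` replacing the internal test.
#' @return object of class `organ_enrichment`: list with `genes` (character
#'   vector of enriched genes) and `comparisons` (per-comparison tibble
#'   with `log2fc`, `p`, `qualifies`).
#' @export
enriched_genes <- function(mat, sample_info = NULL, focal_organs, alpha = 0.05,
                           mode = c("pairwise", "pooled"),
                           adjust = c("none", "BH"), de_table = NULL) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  if (length(focal_organs) != 2) abort("`focal_organs` must name two organs.")
  if (is.null(de_table)) {
    check_columns(sample_info, c("sample", "organ"), "`sample_info`")
    if (!all(focal_organs %in% sample_info$organ)) {
      abort("focal organ(s) absent from `sample_info`.")
    }
    if (is.null(rownames(mat)) || is.null(colnames(mat))) {
      abort("`mat` needs gene rownames and sample colnames.")
    }
    if (any(mat < 0)) abort("abundances must be non-negative.")
    others <- setdiff(unique(sample_info$organ), focal_organs)
    if (length(others) == 0) abort("no non-focal organs to compare against.")
    organ_cols <- function(o) sample_info$sample[sample_info$organ %in% o]
    lmat <- log2(mat + 1)
    grid <- expand_grid(
      focal = focal_organs,
      other = if (mode == "pairwise") others else "pooled_others"
    )
    de_table <- pmap(grid, function(focal, other) {
      fc <- lmat[, organ_cols(focal), drop = FALSE]
      oc <- lmat[, organ_cols(if (other == "pooled_others") others else other),
                 drop = FALSE]
      if (ncol(fc) < 2 || ncol(oc) < 2) {
        abort("need >= 2 replicates per organ for the internal test.")
      }
      p <- vapply(seq_len(nrow(lmat)), function(i) {
        x <- fc[i, ]; y <- oc[i, ]
        if (stats::sd(x) == 0 && stats::sd(y) == 0) {
          return(if (mean(x) > mean(y)) 0 else 1)
        }
        stats::t.test(x, y, alternative = "greater")$p.value
      }, numeric(1))
      tibble(gene = rownames(mat), focal = focal, other = other,
             log2fc = rowMeans(fc) - rowMeans(oc), p = p)
    }) |> list_rbind()
  } else {
    check_columns(de_table, c("gene", "focal", "other", "log2fc", "p"),
                  "`de_table`")
  }
  if (adjust == "BH") {
    de_table <- de_table |>
      group_by(.data$focal, .data$other) |>
      mutate(p = stats::p.adjust(.data$p, "BH")) |>
      ungroup()
  }
  comparisons <- mutate(de_table, qualifies = .data$p < alpha & .data$log2fc > 0)
  verdict <- comparisons |>
    group_by(.data$gene) |>
    summarise(enriched = all(.data$qualifies), .groups = "drop")
  structure(
    list(genes = sort(verdict$gene[verdict$enriched]),
         comparisons = comparisons, alpha = alpha, mode = mode),
    class = "organ_enrichment"
  )
}

#' @export
print.organ_enrichment <- function(x, ...) {
  cat("<organ_enrichment> ", length(x$genes), " enriched gene(s) at alpha = ",
      x$alpha, " (", x$mode, " comparisons)\n", sep = "")
  invisible(x)
}

#' Read tabular similarity hits (12-column BLAST outfmt 6)
#' @param path tab-separated file with the standard 12 columns.
#' @return tibble with `query`, `subject`, ..., `evalue`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("query", "subject", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore"),
    col_types = "ccnnnnnnnnnn", comment = "#"
  )
}

#' Reciprocal best-hit orthologue pairs
#'
#' A pair (a, b) is reported when b is a's highest-bitscore subject in the
#' A-vs-B search and a is b's highest-bitscore subject in the B-vs-A
#' search, with both hits at or below the E-value cutoff. Bitscore ties are
#' broken by lower E-value, then lexicographic subject id, making the
#' result deterministic; each gene appears in at most one pair.
#'
#' @param hits_ab,hits_ba similarity-hit tibbles with at least `query`,
#'   `subject`, `bitscore`, `evalue` (e.g. from [read_blast_tab()]).
#' @param e_cutoff maximum E-value for a hit to count.
#' @return tibble: `a_gene`, `b_gene`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, e_cutoff = 1e-5) {
  best <- function(h, what) {
    check_columns(h, c("query", "subject", "bitscore", "evalue"), what)
    h |>
      filter(.data$evalue <= e_cutoff) |>
      arrange(.data$query, desc(.data$bitscore), .data$evalue, .data$subject) |>
      distinct(.data$query, .keep_all = TRUE) |>
      select("query", "subject")
  }
  ab <- best(hits_ab, "`hits_ab`")
  ba <- best(hits_ba, "`hits_ba`")
  inner_join(ab, ba, by = c(query = "subject", subject = "query")) |>
    transmute(a_gene = .data$query, b_gene = .data$subject) |>
    arrange(.data$a_gene)
}
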