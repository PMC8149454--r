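#' @title Consensus open-chromatin peaks and gene annotation
#' @description Replicated ATAC-seq peak calls are reduced to consensus
#'   open-chromatin regions: a consensus peak is the intersection of a
#'   replicate-1 peak with an overlapping replicate-2 peak; overlapping
#'   intersections are merged; regions shorter than a minimum length or
#'   overlapping repeat annotation beyond a tolerated fraction are removed.
#'   Peaks are then assigned to gene models as promoter, exon, intron or
#'   intergenic by the position of their midpoint. All coordinates are
#'   BED-style 0-based half-open.
#' @name peaks
NULL

# tibble(chrom,start,end) -> GRanges (internal 1-based closed)
.as_granges <- function(x, what = "intervals") {
  check_columns(x, c("chrom", "start", "end"), what)
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    abort(paste0("invalid interval in ", what, " at row ", bad[[1]], ": ",
                 x$chrom[[bad[[1]]]], ":", x$start[[bad[[1]]]], "-",
                 x$end[[bad[[1]]]], " (need 0 <= start < end)."))
  }
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1, x$end))
}

.gr_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Read peak calls from BED or narrowPeak files
#'
#' BED3+ and ENCODE narrowPeak are accepted; columns beyond chrom/start/end
#' and (when present) name, score, strand are ignored.
#'
#' @param path BED-like file.
#' @return tibble: `chrom`, `start`, `end` (0-based half-open), plus `name`,
#'   `score`, `strand` when present.
#' @export
read_peaks_bed <- function(path) {
  first <- readLines(path, n = 50, warn = FALSE)
  first <- first[!grepl("^(#|track|browser)", first) & nzchar(first)]
  ncol_file <- if (length(first)) length(strsplit(first[[1]], "\t")[[1]]) else 3L
  gr <- if (ncol_file >= 10) {
    rtracklayer::import(path, format = "BED",
      extraCols = c(signalValue = "numeric", pValue = "numeric",
                    qValue = "numeric", peak = "integer"))
  } else {
    rtracklayer::import(path, format = "BED")
  }
  out <- .gr_to_tbl(gr)
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$name)) out$name <- as.character(md$name)
  if (!is.null(md$score)) out$score <- as.numeric(md$score)
  s <- as.character(GenomicRanges::strand(gr))
  out$strand <- ifelse(s == "*", ".", s)
  out
}

#' Write intervals as a BED file
#' @param x tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_columns(x, c("chrom", "start", "end"), "`x`")
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if ("name" %in% names(x)) {
    cols <- c(cols, list(x[["name"]]))
    if ("score" %in% names(x)) {
      cols <- c(cols, list(x[["score"]]))
      if ("strand" %in% names(x)) cols <- c(cols, list(x[["strand"]]))
    }
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Build consensus peaks from two replicate peak sets
#'
#' A region is kept when it is recovered in both replicates: each overlap
#' (at least 1 bp) between a replicate-1 and a replicate-2 peak contributes
#' its intersection, overlapping intersections are merged, and the merged
#' regions are filtered by minimum length and by repeat overlap.
#'
#' @param rep1,rep2 peak tibbles (`chrom`, `start`, `end`; 0-based
#'   half-open), e.g. from [read_peaks_bed()].
#' @param min_length minimum consensus region length in bp (the length
#'   filter applies after intersection and merging).
#' @param repeats optional repeat-annotation tibble (`chrom`, `start`,
#'   `end`).
#' @param max_repeat_fraction peaks whose fraction of bases covered by
#'   repeats exceeds this are dropped; the default 0 removes any peak
#'   touching a repeat.
#' @return tibble of class `consensus_peaks`: `peak_id`
#'   (`chrom:start-end`), `chrom`, `start`, `end`, `support` (= 2),
#'   `repeat_fraction`; sorted by (chrom, start); pairwise disjoint.
#' @examples
#' rep1 <- tibble::tibble(chrom = "chr1", start = c(10, 300), end = c(250, 380))
#' rep2 <- tibble::tibble(chrom = "chr1", start = c(100, 320), end = c(260, 410))
#' consensus_peaks(rep1, rep2, min_length = 100)
#' @export
consensus_peaks <- function(rep1, rep2, min_length = 100, repeats = NULL,
                            max_repeat_fraction = 0) {
  gr1 <- .as_granges(rep1, "`rep1`")
  gr2 <- .as_granges(rep2, "`rep2`")
  hits <- GenomicRanges::findOverlaps(gr1, gr2, minoverlap = 1L)
  inter <- GenomicRanges::pintersect(gr1[S4Vectors::queryHits(hits)],
                                     gr2[S4Vectors::subjectHits(hits)])
  merged <- GenomicRanges::reduce(inter)
  merged <- merged[GenomicRanges::width(merged) >= min_length]

  rep_frac <- rep(0, length(merged))
  if (!is.null(repeats) && nrow(repeats) > 0) {
    rep_gr <- GenomicRanges::reduce(.as_granges(repeats, "`repeats`"))
    cov <- GenomicRanges::intersect(merged, rep_gr)
    ov <- GenomicRanges::findOverlaps(merged, cov)
    covered <- tapply(
      GenomicRanges::width(GenomicRanges::pintersect(
        merged[S4Vectors::queryHits(ov)], cov[S4Vectors::subjectHits(ov)])),
      factor(S4Vectors::queryHits(ov), levels = seq_along(merged)), sum)
    covered[is.na(covered)] <- 0
    rep_frac <- as.numeric(covered) / GenomicRanges::width(merged)
  }
  keep <- rep_frac <= max_repeat_fraction
  out <- .gr_to_tbl(merged[keep])
  out <- mutate(out,
    peak_id = paste0(.data$chrom, ":", .data$start, "-", .data$end),
    support = 2L,
    repeat_fraction = rep_frac[keep],
    .before = 1
  )
  out <- arrange(out, .data$chrom, .data$start)
  class(out) <- c("consensus_peaks", class(out))
  out
}

#' Read gene models from a GFF3 file
#'
#' Extracts `gene` features (gene extent, strand, id) and their exons
#' (via the mRNA/gene Parent chain). GFF3 1-based closed coordinates are
#' converted to 0-based half-open.
#'
#' @param path GFF3 file.
#' @return a `gene_models` list with tibbles `genes` (`gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `tss`) and `exons` (`gene_id`, `chrom`,
#'   `start`, `end`). `tss` is the 0-based first transcribed base
#'   (`start` on +, `end - 1` on -).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  gid <- as.character(md$ID)
  genes_gr <- gr[type == "gene"]
  if (length(genes_gr) == 0) abort("no 'gene' features found in GFF3.")
  genes <- tibble(
    gene_id = as.character(S4Vectors::mcols(genes_gr)$ID),
    chrom = as.character(GenomicRanges::seqnames(genes_gr)),
    strand = as.character(GenomicRanges::strand(genes_gr)),
    start = GenomicRanges::start(genes_gr) - 1L,
    end = GenomicRanges::end(genes_gr)
  )
  # map transcripts to genes so exon Parents resolve either way
  parent <- vapply(md$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  tx2gene <- stats::setNames(parent[type %in% c("mRNA", "transcript")],
                             gid[type %in% c("mRNA", "transcript")])
  ex <- gr[type == "exon"]
  if (length(ex) > 0) {
    ep <- vapply(S4Vectors::mcols(ex)$Parent,
                 function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
                 character(1))
    owner <- ifelse(ep %in% genes$gene_id, ep, unname(tx2gene[ep]))
    keep <- !is.na(owner)
    exons <- tibble(
      gene_id = owner[keep],
      chrom = as.character(GenomicRanges::seqnames(ex))[keep],
      start = GenomicRanges::start(ex)[keep] - 1L,
      end = GenomicRanges::end(ex)[keep]
    ) |> distinct() |> arrange(.data$gene_id, .data$start)
  } else {
    exons <- tibble(gene_id = character(), chrom = character(),
                    start = integer(), end = integer())
  }
  gene_models(genes, exons)
}

#' Assemble gene models from tibbles
#'
#' @param genes tibble: `gene_id`, `chrom`, `strand` (`+`/`-`), `start`,
#'   `end` (0-based half-open gene extent).
#' @param exons tibble: `gene_id`, `chrom`, `start`, `end`; may be empty.
#' @return object of class `gene_models`; the genes table gains a `tss`
#'   column (0-based position of the first transcribed base).
#' @export
gene_models <- function(genes, exons = NULL) {
  check_columns(genes, c("gene_id", "chrom", "strand", "start", "end"), "`genes`")
  if (is.null(exons)) {
    exons <- tibble(gene_id = character(), chrom = character(),
                    start = integer(), end = integer())
  }
  check_columns(exons, c("gene_id", "chrom", "start", "end"), "`exons`")
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'.")
  }
  genes <- mutate(as_tibble(genes),
                  tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L))
  structure(list(genes = genes, exons = as_tibble(exons)), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x$genes), " genes, ", nrow(x$exons), " exons\n",
      sep = "")
  invisible(x)
}

#' Annotate peaks against gene models
#'
#' Each peak is categorized by the position of its midpoint with priority
#' promoter > exon > intron > intergenic: promoter when the midpoint falls
#' within `promoter_up` bp upstream to `promoter_down` bp downstream of any
#' TSS (in transcription orientation), exon when inside an annotated exon,
#' intron when inside a gene body but not an exon, intergenic otherwise.
#' The nearest gene is the one minimizing |midpoint - TSS| and
#' `tss_distance` is that signed offset in transcription orientation
#' (negative upstream of the TSS).
#'
#' @param peaks tibble of intervals (`chrom`, `start`, `end`), e.g.
#'   [consensus_peaks()] output.
#' @param genes a [gene_models()] object.
#' @param promoter_up,promoter_down promoter window, bp upstream /
#'   downstream of the TSS.
#' @return `peaks` with added columns `midpoint`, `category` (factor:
#'   promoter, exon, intron, intergenic), `nearest_gene`, `tss_distance`.
#' @export
annotate_peaks <- function(peaks, genes, promoter_up = 1000, promoter_down = 100) {
  check_columns(peaks, c("chrom", "start", "end"), "`peaks`")
  stopifnot(inherits(genes, "gene_models"))
  peaks <- as_tibble(peaks)
  g <- genes$genes
  mid <- as.integer(floor((peaks$start + peaks$end) / 2))

  n <- nrow(peaks)
  category <- rep("intergenic", n)
  nearest_gene <- rep(NA_character_, n)
  tss_distance <- rep(NA_integer_, n)

  if (nrow(g) > 0) {
    mid_gr <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
    # signed distance to every same-chromosome TSS; nearest by |d|
    for (i in seq_len(n)) {
      on_chr <- which(g$chrom == peaks$chrom[[i]])
      if (length(on_chr) == 0) next
      d <- ifelse(g$strand[on_chr] == "+",
                  mid[[i]] - g$tss[on_chr],
                  g$tss[on_chr] - mid[[i]])
      j <- on_chr[which.min(abs(d))]
      nearest_gene[[i]] <- g$gene_id[[j]]
      tss_distance[[i]] <- as.integer(d[[which.min(abs(d))]])
    }
    # promoter windows, gene bodies and exons as interval sets
    prom_start <- ifelse(g$strand == "+", g$tss - promoter_up, g$tss - promoter_down + 1L)
    prom_end <- ifelse(g$strand == "+", g$tss + promoter_down, g$tss + promoter_up + 1L)
    prom <- tibble(chrom = g$chrom, start = pmax(0L, as.integer(prom_start)),
                   end = as.integer(prom_end)) |> filter(.data$start < .data$end)
    in_set <- function(tbl) {
      if (nrow(tbl) == 0) return(rep(FALSE, n))
      GenomicRanges::countOverlaps(mid_gr, .as_granges(tbl)) > 0
    }
    in_prom <- in_set(prom)
    in_exon <- in_set(genes$exons)
    in_body <- in_set(select(g, "chrom", "start", "end"))
    category <- ifelse(in_prom, "promoter",
                ifelse(in_exon, "exon",
                ifelse(in_body, "intron", "intergenic")))
  }
  mutate(peaks,
    midpoint = mid,
    category = factor(category, levels = c("promoter", "exon", "intron", "intergenic")),
    nearest_gene = nearest_gene,
    tss_distance = tss_distance
  )
}

#' Count passing motif hits per gene
#'
#' Joins scan hits to annotated peaks and tallies, for each gene, the number
#' of passing motif sites found in peaks whose nearest gene it is. Genes
#' with no passing sites are omitted.
#'
#' @param hits [scan_regions()] output whose `region_id`s are peak ids.
#' @param peaks [annotate_peaks()] output carrying `peak_id` and
#'   `nearest_gene`.
#' @return tibble: `gene_id`, `n_sites`, sorted by decreasing `n_sites`.
#' @export
peaks_near_genes <- function(hits, peaks) {
  check_columns(hits, c("region_id", "passed"), "`hits`")
  check_columns(peaks, c("peak_id", "nearest_gene"), "`peaks`")
  dangling <- setdiff(unique(hits$region_id), peaks$peak_id)
  if (length(dangling) > 0) {
    abort(paste0("hit region_id(s) not present in peaks: ",
                 paste(utils::head(dangling, 3), collapse = ", ")))
  }
  hits |>
    filter(.data$passed) |>
    inner_join(select(peaks, "peak_id", "nearest_gene"),
               by = c(region_id = "peak_id")) |>
    filter(!is.na(.data$nearest_gene)) |>
    count(gene_id = .data$nearest_gene, name = "n_sites") |>
    arrange(desc(.data$n_sites), .data$gene_id)
}

#' Extract peak sequences from a genome
#'
#' @param peaks tibble with `chrom`, `start`, `end` (and `peak_id`, used as
#'   the region id when present).
#' @param genome named `DNAStringSet` (or named character vector).
#' @return region tibble (`region_id`, `sequence`) ready for
#'   [scan_regions()].
#' @export
peak_sequences <- function(peaks, genome) {
  check_columns(peaks, c("chrom", "start", "end"), "`peaks`")
  if (!inherits(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  missing <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing) > 0) {
    abort(paste0("chromosome(s) absent from genome: ",
                 paste(missing, collapse = ", ")))
  }
  ids <- if ("peak_id" %in% names(peaks)) peaks[["peak_id"]] else
    paste0(peaks$chrom, ":", peaks$start, "-", peaks$end)
  seqs <- as.character(Biostrings::subseq(
    genome[peaks$chrom], start = peaks$start + 1L, end = peaks$end))
  tibble(region_id = ids, sequence = unname(seqs))
}
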