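test_that("consensus peaks match the hand-enumerated intersection oracle", {
  rep1 <- tibble::tibble(chrom = "chr1", start = c(10, 300, 500),
                         end = c(250, 380, 700))
  rep2 <- tibble::tibble(chrom = "chr1", start = c(100, 320),
                         end = c(260, 410))
  cp <- consensus_peaks(rep1, rep2, min_length = 100)
  # (100,250) kept (150 bp); (320,380) dropped (60 bp); (500,700) unmatched
  expect_identical(nrow(cp), 1L)
  expect_identical(cp$start, 100L)
  expect_identical(cp$end, 250L)
  expect_identical(cp$support, 2L)
})

test_that("identical replicates reduce to a length-and-repeat filter", {
  withr::with_seed(41, {
    reps <- random_intervals(30)
    cp <- consensus_peaks(reps, reps, min_length = 100)
    oracle <- oracle_consensus(reps, reps, 100)
    expect_equal(cp$start, oracle$start)
    expect_equal(cp$end, oracle$end)
    expect_true(all(cp$end - cp$start >= 100))
  })
})

test_that("consensus construction is commutative and matches the oracle on random inputs", {
  withr::with_seed(42, {
    for (k in 1:5) {
      r1 <- random_intervals(25)
      r2 <- random_intervals(25)
      a <- consensus_peaks(r1, r2, min_length = 50)
      b <- consensus_peaks(r2, r1, min_length = 50)
      expect_equal(a[c("chrom", "start", "end")], b[c("chrom", "start", "end")])
      oracle <- oracle_consensus(r1, r2, 50)
      expect_equal(a$start, oracle$start)
      expect_equal(a$end, oracle$end)
      # outputs pairwise disjoint after merging
      if (nrow(a) > 1) expect_true(all(a$start[-1] > a$end[-nrow(a)]))
    }
  })
})

test_that("repeat overlap removes peaks per the tolerated fraction", {
  r <- tibble::tibble(chrom = "chr1", start = 100, end = 300)
  inside <- tibble::tibble(chrom = "chr1", start = 50, end = 350)
  expect_identical(nrow(consensus_peaks(r, r, 100, repeats = inside,
                                        max_repeat_fraction = 0)), 0L)
  half <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
  expect_identical(nrow(consensus_peaks(r, r, 100, repeats = half,
                                        max_repeat_fraction = 0)), 0L)
  cp <- consensus_peaks(r, r, 100, repeats = half, max_repeat_fraction = 0.6)
  expect_identical(nrow(cp), 1L)
  expect_equal(cp$repeat_fraction, 0.5)
})

test_that("invalid intervals are rejected with the offending record named", {
  bad <- tibble::tibble(chrom = "chr1", start = c(10, 500), end = c(100, 400))
  good <- tibble::tibble(chrom = "chr1", start = 10, end = 100)
  expect_error(consensus_peaks(bad, good, 10), "row 2")
})

test_that("BED and narrowPeak files round-trip through the readers", {
  path <- withr::local_tempfile(fileext = ".bed")
  tbl <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(0L, 150L),
                        end = c(100L, 400L), name = c("p1", "p2"),
                        score = c(5, 9), strand = c("+", "."))
  write_bed(tbl, path)
  back <- read_peaks_bed(path)
  expect_equal(back$start, tbl$start)
  expect_equal(back$end, tbl$end)
  expect_identical(back$name, tbl$name)
  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t10\t200\tpeak1\t100\t.\t5.5\t3.2\t2.1\t50",
               "chr1\t400\t900\tpeak2\t200\t.\t7.5\t4.2\t3.1\t250"), np)
  peaks <- read_peaks_bed(np)
  expect_identical(peaks$start, c(10L, 400L))
  expect_identical(peaks$end, c(200L, 900L))
})

test_that("midpoint annotation follows the promoter > exon > intron > intergenic priority", {
  gm <- gene_models(
    tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                   start = 1000L, end = 5000L),
    tibble::tibble(gene_id = "g1", chrom = "chr1",
                   start = c(1000L, 3000L), end = c(1500L, 3500L))
  )
  ann <- annotate_peaks(
    tibble::tibble(chrom = "chr1",
                   start = c(400L, 1100L, 2000L, 100000L, 3100L),
                   end = c(900L, 1300L, 2400L, 100400L, 3300L)),
    gm, promoter_up = 1000, promoter_down = 100
  )
  # midpoint 650: within [tss-1000, tss+100) => promoter, distance -350
  expect_identical(as.character(ann$category),
                   c("promoter", "exon", "intron", "intergenic", "exon"))
  expect_identical(ann$tss_distance[[1]], -350L)
  expect_identical(ann$nearest_gene[[1]], "g1")
  # every peak gets exactly one category and the split sums to the total
  expect_identical(sum(table(ann$category)), nrow(ann))
})

test_that("promoter windows follow transcription orientation on the minus strand", {
  gm <- gene_models(
    tibble::tibble(gene_id = "gneg", chrom = "chr1", strand = "-",
                   start = 1000L, end = 2000L)
  )
  # tss = 1999; a peak with midpoint 2500 is 501 bp upstream in gene terms
  ann <- annotate_peaks(tibble::tibble(chrom = "chr1", start = 2400L, end = 2600L),
                        gm, promoter_up = 1000, promoter_down = 100)
  expect_identical(as.character(ann$category), "promoter")
  expect_identical(ann$tss_distance[[1]], -501L)
})

test_that("an empty gene set yields intergenic annotations", {
  gm <- gene_models(tibble::tibble(gene_id = character(), chrom = character(),
                                   strand = character(), start = integer(),
                                   end = integer()))
  ann <- annotate_peaks(tibble::tibble(chrom = "chr1", start = 0L, end = 100L), gm)
  expect_identical(as.character(ann$category), "intergenic")
  expect_true(is.na(ann$nearest_gene))
})

test_that("GFF3 gene models are read with exons resolved through mRNA parents", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1001\t5000\t.\t+\t.\tID=gene1",
    "chr1\ttest\tmRNA\t1001\t5000\t.\t+\t.\tID=rna1;Parent=gene1",
    "chr1\ttest\texon\t1001\t1500\t.\t+\t.\tID=e1;Parent=rna1",
    "chr1\ttest\texon\t3001\t3500\t.\t+\t.\tID=e2;Parent=rna1",
    "chr1\ttest\tgene\t8001\t9000\t.\t-\t.\tID=gene2"
  ), path)
  gm <- read_gene_models(path)
  expect_identical(gm$genes$gene_id, c("gene1", "gene2"))
  # 1-based closed -> 0-based half-open
  expect_identical(gm$genes$start, c(1000L, 8000L))
  expect_identical(gm$genes$tss, c(1000L, 8999L))
  expect_identical(nrow(gm$exons), 2L)
  expect_identical(gm$exons$gene_id, c("gene1", "gene1"))
})

test_that("per-gene site counts follow the annotation and drop zero-hit genes", {
  peaks <- tibble::tibble(peak_id = c("pk1", "pk2", "pk3"),
                          nearest_gene = c("g1", "g1", "g2"))
  hits <- tibble::tibble(region_id = c("pk1", "pk1", "pk2", "pk3"),
                         passed = c(TRUE, TRUE, FALSE, FALSE))
  counts <- peaks_near_genes(hits, peaks)
  expect_identical(counts$gene_id, "g1")
  expect_identical(counts$n_sites, 2L)
  none <- peaks_near_genes(dplyr::mutate(hits, passed = FALSE), peaks)
  expect_identical(nrow(none), 0L)
  expect_error(
    peaks_near_genes(tibble::tibble(region_id = "ghost", passed = TRUE), peaks),
    "ghost")
})

test_that("planted gene-to-site assignments are recovered from the generator truth", {
  withr::with_seed(43, {
    g <- gen_genome(1, 30000, repeat_density = 0)
    pm <- gen_pwm(10, 0.9, "planted")
    bg <- genomic_background(g$genome, 300, 300)
    thr <- calibrate_threshold(pm, bg, 0.01)
    sim <- gen_peaks_with_motifs(g$genome, pm, n_peaks = 20, peak_length = 300,
                                 planted_fraction = 0.5, jitter = 0, dropout = 0,
                                 threshold = thr, background = bg)
    cp <- consensus_peaks(sim$rep1, sim$rep2, min_length = 100)
    genes <- gene_models(tibble::tibble(
      gene_id = paste0("g", seq_len(nrow(sim$base_peaks))), chrom = sim$base_peaks$chrom,
      strand = "+", start = sim$base_peaks$start, end = sim$base_peaks$end))
    ann <- annotate_peaks(cp, genes, promoter_up = 200, promoter_down = 200)
    hits <- scan_regions(pm, peak_sequences(ann, sim$genome), thr, bg)
    counts <- peaks_near_genes(hits, ann)
    planted_genes <- paste0("g", which(sim$truth$planted))
    expect_true(all(planted_genes %in% counts$gene_id))
  })
})
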