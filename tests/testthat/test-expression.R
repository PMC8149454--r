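ct_grid <- function(ct_map, replicates = 3, noise = 0, ref_ct = 15) {
  # ct_map: named vector tissue -> target Ct; reference fixed at ref_ct
  tidyr::expand_grid(gene = c("tgt", "ref"), tissue = names(ct_map),
                     replicate = seq_len(replicates)) |>
    dplyr::mutate(ct = ifelse(gene == "tgt", ct_map[tissue], ref_ct) +
                    stats::rnorm(dplyr::n(), sd = noise))
}

test_that("2^-ddCt identities: calibrator RQ 1, two extra cycles give RQ 0.25", {
  tab <- ct_grid(c(gill = 18, hep = 20))
  rq <- delta_delta_ct(tab, "tgt", calibrator_tissue = "gill",
                       reference_gene = "ref")
  expect_equal(rq$rq[rq$tissue == "gill"], 1)
  # dCt hep 5, dCt gill 3 => ddCt 2 => RQ 2^-2
  expect_equal(rq$rq[rq$tissue == "hep"], 0.25)
  expect_true(all(rq$ci_low <= rq$rq & rq$rq <= rq$ci_high))
})

test_that("missing reference wells and single replicates are handled explicitly", {
  tab <- ct_grid(c(gill = 18, hep = 20))
  expect_error(delta_delta_ct(dplyr::filter(tab, !(gene == "ref" & tissue == "hep")),
                              "tgt", "gill", "ref"),
               "missing reference")
  one <- ct_grid(c(gill = 18, hep = 20), replicates = 1)
  rq <- delta_delta_ct(one, "tgt", "gill", "ref")
  expect_equal(rq$rq[rq$tissue == "hep"], 0.25)
  expect_true(all(is.na(rq$ci_low)))
})

test_that("RQ is invariant to a constant shift of every Ct", {
  withr::with_seed(61, {
    tab <- ct_grid(c(gill = 18, hep = 20, mantle = 22), noise = 0.2)
    rq1 <- delta_delta_ct(tab, "tgt", "gill", "ref")
    rq2 <- delta_delta_ct(dplyr::mutate(tab, ct = ct + 7), "tgt", "gill", "ref")
    expect_equal(rq1$rq, rq2$rq, tolerance = 1e-12)
    expect_equal(rq1$ci_low, rq2$ci_low, tolerance = 1e-12)
  })
})

test_that("simulated fold changes are recovered within the confidence interval", {
  withr::with_seed(62, {
    f <- 6 # true hep/gill fold change
    cover <- replicate(60, {
      tab <- ct_grid(c(gill = 20, hep = 20 - log2(f)), replicates = 4,
                     noise = 0.15)
      rq <- delta_delta_ct(tab, "tgt", "gill", "ref")
      hep <- rq[rq$tissue == "hep", ]
      c(hep$rq, hep$ci_low <= f && f <= hep$ci_high)
    })
    expect_equal(mean(cover[1, ]), f, tolerance = 0.05)
    expect_gte(mean(cover[2, ]), 0.8) # nominal 95% coverage
  })
})

test_that("tissue-panel renormalization scales to the maximum and keeps ratios", {
  rq <- tibble::tibble(gene = "g", tissue = c("a", "b", "c"), rq = c(2, 4, 1),
                       ci_low = c(1.5, 3, 0.8), ci_high = c(2.5, 5, 1.2),
                       n_replicates = 3L)
  nn <- normalize_to_max_tissue(rq)
  expect_equal(nn$rq, c(0.5, 1, 0.25))
  expect_equal(nn$ci_low, rq$ci_low / 4)
  single <- normalize_to_max_tissue(rq[2, ])
  expect_equal(single$rq, 1)
  withr::with_seed(63, {
    r <- dplyr::mutate(rq, rq = stats::runif(3, 0.5, 8))
    nr <- normalize_to_max_tissue(r)
    expect_equal(nr$rq / nr$rq[[1]], r$rq / r$rq[[1]], tolerance = 1e-12)
  })
})

test_that("organ enrichment is a conjunction over both focal samples and every organ", {
  organs <- c("digestive_gland", "hepatopancreas", "gill", "mantle")
  info <- tidyr::expand_grid(organ = organs, rep = 1:3) |>
    dplyr::mutate(sample = paste0(organ, "_", rep)) |>
    dplyr::select(sample, organ)
  base <- matrix(100, 2, nrow(info), dimnames = list(c("gA", "gB"), info$sample))
  jit <- matrix(seq(-1, 1, length.out = length(base)), nrow = 2) # break ties
  mat <- base + jit
  # gA: high in both focal organs; gB: high in hepatopancreas only
  mat["gA", info$organ %in% organs[1:2]] <- 1000 + jit[1, info$organ %in% organs[1:2]]
  mat["gB", info$organ == "hepatopancreas"] <- 1000
  mat["gB", info$organ == "digestive_gland"] <- 50
  res <- enriched_genes(mat, info, organs[1:2])
  expect_identical(res$genes, "gA")
  comp <- tidy(res)
  expect_false(all(comp$qualifies[comp$gene == "gB"]))
  expect_error(enriched_genes(mat, info, c("digestive_gland", "kidney")),
               "absent")
})

test_that("raising a focal gene's expression never removes it from the enriched set", {
  withr::with_seed(64, {
    sim <- gen_expression(n_genes = 120, n_enriched = 15, effect = 3)
    res1 <- enriched_genes(sim$mat, sim$sample_info, sim$focal_organs)
    boosted <- sim$mat
    focal_cols <- sim$sample_info$sample[sim$sample_info$organ %in% sim$focal_organs]
    boosted[, focal_cols] <- boosted[, focal_cols] * 4
    res2 <- enriched_genes(boosted, sim$sample_info, sim$focal_organs)
    expect_true(all(res1$genes %in% res2$genes))
  })
})

test_that("planted enriched genes are recovered and nulls produce few false calls", {
  withr::with_seed(65, {
    sim <- gen_expression(n_genes = 400, n_enriched = 30, effect = 4,
                          dispersion = 0.3)
    res <- enriched_genes(sim$mat, sim$sample_info, sim$focal_organs)
    truth <- sim$truth$gene[sim$truth$enriched]
    expect_gte(mean(truth %in% res$genes), 0.95)
    expect_lte(sum(!res$genes %in% truth), 5)
    # pooled mode also runs and respects the conjunction
    pooled <- enriched_genes(sim$mat, sim$sample_info, sim$focal_organs,
                             mode = "pooled")
    expect_gte(mean(truth %in% pooled$genes), 0.95)
    # no effect: the conjunction of 6 one-sided tests rarely fires
    null_sim <- gen_expression(n_genes = 400, n_enriched = 0, effect = 0)
    null_res <- enriched_genes(null_sim$mat, null_sim$sample_info,
                               null_sim$focal_organs)
    expect_lte(length(null_res$genes), 0.05 * 400)
  })
})

test_that("an external DE table drives the same conjunction rule", {
  de <- tibble::tibble(
    gene = rep(c("g1", "g2"), each = 2),
    focal = rep(c("digestive_gland", "hepatopancreas"), 2),
    other = "gill",
    log2fc = c(2, 2, 2, -1),
    p = c(0.001, 0.002, 0.001, 0.001)
  )
  res <- enriched_genes(mat = NULL, sample_info = tibble::tibble(
    sample = "s", organ = c("digestive_gland")), # unused with de_table
    focal_organs = c("digestive_gland", "hepatopancreas"), de_table = de)
  expect_identical(res$genes, "g1")
})

test_that("reciprocal best hits require mutual top bitscores under the E-value cutoff", {
  ab <- tibble::tibble(query = c("a1", "a1", "a2"), subject = c("b1", "b2", "b1"),
                       bitscore = c(100, 90, 80), evalue = c(1e-20, 1e-10, 1e-9))
  ba <- tibble::tibble(query = c("b1", "b2"), subject = c("a1", "a1"),
                       bitscore = c(95, 50), evalue = c(1e-18, 1e-6))
  expect_equal(reciprocal_best_hits(ab, ba),
               tibble::tibble(a_gene = "a1", b_gene = "b1"))
  # reciprocity broken for a1: b1's best is a2, so a1 stays unpaired
  ba2 <- tibble::tibble(query = "b1", subject = "a2", bitscore = 95, evalue = 1e-18)
  expect_false("a1" %in% reciprocal_best_hits(ab, ba2)$a_gene)
  # E-value cutoff excludes otherwise-mutual pairs
  weak <- dplyr::mutate(ba, evalue = 1e-3)
  expect_identical(nrow(reciprocal_best_hits(ab, weak)), 0L)
})

test_that("random 50x50 hit tables match the double-loop oracle and form a matching", {
  withr::with_seed(66, {
    for (k in 1:3) {
      a_ids <- paste0("a", 1:50); b_ids <- paste0("b", 1:50)
      mk <- function(q, s) tibble::tibble(
        query = sample(q, 300, replace = TRUE),
        subject = sample(s, 300, replace = TRUE),
        bitscore = round(stats::runif(300, 30, 200), 1),
        evalue = 10^stats::runif(300, -30, -2)
      ) |> dplyr::distinct(query, subject, .keep_all = TRUE)
      ab <- mk(a_ids, b_ids); ba <- mk(b_ids, a_ids)
      got <- reciprocal_best_hits(ab, ba, 1e-5)
      want <- oracle_rbh(as.data.frame(ab), as.data.frame(ba), 1e-5)
      expect_identical(got$a_gene, want$a_gene)
      expect_identical(got$b_gene, want$b_gene)
      expect_false(anyDuplicated(got$a_gene) > 0)
      expect_false(anyDuplicated(got$b_gene) > 0)
    }
  })
})
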