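toy_table <- function() {
  tibble::tibble(
    group = c("blank", "blank", "pdx", "pdx"),
    bio_replicate = c(1, 2, 1, 2),
    tech_replicate = 1,
    firefly = c(200, 300, 800, 1200),
    renilla = c(100, 150, 200, 300)
  )
}

test_that("the blank control's mean relative activity is exactly 1.00", {
  acts <- relative_activity(toy_table(), "blank")
  expect_identical(mean(acts$relative_activity[acts$group == "blank"]), 1)
  # control ratios are (2, 2); a well at ratio 4 has relative activity 2.0
  expect_equal(acts$relative_activity[acts$group == "pdx"], c(2, 2))
})

test_that("normalization is invariant to row order and validates its inputs", {
  tab <- toy_table()
  shuffled <- tab[c(3, 1, 4, 2), ]
  a1 <- relative_activity(tab, "blank")
  a2 <- relative_activity(shuffled, "blank")
  merged <- dplyr::left_join(
    a1, a2, by = c("group", "bio_replicate", "tech_replicate"))
  expect_equal(merged$relative_activity.x, merged$relative_activity.y)
  expect_error(relative_activity(dplyr::mutate(tab, renilla = c(1, 0, 1, 1)),
                                 "blank"), "positive")
  expect_error(relative_activity(tab, "missing_ctrl"), "no wells")
})

test_that("technical replicates collapse to biological means", {
  tab <- tibble::tibble(group = "g", bio_replicate = c(1, 1, 2, 2),
                        tech_replicate = c(1, 2, 1, 2),
                        firefly = c(100, 300, 400, 400), renilla = 100)
  acts <- collapse_tech_reps(
    dplyr::mutate(tab, relative_activity = firefly / renilla))
  expect_equal(acts$relative_activity, c(2, 4))
})

test_that("adjacent-dose Student t and Holm adjustment match hand computation", {
  acts <- tibble::tibble(
    group = rep(c("d1", "d2"), each = 3),
    relative_activity = c(1.0, 1.1, 0.9, 2.0, 2.1, 1.9)
  )
  res <- dose_response_tests(acts, c("d1", "d2"))
  # pooled sd 0.1, se 0.1*sqrt(2/3): |t| = 1 / 0.081650 = 12.2474 on 4 df
  expect_equal(abs(res$t), 12.24745, tolerance = 1e-5)
  expect_equal(res$df, 4)
  expect_equal(res$t, oracle_pooled_t(acts$relative_activity[1:3],
                                      acts$relative_activity[4:6]),
               tolerance = 1e-10)
  expect_equal(res$p, 2 * stats::pt(-12.24745, 4), tolerance = 1e-5)
  # identical groups: t = 0, p = 1
  same <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                         relative_activity = rep(c(1, 1.2, 0.8), 2))
  expect_equal(dose_response_tests(same, c("a", "b"))$p, 1)
  # Holm step-down on raw (0.01, 0.02, 0.30) -> (0.03, 0.04, 0.30)
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.30), "holm"),
               c(0.03, 0.04, 0.30))
  # degenerate pair flagged rather than tested
  flat <- tibble::tibble(group = rep(c("a", "b"), each = 2),
                         relative_activity = c(1, 1, 2, 2))
  res_flat <- dose_response_tests(flat, c("a", "b"))
  expect_true(res_flat$degenerate)
  expect_true(is.na(res_flat$p))
})

test_that("the sum pool enumerates all pairwise sums with an exact mean identity", {
  pool <- pooled_sum_null(c(1, 2), c(10, 20))
  expect_setequal(pool$values, c(11, 12, 21, 22))
  single <- pooled_sum_null(3, 4)
  expect_equal(single$values, 7)
  expect_equal(single$ci_low, 7)
  expect_equal(single$ci_high, 7)
  withr::with_seed(71, {
    for (k in 1:5) {
      a <- stats::rnorm(sample(2:10, 1)); b <- stats::rnorm(sample(2:10, 1))
      p <- pooled_sum_null(a, b)
      expect_equal(mean(p$values), mean(a) + mean(b), tolerance = 1e-12)
      expect_lte(p$ci_low, p$ci_high)
      expect_length(p$values, length(a) * length(b))
    }
  })
})

test_that("bootstrap p hits its floor when the observed mean beats every pooled sum", {
  pool <- pooled_sum_null(c(1, 2, 3), c(1, 2))
  res <- synergy_bootstrap_p(pool, combined_group = c(10, 12), n_boot = 999,
                             seed = 1)
  expect_equal(res$p_value, 1 / 1000)
})

test_that("a two-value pool with a midpoint observation converges to p = 0.5", {
  pool <- pooled_sum_null(c(0.5), c(0.5, 2.5)) # pool = {1, 3}
  res <- synergy_bootstrap_p(pool, combined_group = 2, n_boot = 4000, seed = 2)
  expect_equal(res$p_value, 0.5, tolerance = 0.05)
})

test_that("a fixed seed reproduces the bootstrap p bit for bit", {
  withr::with_seed(72, {
    pool <- pooled_sum_null(stats::rnorm(5, 2), stats::rnorm(5, 1.5))
    comb <- stats::rnorm(3, 3.6, 0.1)
  })
  p1 <- synergy_bootstrap_p(pool, comb, n_boot = 5000, seed = 99)$p_value
  p2 <- synergy_bootstrap_p(pool, comb, n_boot = 5000, seed = 99)$p_value
  expect_identical(p1, p2)
  # monotone non-increasing in the observed mean under the same seed schedule
  shifts <- c(0, 0.2, 0.5, 1)
  ps <- vapply(shifts, function(d) {
    synergy_bootstrap_p(pool, comb + d, n_boot = 2000, seed = 7)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps >= 1 / 2001 & ps <= 1))
})

test_that("noise-free additive data are judged non-synergistic, exact-sum data sit in the CI", {
  sim <- gen_luciferase(mode = "additive", noise_sd = 0, seed = 73)
  res <- luciferase_synergy(sim$table, sim$control_group, sim$group_a,
                            sim$group_b, sim$combined, n_boot = 500, seed = 1)
  expect_equal(res$p_value, 1) # combined mean 2.5 < every pooled sum (3.5)
  sum_sim <- gen_luciferase(mode = "sum", noise_sd = 0, seed = 74)
  res2 <- luciferase_synergy(sum_sim$table, sum_sim$control_group,
                             sum_sim$group_a, sum_sim$group_b,
                             sum_sim$combined, n_boot = 500, seed = 1)
  expect_gte(res2$observed_mean, res2$pool$ci_low)
  expect_lte(res2$observed_mean, res2$pool$ci_high)
})

test_that("synergistic data reject additivity and tidy() reports the test", {
  withr::with_seed(75, {
    rejected <- vapply(1:20, function(i) {
      sim <- gen_luciferase(mode = "synergistic", synergy_factor = 2,
                            noise_sd = 0.05)
      res <- luciferase_synergy(sim$table, sim$control_group, sim$group_a,
                                sim$group_b, sim$combined, n_boot = 400)
      res$p_value < 0.05
    }, logical(1))
    expect_gte(mean(rejected), 0.9)
  })
  sim <- gen_luciferase(mode = "synergistic", seed = 76)
  res <- luciferase_synergy(sim$table, sim$control_group, sim$group_a,
                            sim$group_b, sim$combined, n_boot = 200, seed = 3)
  td <- tidy(res)
  expect_identical(nrow(td), 1L)
  expect_true(all(c("observed_mean", "ci_low", "ci_high", "p_value") %in% names(td)))
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
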