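test_that("mean_sem matches hand calculations and rejects degenerate input", {
  expect_equal(mean_sem(c(5, 5, 5)), tibble::tibble(mean = 5, sem = 0, n = 3L))
  ms <- mean_sem(c(1, 2, 3))
  expect_equal(ms$mean, 2)
  expect_equal(ms$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_error(mean_sem(numeric(0)), "non-empty")
  expect_error(mean_sem(7), "n = 1")
})

test_that("pooled t-test matches the closed form on random samples", {
  pooled_t <- function(a, b) {
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    df <- length(a) + length(b) - 2
    list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
  }
  withr::with_seed(123, {
    for (i in 1:100) {
      a <- rnorm(sample(2:12, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
      b <- rnorm(sample(2:12, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
      res <- t_test_groups(a, b)
      ref <- pooled_t(a, b)
      expect_equal(res$t_statistic, ref$t, tolerance = 1e-10)
      expect_equal(res$degrees_of_freedom, ref$df)
      expect_equal(res$p_value, ref$p, tolerance = 1e-10)
    }
  })
})

test_that("worked t-test example and edge conventions hold", {
  res <- t_test_groups(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t_statistic, -1.2247, tolerance = 1e-4)
  expect_equal(res$degrees_of_freedom, 4)
  expect_equal(res$p_value, 0.2879, tolerance = 1e-3)
  same <- t_test_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  degen <- t_test_groups(c(0, 0), c(0, 0))
  expect_true(degen$degenerate_flag)
  expect_equal(degen$p_value, 1)
  expect_error(t_test_groups(1, c(1, 2)), "at least two")
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(glance(res),
               c("t_statistic", "degrees_of_freedom", "p_value", "stars"))
})

test_that("significance stars follow the figure-legend thresholds", {
  expect_identical(significance_stars(0.00005), "****")
  expect_identical(significance_stars(0.0007), "**")
  expect_identical(significance_stars(0.2), "ns")
  # boundary probes: thresholds are strict
  expect_identical(
    significance_stars(c(0.0001, 0.0005, 0.001, 0.05)),
    c("***", "**", "*", "ns")
  )
  expect_identical(
    significance_stars(c(9.9e-5, 4.9e-4, 9.9e-4, 0.049)),
    c("****", "***", "**", "*")
  )
  # star count is monotone non-increasing in p
  ps <- sort(runif(50))
  n_stars <- nchar(gsub("ns", "", significance_stars(ps)))
  expect_true(all(diff(n_stars) <= 0))
  expect_error(significance_stars(1.2), "0, 1")
  expect_error(significance_stars(-0.1), "0, 1")
})

test_that("relative expression halves per extra cycle and is reciprocal", {
  expect_equal(relative_expression(20, 20), 1)
  expect_equal(relative_expression(21, 20), 0.5)
  expect_equal(relative_expression(18, 20), 4)
  for (k in c(-3, 0.5, 2, 7)) {
    expect_equal(relative_expression(10, 10 + k) *
                   relative_expression(10 + k, 10), 1)
  }
  expect_error(relative_expression(NA, 20), "finite")
})

test_that("expression_table joins targets to the per-sample reference Ct", {
  ct <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 3),
    gene = rep(c("EF1a", "CDC20", "MAD2L1"), 2),
    ct = c(20, 22, 21, 19, 22, 23)
  )
  et <- expression_table(ct)
  expect_identical(nrow(et), 4L)
  expect_equal(et$relative_expression[et$sample_id == "s1" &
                                        et$target_gene == "CDC20"], 0.25)
  expect_equal(et$relative_expression[et$sample_id == "s2" &
                                        et$target_gene == "MAD2L1"], 2^-4)
  expect_error(expression_table(dplyr::filter(ct, gene != "EF1a")),
               "Reference gene")
  expect_error(
    expression_table(rbind(ct, tibble::tibble(sample_id = "s3",
                                              gene = "CDC20", ct = 25))),
    "s3"
  )
})

test_that("phase frequencies are percentages summing to 100", {
  pf <- phase_frequencies(c(late_prophase = 63, prometaphase_metaphase = 30,
                            anaphase = 7))
  expect_equal(pf$percent, c(63, 30, 7))
  one <- phase_frequencies(c(G2 = 5))
  expect_equal(one$percent, 100)
  eq <- phase_frequencies(stats::setNames(rep(2, 6), mitosis_phases()))
  expect_equal(eq$percent, rep(100 / 6, 6))
  expect_equal(sum(eq$percent), 100, tolerance = 0.01)
  expect_error(phase_frequencies(c(G2 = 0)), "positive")
  expect_error(phase_frequencies(c(G2 = -1, S = 3)), "non-negative")
})

test_that("group summaries and pairwise comparisons assemble tidily", {
  withr::with_seed(5, {
    df <- tibble::tibble(
      stage = rep(c(1, 3), each = 9),
      ploidy_class = rep(rep(c("2n", "3n_alpha", "3n_beta"), each = 3), 2),
      gti_percent = c(rnorm(3, 20, 1), rnorm(3, 17, 1), rnorm(3, 10, 1),
                      rnorm(3, 85, 2), rnorm(3, 71, 2), rnorm(3, 23, 2))
    )
  })
  gs <- group_summary(df, "gti_percent")
  expect_identical(nrow(gs), 6L)
  expect_true(all(gs$n == 3))
  cmp <- compare_groups(df, "gti_percent")
  expect_identical(nrow(cmp), 6L)  # 3 pairs x 2 stages
  big <- cmp[cmp$stage == 3 & cmp$group_a == "2n" & cmp$group_b == "3n_beta", ]
  expect_lt(big$p_value, 0.001)
  expect_gt(big$mean_a, big$mean_b)
})
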