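# brute-force step-up evaluation of the Benjamini–Hochberg definition:
# find the largest k with p_(k) <= k q / m and reject the k smallest
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) * q / m)
  rej <- rep(FALSE, m)
  if (length(ks) > 0) rej[o[seq_len(max(ks))]] <- TRUE
  rej
}

test_that("t-test wrappers match hand computation and handle tails", {
  x <- c(0.54, 0.57, 0.49, 0.61, 0.53)
  res <- one_sample_t(x, mu0 = 0.5, tail = "greater")
  t_hand <- (mean(x) - 0.5) / (sd(x) / sqrt(5))
  expect_equal(res$statistic, t_hand)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, pt(t_hand, df = 4, lower.tail = FALSE))
  # two-tailed p doubles the one-tailed p on the hypothesized side
  res2 <- one_sample_t(x, mu0 = 0.5, tail = "two")
  expect_equal(res2$p_value, 2 * res$p_value)

  sym <- c(0.4, 0.6, 0.45, 0.55)
  expect_equal(one_sample_t(sym, 0.5, "two")$statistic, 0)
  expect_equal(one_sample_t(sym, 0.5, "two")$p_value, 1)
  expect_equal(paired_t(x, x)$statistic, 0)
  expect_error(one_sample_t(rep(0.5, 4), 0.5), "zero variance")
})

test_that("BH rejection mask follows the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05), rep(TRUE, 4))
  expect_true(bh_fdr(0.04, q = 0.05))
  expect_equal(bh_fdr(rep(1, 5)), rep(FALSE, 5))
  # step-up rescue: a late small p-value rescues earlier ones
  p <- c(0.04, 0.049, 0.05, 0.01)
  expect_equal(bh_fdr(p, q = 0.05), bh_oracle(p, 0.05))
})

test_that("BH equals the brute-force step-up definition for m <= 10", {
  set.seed(31)
  for (i in 1:60) {
    m <- sample(1:10, 1)
    p <- round(runif(m)^2, 3)       # ties happen after rounding
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_equal(bh_fdr(p, q), bh_oracle(p, q))
  }
})

test_that("the per-region ledger enumerates exactly the 12 tests", {
  set.seed(12)
  n <- 13
  res <- tibble::tibble(
    participant = sprintf("s%02d", 1:n),
    category_acc_oddball = rnorm(n, 0.72, 0.05),
    category_acc_oneback = rnorm(n, 0.75, 0.05),
    task_acc = rnorm(n, 0.62, 0.05),
    category_cross_acc = rnorm(n, 0.68, 0.05),
    cross_ratio = rnorm(n, 0.85, 0.1),
    task_cross_acc = rnorm(n, 0.60, 0.05),
    pdd_acc = rnorm(n, 0.55, 0.04))
  res$category_acc_overall <- (res$category_acc_oddball +
                                 res$category_acc_oneback) / 2
  led <- region_test_ledger(res)
  expect_equal(nrow(led), 12)
  expect_equal(anyDuplicated(led$test), 0)
  expect_equal(led$tail[led$test == "category_oddball_vs_oneback"], "two")
  expect_equal(led$tail[led$test == "cross_ratio_vs_one"], "less")
  expect_equal(led$tail[led$test == "pattern_difference_vs_chance"],
               "greater")
  expect_equal(led$significant, bh_oracle(led$p_value, 0.05))
  # deterministic
  expect_identical(led, region_test_ledger(res))
  # missing inputs are named
  expect_error(region_test_ledger(res[setdiff(names(res),
                                              "category_cross_acc")]),
               "category cross-decoding")
})

test_that("sector aggregation averages final per-region values", {
  per <- tidyr::expand_grid(participant = c("p1", "p2"),
                            region = c("V1", "V2", "V3", "V4"))
  per$value <- rep(c(0.6, 0.6, 0.7, 0.7), 2)
  sec <- sector_aggregate(per, list(`V1-V4` = c("V1", "V2", "V3", "V4")))
  expect_equal(sec$value, c(0.65, 0.65))
  one <- sector_aggregate(per[per$region == "V1", ], list(solo = "V1"))
  expect_equal(one$value, c(0.6, 0.6))
  expect_error(sector_aggregate(per[-1, ],
                                list(`V1-V4` = c("V1", "V2", "V3", "V4"))),
               "missing region")
  expect_error(sector_aggregate(per, list(a = "V1", b = c("V1", "V2"))),
               "at most one sector")
})

test_that("sectors average ratios, not accuracies entering ratios", {
  # averaging accuracies then taking the ratio is not the same as
  # averaging the per-region ratios: the final-stage rule is the latter
  within <- c(0.9, 0.6); between <- c(0.7, 0.58)
  per_region_ratio <- cross_decoding_ratio(within, between)
  final_stage <- mean(per_region_ratio)
  premature <- cross_decoding_ratio(mean(within), mean(between))
  expect_false(isTRUE(all.equal(final_stage, premature)))
  per <- tibble::tibble(participant = "p1", region = c("a", "b"),
                        value = per_region_ratio)
  sec <- sector_aggregate(per, list(ab = c("a", "b")))
  expect_equal(sec$value, final_stage)
})
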