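test_that("difference-vector sets enumerate runs x pairs with fixed order", {
  co <- simulate_cohort(small_config(n_participants = 1, n_categories = 8,
                                     n_runs_per_task = 10, n_voxels = 16))
  d <- co$data
  dv <- difference_vectors(d, "category")
  expect_equal(nrow(dv), choose(8, 2) * 20)            # 280 per task
  expect_equal(as.integer(table(dv$context)), c(280L, 280L))
  dv2 <- difference_vectors(d, "task")
  expect_equal(nrow(dv2), 8 * 10)                      # categories x folds
  expect_equal(unique(dv2$pair), "Oddball|Oneback")
  expect_equal(sort(unique(dv2$context)), sort(unique(d$category)))
})

test_that("subtraction order is lexicographic and exact", {
  d <- toy_two_class(noise_sd = 0.1, seed = 3)
  dv <- difference_vectors(d, "category")
  a <- d$pattern[d$run == 1 & d$category == "A", ]
  b <- d$pattern[d$run == 1 & d$category == "B", ]
  v <- dv$vector[dv$fold == 1, , drop = FALSE][1, ]
  expect_equal(unname(v), unname(a - b))   # "A|B" means A minus B

  # identical block patterns give the zero vector
  dz <- d
  dz$pattern[dz$run == 1, ] <- matrix(rep(dz$pattern[1, ], 2), 2,
                                      byrow = TRUE)
  dvz <- difference_vectors(dz, "category")
  expect_equal(unname(dvz$vector[dvz$fold == 1, ][1, ]),
               rep(0, ncol(dz$pattern)))
})

test_that("incomplete pairs are skipped with a warning, not dropped silently", {
  d <- small_cohort(n_participants = 1)$data
  d_missing <- d[!(d$run == 1 & d$category == "cat01"), ]
  expect_warning(dv <- difference_vectors(d_missing, "category"),
                 "skipped")
  full <- choose(4, 2) * length(unique(d$run))
  expect_equal(nrow(dv), full - 3)   # cat01 pairs with 3 others in run 1
})

test_that("interaction decoding is invariant to task relabeling", {
  fx <- scenario_fixtures(n_runs_per_task = 8)
  d <- fx$interaction_reversing
  a1 <- pattern_difference_decoding(d)$accuracy
  d2 <- d
  d2$task <- ifelse(d$task == "Oddball", "Oneback", "Oddball")
  a2 <- pattern_difference_decoding(d2)$accuracy
  expect_equal(a1, a2)
})

test_that("cross-decoding ratio matches its closed forms", {
  expect_equal(cross_decoding_ratio(0.75, 0.625), 0.5)
  expect_equal(cross_decoding_ratio(0.8, 0.8), 1)
  expect_equal(cross_decoding_ratio(0.75, 0.6, transform = "probit"),
               qnorm(0.6) / qnorm(0.75))
  expect_equal(round(cross_decoding_ratio(0.75, 0.6, "probit"), 4), 0.3756)
  expect_warning(r <- cross_decoding_ratio(c(0.75, 0.45), c(0.6, 0.6)),
                 "undefined")
  expect_equal(r, c(0.4, NA))
  expect_error(cross_decoding_ratio(0.75, 1, transform = "probit"),
               "inside")
})

test_that("direction correlation guards its preconditions", {
  expect_equal(direction_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(direction_correlation(c(1, 2), c(1, 2)), "3 participants")
  expect_error(direction_correlation(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
})

test_that("permutation p-values hit their edge cases", {
  fx <- scenario_fixtures(n_runs_per_task = 8)
  # perfectly decodable interaction: no permutation can beat the observed
  res <- pdd_permutation_test(fx$interaction_reversing, n_perm = 30,
                              seed = 5)
  expect_equal(res$p_value, 0)
  expect_equal(res$observed, 1)
  res2 <- pdd_permutation_test(fx$interaction_reversing, n_perm = 30,
                               seed = 5, correction = "add_one")
  expect_equal(res2$p_value, 1 / 31)
  # reproducible for a fixed seed
  res3 <- pdd_permutation_test(fx$oblique, n_perm = 20, seed = 9)
  res4 <- pdd_permutation_test(fx$oblique, n_perm = 20, seed = 9)
  expect_identical(res3$p_value, res4$p_value)
})

test_that("graded interaction strength raises interaction decoding", {
  accs <- sapply(c(0, 0.5, 1.0), function(g) {
    co <- simulate_cohort(small_config(
      n_participants = 2, n_categories = 4, n_runs_per_task = 6,
      n_voxels = 60, geometry_mode = if (g == 0) "additive" else "rotation",
      interaction_gain = g, category_gain = 0.45, seed = 77))
    mean(pattern_difference_decoding(znormalize_blocks(co$data))$accuracy)
  })
  expect_true(all(diff(accs) > -0.05))   # non-decreasing up to noise
  expect_gt(accs[3], accs[1] + 0.05)
})
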