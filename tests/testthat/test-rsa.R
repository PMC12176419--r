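fake_condition_pairs <- function(n_cat = 8, seed = 1) {
  set.seed(seed)
  conds <- as.vector(outer(sprintf("cat%02d", 1:n_cat),
                           c("Oddball", "Oneback"), paste, sep = ":"))
  p <- utils::combn(sort(conds), 2)
  tibble::tibble(cond_a = p[1, ], cond_b = p[2, ],
                 accuracy = runif(ncol(p), 0.4, 1))
}

test_that("a full 16-condition RDM has 120 distinct pairs", {
  pw <- fake_condition_pairs()
  expect_equal(nrow(pw), 120)
  rdm <- condition_rdm(pw)
  expect_equal(dim(rdm), c(16, 16))
  expect_true(all(diag(rdm) == 0))
  expect_equal(unclass(rdm), t(unclass(rdm)))
  expect_error(condition_rdm(pw[-5, ]), "missing pairwise accuracy")
})

test_that("chance subtraction clips negative distances to zero", {
  pw <- fake_condition_pairs()
  pw$accuracy <- rep(c(0.5, 0.45, 0.8), length.out = nrow(pw))
  dm <- clip_chance_distances(condition_rdm(pw))
  vals <- sort(unique(dm[upper.tri(dm)]))
  expect_equal(vals, c(0, 0.3))
  expect_true(all(dm >= 0 & dm <= 0.5))
})

test_that("classical MDS recovers an exact Euclidean configuration", {
  pts <- matrix(c(0, 0, 3, 0, 3, 4, 0, 4), 4, 2, byrow = TRUE,
                dimnames = list(letters[1:4], NULL))
  m <- as.matrix(dist(pts))
  rdm <- mixsel:::new_rdm(m)
  emb <- mds_embed(rdm, n_dims = 2)
  rec <- as.matrix(dist(as.matrix(emb[, c("dim1", "dim2")])))
  expect_lt(max(abs(rec - m)), 1e-9)
  # canonical orientation is deterministic
  emb2 <- mds_embed(rdm, n_dims = 2)
  expect_identical(emb, emb2)

  zero <- mixsel:::new_rdm(matrix(0, 3, 3,
                                  dimnames = list(letters[1:3],
                                                  letters[1:3])))
  expect_warning(e0 <- mds_embed(zero), "degenerate")
  expect_true(all(e0$dim1 == 0 & e0$dim2 == 0))
})

test_that("category similarity vectors use a stable canonical pair order", {
  co <- simulate_cohort(small_config(n_participants = 1, n_categories = 8,
                                     n_runs_per_task = 2, n_voxels = 16))
  pa <- category_pair_accuracies(znormalize_blocks(co$data))
  sv <- category_similarity_vectors(pa)
  expect_equal(ncol(sv$sim), 28)
  expect_equal(nrow(sv), 2)   # one vector per task
  # entries equal the underlying pairwise accuracies, unclipped
  g <- pa[pa$task == "Oddball", ]
  v <- sv$sim[sv$task == "Oddball", , drop = FALSE]
  key <- paste(g$cat_a, g$cat_b, sep = "|")
  expect_equal(unname(drop(v))[match(key, colnames(sv$sim))], g$accuracy)
  # shuffling row order does not change the vector
  sv2 <- category_similarity_vectors(pa[sample(nrow(pa)), ])
  expect_equal(sv$sim, sv2$sim)
})

test_that("second-order distances are 1 minus Pearson r", {
  sv <- tibble::tibble(
    participant = "p", region = c("r1", "r2", "r3"), task = "Oddball",
    sim = rbind(c(1, 2, 3, 4), c(4, 3, 2, 1), c(1, 3, 2, 4)))
  so <- second_order_rdm(sv)
  expect_equal(so["r1:Oddball", "r2:Oddball"], 1 - cor(c(1, 2, 3, 4),
                                                       c(4, 3, 2, 1)))
  expect_equal(so["r1:Oddball", "r3:Oddball"], 1 - cor(c(1, 2, 3, 4),
                                                       c(1, 3, 2, 4)))
  expect_true(all(so >= 0 & so <= 2))
  sv$sim[2, ] <- 1
  expect_error(second_order_rdm(sv), "zero-variance")
})

test_that("variance explained is 1 for identical geometries and excludes
           the participant's own data from the reference", {
  base <- c(0.9, 0.7, 0.8, 0.55, 0.95, 0.6)
  sv <- tidyr::expand_grid(participant = c("p1", "p2", "p3", "p4"),
                           task = c("Oddball", "Oneback"))
  sv$region <- "r"
  sv$sim <- matrix(rep(base, each = nrow(sv)), nrow(sv))
  ve <- geometry_variance_explained(sv)
  expect_equal(ve$variance_explained, rep(1, 4))
  expect_equal(ve$within, rep(1, 4))

  # an aberrant participant cannot inflate their own reference
  sv2 <- sv
  odd_vec <- rev(base)
  sv2$sim[sv2$participant == "p4", ] <- matrix(rep(odd_vec, each = 2), 2)
  ve2 <- geometry_variance_explained(sv2)
  ref_cor <- cor(odd_vec, base)
  expect_equal(ve2$within[4], ref_cor, tolerance = 1e-12)
})

test_that("between-task RDM correlation and its coupling test work", {
  sv <- tibble::tibble(
    participant = rep(c("p1", "p2", "p3"), each = 2),
    region = "r",
    task = rep(c("Oddball", "Oneback"), 3),
    sim = rbind(c(1, 2, 3), c(1, 2, 3),
                c(1, 2, 3), c(3, 2, 1),
                c(1, 3, 2), c(1, 3, 2)))
  btr <- between_task_rdm_correlation(sv)
  expect_equal(btr$between_task_r, c(1, -1, 1))
  res <- interaction_geometry_correlation(c(0.5, 0.9, 0.5),
                                          btr$between_task_r)
  expect_equal(res$r, -1)
  expect_error(interaction_geometry_correlation(c(1, 1, 1), c(1, 0, 1)),
               "zero variance")
})

test_that("rotated geometries embed congruently across tasks", {
  co <- simulate_cohort(small_config(
    n_participants = 1, n_categories = 6, n_voxels = 40,
    geometry_mode = "rotation", interaction_gain = 0.9, category_gain = 0.3))
  tp <- co$truth$participants[[1]]
  embed_task <- function(m) {
    dm <- as.matrix(dist(m))
    dimnames(dm) <- list(sprintf("c%d", 1:6), sprintf("c%d", 1:6))
    as.matrix(mds_embed(mixsel:::new_rdm(dm), n_dims = 2)[, c("dim1",
                                                              "dim2")])
  }
  e1 <- embed_task(tp$category_templates_per_task[[1]])
  e2 <- embed_task(tp$category_templates_per_task[[2]])
  pr <- vegan::procrustes(e1, e2, symmetric = TRUE)
  expect_lt(pr$ss, 1e-9)
})
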