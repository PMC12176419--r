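#' Representational dissimilarity matrices
#'
#' An RDM is a symmetric condition-by-condition matrix with zero diagonal.
#' Here dissimilarities are pairwise decoding accuracies (chance .5 means
#' indistinguishable).
#'
#' `condition_rdm()` assembles an RDM from a long table of pairwise
#' accuracies as produced by [condition_pairwise_accuracies()] or
#' [category_pair_accuracies()] (for the latter, pass the task-specific
#' subset and name the columns `cond_a`/`cond_b`). Every off-diagonal pair
#' must be present; a missing pair is an error naming it.
#'
#' @param pairwise long tibble with columns `cond_a`, `cond_b`, `accuracy`;
#'   if several rows per pair are present (e.g. several participants) they
#'   are averaged.
#' @return a `mixsel_rdm`: a labeled symmetric matrix.
#' @export
condition_rdm <- function(pairwise) {
  stopifnot(all(c("cond_a", "cond_b", "accuracy") %in% names(pairwise)))
  pw <- pairwise |>
    group_by(.data$cond_a, .data$cond_b) |>
    summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  labels <- sort(unique(c(pw$cond_a, pw$cond_b)))
  m <- matrix(NA_real_, length(labels), length(labels),
              dimnames = list(labels, labels))
  diag(m) <- 0
  idx_a <- match(pw$cond_a, labels); idx_b <- match(pw$cond_b, labels)
  m[cbind(idx_a, idx_b)] <- pw$accuracy
  m[cbind(idx_b, idx_a)] <- pw$accuracy
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(sprintf("missing pairwise accuracy for %s vs %s",
                  labels[miss[1]], labels[miss[2]]))
  }
  new_rdm(m)
}

new_rdm <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m),
            isTRUE(all.equal(m, t(m))), all(diag(m) == 0))
  structure(m, class = c("mixsel_rdm", "matrix", "array"))
}

#' @export
print.mixsel_rdm <- function(x, ...) {
  cat(sprintf("Condition RDM: %d conditions, %d pairs\n",
              nrow(x), choose(nrow(x), 2)))
  print(unclass(round(x, 3)))
  invisible(x)
}

#' Convert accuracy dissimilarities to distances for embedding
#'
#' Subtracts chance (.5) from each pairwise accuracy and clips negative
#' results to zero, yielding a valid distance-like matrix for
#' multidimensional scaling (chance-level pairs map to distance 0).
#'
#' @param rdm a `mixsel_rdm` of accuracies.
#' @return a `mixsel_rdm` of clipped distances in [0, .5].
#' @export
clip_chance_distances <- function(rdm) {
  stopifnot(inherits(rdm, "mixsel_rdm"))
  m <- pmax(unclass(rdm) - CHANCE, 0)
  diag(m) <- 0
  new_rdm(m)
}

#' Classical multidimensional scaling of an RDM
#'
#' Deterministic classical (Torgerson) scaling via double-centering
#' eigendecomposition, with a fixed orientation: in each output dimension
#' the coordinate of largest magnitude is made positive. Exact Euclidean
#' configurations are recovered up to this canonical orientation.
#'
#' @param rdm a `mixsel_rdm` of distances (see [clip_chance_distances()]).
#' @param n_dims number of embedding dimensions.
#' @return a `mixsel_mds` tibble: `condition`, `dim1`, `dim2`, ...
#' @export
mds_embed <- function(rdm, n_dims = 2) {
  stopifnot(inherits(rdm, "mixsel_rdm"))
  m <- unclass(rdm)
  if (all(m == 0)) {
    warn("degenerate all-zero RDM: all conditions embed at the origin")
    coords <- matrix(0, nrow(m), n_dims)
  } else {
    # rank-deficient configurations are padded with zero dimensions below
    coords <- suppressWarnings(cmdscale(m, k = n_dims))
    if (ncol(coords) < n_dims) {   # rank-deficient configuration
      coords <- cbind(coords,
                      matrix(0, nrow(coords), n_dims - ncol(coords)))
    }
    for (j in seq_len(ncol(coords))) {
      i <- which.max(abs(coords[, j]))
      if (coords[i, j] < 0) coords[, j] <- -coords[, j]
    }
  }
  out <- as_tibble(coords, .name_repair = ~ paste0("dim", seq_len(n_dims)))
  out <- dplyr::bind_cols(tibble(condition = rownames(m)), out)
  class(out) <- c("mixsel_mds", class(out))
  out
}

# canonical lexicographic category-pair order shared by all similarity
# vectors
canonical_pairs <- function(cats) {
  p <- combn(sort(unique(cats)), 2)
  paste(p[1, ], p[2, ], sep = "|")
}

#' Category similarity vectors per participant and task
#'
#' Flattens the per-task pairwise category accuracies (no chance subtraction,
#' no clipping) into vectors in a canonical lexicographic pair order — the
#' unit of all RDM-correlation analyses (28 entries for 8 categories).
#'
#' @param pair_acc long tibble from [category_pair_accuracies()].
#' @return tibble: `participant`, `region`, `task`, matrix column `sim`.
#' @export
category_similarity_vectors <- function(pair_acc) {
  stopifnot(all(c("participant", "region", "task", "cat_a", "cat_b",
                  "accuracy") %in% names(pair_acc)))
  order_key <- canonical_pairs(c(pair_acc$cat_a, pair_acc$cat_b))
  groups <- dplyr::group_split(
    group_by(pair_acc, .data$participant, .data$region, .data$task))
  out <- list_rbind(map(groups, function(g) {
    key <- paste(g$cat_a, g$cat_b, sep = "|")
    if (!setequal(key, order_key) || anyDuplicated(key) > 0) {
      abort(sprintf("incomplete category pair set for %s / %s / %s",
                    g$participant[1], g$region[1], g$task[1]))
    }
    tibble(participant = g$participant[1], region = g$region[1],
           task = g$task[1],
           sim = matrix(g$accuracy[match(order_key, key)], nrow = 1,
                        dimnames = list(NULL, order_key)))
  }))
  colnames(out$sim) <- order_key   # row-binding drops matrix dimnames
  out
}

#' Second-order RDM across region-task entries
#'
#' Correlation distance (1 - Pearson r) between category similarity vectors,
#' one entry per (region, task); participants are averaged first. Embedding
#' this RDM shows how representational geometry varies across regions and
#' task contexts.
#'
#' @param sim_vectors tibble from [category_similarity_vectors()].
#' @return a `mixsel_rdm` over `"region:task"` entries, distances in [0, 2].
#' @export
second_order_rdm <- function(sim_vectors) {
  groups <- dplyr::group_split(
    group_by(sim_vectors, .data$region, .data$task))
  if (length(groups) < 2) abort("need at least 2 (region, task) entries")
  labels <- map_chr(groups, ~ paste(.x$region[1], .x$task[1], sep = ":"))
  vecs <- map(groups, ~ colMeans(.x$sim))
  if (any(map_dbl(vecs, sd) == 0)) {
    abort("zero-variance similarity vector; correlation distance undefined")
  }
  cmat <- cor(do.call(cbind, vecs))
  m <- 1 - cmat
  diag(m) <- 0
  m <- (m + t(m)) / 2
  dimnames(m) <- list(labels, labels)
  new_rdm(m)
}

#' Reliability-corrected between-task geometry comparison
#'
#' Quantifies how much a task change alters the category representational
#' geometry, corrected for how reliable that geometry is across participants
#' (its noise ceiling). For each participant, the within-task correlation
#' compares their similarity vector for a task with the average vector of
#' the *remaining* participants for the same task (averaged over the two
#' tasks); the between-task correlation crosses tasks the same way. Each
#' participant's between-task correlation is divided by the group-mean
#' within-task correlation and squared, giving the proportion of reliable
#' RDM variance shared across tasks: 1 means the geometry is unchanged by
#' task; values below 1 indicate a genuine geometry change (reshaping rather
#' than mere rotation of the pattern space, which leaves the RDM intact).
#'
#' Negative correlations are not clipped before squaring: the squared ratio
#' discards the sign, and the sign is retained in the per-participant
#' columns.
#'
#' @param sim_vectors tibble from [category_similarity_vectors()], both
#'   tasks, at least 3 participants.
#' @return tibble per participant x region: `within`, `between`,
#'   `group_mean_within`, `variance_explained`.
#' @export
geometry_variance_explained <- function(sim_vectors) {
  regions <- dplyr::group_split(group_by(sim_vectors, .data$region))
  list_rbind(map(regions, function(sv) {
    tasks <- sort(unique(sv$task))
    stopifnot(length(tasks) == 2)
    parts <- sort(unique(sv$participant))
    if (length(parts) < 3) abort("need at least 3 participants")
    get_vec <- function(p, tk) {
      row <- dplyr::filter(sv, .data$participant == p, .data$task == tk)
      if (nrow(row) != 1) abort(sprintf("missing vector for %s / %s", p, tk))
      drop(row$sim)
    }
    others_mean <- function(p, tk) {
      vs <- map(setdiff(parts, p), get_vec, tk = tk)
      colMeans(do.call(rbind, vs))
    }
    per <- map(parts, function(p) {
      own <- map(tasks, get_vec, p = p)
      ref <- map(tasks, others_mean, p = p)
      if (any(map_dbl(c(own, ref), sd) == 0)) {
        abort(sprintf("zero-variance similarity vector (participant %s)", p))
      }
      within <- mean(c(cor(own[[1]], ref[[1]]), cor(own[[2]], ref[[2]])))
      between <- mean(c(cor(own[[1]], ref[[2]]), cor(own[[2]], ref[[1]])))
      tibble(participant = p, region = sv$region[1],
             within = within, between = between)
    }) |> list_rbind()
    per$group_mean_within <- mean(per$within)
    per$variance_explained <- (per$between / per$group_mean_within)^2
    per
  }))
}

#' Direct between-task RDM correlation per participant
#'
#' Correlates each participant's own task-1 and task-2 category similarity
#' vectors — a fully within-participant measure of geometry preservation,
#' suitable for correlating with other within-participant quantities.
#'
#' @inheritParams geometry_variance_explained
#' @return tibble per participant x region with `between_task_r`.
#' @export
between_task_rdm_correlation <- function(sim_vectors) {
  groups <- dplyr::group_split(
    group_by(sim_vectors, .data$participant, .data$region))
  list_rbind(map(groups, function(g) {
    tasks <- sort(unique(g$task))
    stopifnot(length(tasks) == 2)
    v1 <- drop(g$sim[g$task == tasks[1], , drop = FALSE])
    v2 <- drop(g$sim[g$task == tasks[2], , drop = FALSE])
    if (sd(v1) == 0 || sd(v2) == 0) {
      abort(sprintf("zero-variance similarity vector (participant %s)",
                    g$participant[1]))
    }
    tibble(participant = g$participant[1], region = g$region[1],
           between_task_r = cor(v1, v2))
  }))
}

#' Correlation between interaction strength and geometry change
#'
#' Across participants, correlates the pattern-difference decoding accuracy
#' (interaction strength) with the direct between-task RDM correlation
#' (geometry preservation). A negative correlation indicates that stronger
#' interactive coding goes with a larger change in representational content.
#'
#' @param pdd_accuracy numeric vector, one interaction decoding accuracy per
#'   participant.
#' @param between_task_r numeric vector, same participants, from
#'   [between_task_rdm_correlation()].
#' @return one-row tibble with Pearson `r` and the two-tailed `p_value`.
#' @export
interaction_geometry_correlation <- function(pdd_accuracy, between_task_r) {
  stopifnot(length(pdd_accuracy) == length(between_task_r))
  if (length(pdd_accuracy) < 3) abort("need at least 3 participants")
  if (sd(pdd_accuracy) == 0 || sd(between_task_r) == 0) {
    abort("zero variance; correlation undefined")
  }
  ct <- cor.test(pdd_accuracy, between_task_r, alternative = "two.sided")
  tibble(r = unname(ct$estimate), p_value = ct$p.value,
         n = length(pdd_accuracy))
}
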