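#' Build difference vectors between condition pairs
#'
#' The multivariate interaction test classifies *difference vectors*: a
#' difference vector is the subtraction of two same-context block patterns
#' that differ in the differencing variable, with a fixed global subtraction
#' order (lexicographically smaller label minus larger).
#'
#' With `differencing = "category"`, the two blocks of a category pair come
#' from the same run (which fixes the task context and cancels run-level
#' additive artifacts); the vector is tagged with that run's task. With
#' `differencing = "task"`, the two blocks come from the two runs of an
#' adjacent run pair (one run per task) and share a category, which becomes
#' the context tag. Fold ids are adjacent run pairs in both cases, so
#' downstream cross-validation never splits a run across folds.
#'
#' A (fold, pair) whose members are incomplete is skipped with a warning;
#' if nothing remains, an error is raised.
#'
#' @param data a pattern tibble (z-normalize first for beta patterns).
#' @param differencing `"category"` or `"task"` — the variable subtracted
#'   out; the other variable is the context the classifier must discriminate.
#' @return tibble: `participant`, `region`, `fold`, `pair`, `context`,
#'   and a matrix column `vector`.
#' @export
difference_vectors <- function(data, differencing = c("category", "task")) {
  differencing <- match.arg(differencing)
  map_participants(data, function(d) {
    folds <- adjacent_pair_folds(
      d, require_both_tasks = differencing == "task")
    d <- left_join(d, folds, by = "run")
    out <- if (differencing == "category") {
      category_difference_vectors(d)
    } else {
      task_difference_vectors(d)
    }
    if (nrow(out) == 0) abort("no complete difference-vector pairs found")
    out
  })
}

category_difference_vectors <- function(d) {
  pairs <- category_pairs(d$category)
  rows <- list(); skipped <- character()
  for (r in sort(unique(d$run))) {
    dr <- dplyr::filter(d, .data$run == r)
    for (p in pairs) {
      i <- match(p[1], dr$category); j <- match(p[2], dr$category)
      if (is.na(i) || is.na(j)) {
        skipped <- c(skipped, sprintf("run %d pair %s|%s", r, p[1], p[2]))
        next
      }
      rows[[length(rows) + 1]] <- tibble(
        participant = d$participant[1], region = d$region[1],
        fold = dr$fold[1], pair = paste(p, collapse = "|"),
        context = dr$task[1],
        vector = dr$pattern[i, , drop = FALSE] - dr$pattern[j, , drop = FALSE])
    }
  }
  if (length(skipped) > 0) {
    warn(paste0("skipped incomplete difference pairs: ",
                paste(skipped, collapse = "; ")))
  }
  list_rbind(rows)
}

task_difference_vectors <- function(d) {
  tasks <- sort(unique(d$task))
  stopifnot(length(tasks) == 2)
  rows <- list(); skipped <- character()
  for (f in sort(unique(d$fold))) {
    df <- dplyr::filter(d, .data$fold == f)
    for (k in sort(unique(d$category))) {
      dk <- dplyr::filter(df, .data$category == k)
      i <- match(tasks[1], dk$task); j <- match(tasks[2], dk$task)
      if (is.na(i) || is.na(j)) {
        skipped <- c(skipped, sprintf("fold %d category %s", f, k))
        next
      }
      rows[[length(rows) + 1]] <- tibble(
        participant = d$participant[1], region = d$region[1],
        fold = f, pair = paste(tasks, collapse = "|"), context = k,
        vector = dk$pattern[i, , drop = FALSE] - dk$pattern[j, , drop = FALSE])
    }
  }
  if (length(skipped) > 0) {
    warn(paste0("skipped incomplete difference pairs: ",
                paste(skipped, collapse = "; ")))
  }
  list_rbind(rows)
}

# decode the context labels of one participant's difference vectors:
# per differencing pair, run-respecting CV over folds, averaged over pairs.
# For task-differencing vectors the contexts are categories, so context
# labels are compared pairwise.
decode_difference_set <- function(dv, spec, permute_training = FALSE) {
  contexts <- sort(unique(dv$context))
  results <- list()
  if (length(contexts) == 2) {
    for (p in sort(unique(dv$pair))) {
      dp <- dplyr::filter(dv, .data$pair == p)
      results[[length(results) + 1]] <-
        decode_over_folds(dp$vector, dp$context, dp$fold, spec,
                          permute_training = permute_training)
    }
  } else {
    ctx_pairs <- combn(contexts, 2, simplify = FALSE)
    for (cp in ctx_pairs) {
      dp <- dplyr::filter(dv, .data$context %in% cp)
      results[[length(results) + 1]] <-
        decode_over_folds(dp$vector, dp$context, dp$fold, spec,
                          permute_training = permute_training)
    }
  }
  sum_counts(results)
}

#' Pattern difference decoding: the multivariate interaction test
#'
#' Tests whether a systematic "difference in differences" is present in the
#' joint code for category and task. Between-category difference vectors are
#' classified by task, and between-task difference vectors are classified by
#' category (pairwise); the two directions test the same interaction effect
#' and their accuracies are averaged. Chance is 0.5; above-chance accuracy
#' indicates nonlinear mixed selectivity, i.e. the category code is not a
#' fixed pattern offset across tasks.
#'
#' @param data a pattern tibble covering both tasks (z-normalize beta
#'   patterns first; the constructed toy fixtures are analyzed raw).
#' @param spec a [decoding_spec()].
#' @return tibble per participant: `accuracy` (direction average),
#'   per-direction accuracies, and pooled correct counts (the input for
#'   [posterior_odds()]).
#' @export
pattern_difference_decoding <- function(data, spec = NULL) {
  spec <- as_decoding_spec(spec)
  map_participants(data, function(d) {
    dv1 <- difference_vectors(d, "category")
    dv2 <- difference_vectors(d, "task")
    pdd_from_vectors(dv1, dv2, spec)
  })
}

pdd_from_vectors <- function(dv1, dv2, spec, permute_training = FALSE) {
  r1 <- decode_difference_set(dv1, spec, permute_training)
  r2 <- decode_difference_set(dv2, spec, permute_training)
  tibble(participant = dv1$participant[1], region = dv1$region[1],
         accuracy = (r1$accuracy + r2$accuracy) / 2,
         acc_category_differences = r1$accuracy,
         acc_task_differences = r2$accuracy,
         n_correct = r1$n_correct + r2$n_correct,
         n_total = r1$n_total + r2$n_total)
}

#' Correlation between the two analysis directions across participants
#'
#' The two directions of the interaction test (category differences across
#' tasks, task differences across categories) measure the same effect; a
#' high across-participant correlation justifies averaging them.
#'
#' @param accuracy_direction1,accuracy_direction2 numeric vectors, one value
#'   per participant.
#' @return Pearson r.
#' @export
direction_correlation <- function(accuracy_direction1, accuracy_direction2) {
  stopifnot(length(accuracy_direction1) == length(accuracy_direction2))
  if (length(accuracy_direction1) < 3) abort("need at least 3 participants")
  if (sd(accuracy_direction1) == 0 || sd(accuracy_direction2) == 0) {
    abort("zero variance in a direction's accuracies")
  }
  cor(accuracy_direction1, accuracy_direction2)
}

#' Cross-decoding generalization ratio
#'
#' Compares between-context decoding with within-context decoding on a scale
#' where 1 means perfect generalization and values below 1 a cross-decoding
#' drop. `"subtract_half"` forms `(between - .5) / (within - .5)` (chance is
#' subtracted from both quantities); `"probit"` forms
#' `qnorm(between) / qnorm(within)`, a ratio on the probit scale where chance
#' maps to 0 so no baseline subtraction is needed.
#'
#' Participants whose within-context accuracy does not exceed chance have no
#' defined ratio: they yield `NA` with a warning rather than being silently
#' dropped.
#'
#' @param within,between decoding accuracies in (0, 1), vectorized.
#' @param transform `"subtract_half"` or `"probit"`.
#' @return numeric vector of ratios.
#' @export
cross_decoding_ratio <- function(within, between,
                                 transform = c("subtract_half", "probit")) {
  transform <- match.arg(transform)
  stopifnot(length(within) == length(between))
  bad <- within <= CHANCE
  if (any(bad)) {
    warn(sprintf(
      "within-context accuracy <= .5 for %d participant(s); ratio undefined, set to NA (indices: %s)",
      sum(bad), paste(which(bad), collapse = ", ")))
  }
  out <- if (transform == "subtract_half") {
    (between - CHANCE) / (within - CHANCE)
  } else {
    if (any(within >= 1 | within <= 0 | between >= 1 | between <= 0)) {
      abort("probit transform needs accuracies strictly inside (0, 1)")
    }
    qnorm(between) / qnorm(within)
  }
  out[bad] <- NA_real_
  out
}

#' Per-participant permutation test for pattern difference decoding
#'
#' Builds the null distribution by shuffling the training labels of the
#' difference vectors immediately before classifier training (within each
#' training set, independently per fold and iteration), recomputing the full
#' two-direction decoding accuracy each time. The p-value is the proportion
#' of permuted iterations with an accuracy strictly higher than the observed
#' one; `correction = "add_one"` gives the (1 + b) / (1 + n_perm) variant
#' that is bounded away from zero.
#'
#' @inheritParams pattern_difference_decoding
#' @param n_perm number of label permutations (the reference analysis uses
#'   1000).
#' @param seed integer seed; permutations are reproducible per participant.
#' @param correction `"none"` (strict proportion-higher rule) or
#'   `"add_one"`.
#' @return tibble per participant: `observed`, `p_value`, `n_perm`.
#' @export
pdd_permutation_test <- function(data, spec = NULL, n_perm = 1000, seed = 1,
                                 correction = c("none", "add_one")) {
  correction <- match.arg(correction)
  spec <- as_decoding_spec(spec)
  stopifnot(n_perm >= 1)
  parts <- split_participants(data)
  list_rbind(imap(parts, function(d, idx) {
    dv1 <- difference_vectors(d, "category")
    dv2 <- difference_vectors(d, "task")
    observed <- pdd_from_vectors(dv1, dv2, spec)$accuracy
    perm <- with_sim_seed(seed + idx, {
      vapply(seq_len(n_perm), function(i) {
        pdd_from_vectors(dv1, dv2, spec, permute_training = TRUE)$accuracy
      }, numeric(1))
    })
    b <- sum(perm > observed)
    p <- if (correction == "none") b / n_perm else (1 + b) / (1 + n_perm)
    tibble(participant = d$participant[1], region = d$region[1],
           observed = observed, p_value = p, n_perm = n_perm)
  }))
}
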