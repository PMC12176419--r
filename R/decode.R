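#' Classifier and cross-validation contract
#'
#' All decoding in the package uses a linear maximum-margin classifier
#' (a support vector machine with regularization constant `cost`, default 1)
#' on the voxel patterns as given — no voxel selection, no rescaling beyond
#' the caller's per-block z-normalization.
#'
#' Cross-validation folds are defined by runs: leave-one-run-out for analyses
#' within a single task, leave-one-adjacent-run-pair-out for analyses that
#' need both tasks in the training set (each adjacent pair contains one run
#' per task under the alternating task order). Cross-context training uses
#' all-but-one run of the training context by default, rotating, so that the
#' training-set size matches within-context decoding and generalization
#' ratios are not biased by data quantity; set `cross_train_all_runs = TRUE`
#' to train on every run of the training context instead.
#'
#' @param cost positive regularization constant of the linear SVM.
#' @param tie_seed seed for the coin flip that breaks exactly-zero decision
#'   values (reported via a message when it ever happens).
#' @param cross_train_all_runs see above.
#' @return a `decoding_spec` list.
#' @export
decoding_spec <- function(cost = 1, tie_seed = 1L,
                          cross_train_all_runs = FALSE) {
  if (cost <= 0) abort("cost must be positive")
  structure(list(cost = cost, tie_seed = as.integer(tie_seed),
                 cross_train_all_runs = isTRUE(cross_train_all_runs)),
            class = "decoding_spec")
}

as_decoding_spec <- function(spec) {
  if (is.null(spec)) decoding_spec() else {
    stopifnot(inherits(spec, "decoding_spec")); spec
  }
}

# fit a two-class linear SVM and return predicted labels for test_x
svm_classify <- function(train_x, train_y, test_x, spec) {
  lev <- sort(unique(train_y))
  if (length(lev) != 2) {
    abort("training fold does not contain both classes")
  }
  fit <- e1071::svm(x = train_x, y = factor(train_y, levels = lev),
                    kernel = "linear", cost = spec$cost, scale = FALSE,
                    type = "C-classification")
  pred <- predict(fit, test_x, decision.values = TRUE)
  dv <- drop(attr(pred, "decision.values"))
  pred <- as.character(pred)
  ties <- which(dv == 0)
  if (length(ties) > 0) {
    inform(sprintf("%d zero decision value(s); tie broken by seeded coin flip",
                   length(ties)))
    pred[ties] <- with_sim_seed(spec$tie_seed,
                                sample(lev, length(ties), replace = TRUE))
  }
  pred
}

# generic fold loop: rows of x are observations, y their labels, fold the
# held-out grouping. Training and test rows never share a fold. Optionally
# permutes the training labels within each training set (for null
# distributions). Returns mean held-out fold accuracy plus correct counts.
decode_over_folds <- function(x, y, fold, spec, permute_training = FALSE) {
  folds <- sort(unique(fold))
  if (length(folds) < 2) abort("need at least 2 cross-validation folds")
  acc <- numeric(length(folds))
  n_correct <- 0L; n_total <- 0L
  for (i in seq_along(folds)) {
    tr <- fold != folds[i]
    y_tr <- y[tr]
    if (permute_training) y_tr <- sample(y_tr)
    pred <- svm_classify(x[tr, , drop = FALSE], y_tr,
                         x[!tr, , drop = FALSE], spec)
    ok <- pred == y[!tr]
    acc[i] <- mean(ok)
    n_correct <- n_correct + sum(ok)
    n_total <- n_total + length(ok)
  }
  list(accuracy = mean(acc), n_correct = n_correct, n_total = n_total)
}

# map an analysis over (participant, region) groups, binding row results
map_participants <- function(data, f) {
  validate_pattern_data(data)
  list_rbind(map(split_participants(data), f))
}

sum_counts <- function(results) {
  list(accuracy = mean(map_dbl(results, "accuracy")),
       n_correct = sum(map_dbl(results, "n_correct")),
       n_total = sum(map_dbl(results, "n_total")))
}

category_pairs <- function(cats) {
  cats <- sort(unique(cats))
  combn(cats, 2, simplify = FALSE)
}

#' Pairwise decoding of two conditions
#'
#' Decodes one pair of category labels within one task (leave-one-run-out) or
#' — when `task` is `NULL` and the pair mixes tasks via `condition = "task"` —
#' one pair of task labels within one category (leave-one-adjacent-run-pair-
#' out). Returns one row per participant with the mean held-out accuracy and
#' the underlying correct counts.
#'
#' @param data a pattern tibble (typically z-normalized).
#' @param pair character vector of two category labels.
#' @param task the task to decode within (for category pairs).
#' @param spec a [decoding_spec()].
#' @return tibble with `participant`, `region`, `accuracy`, `n_correct`,
#'   `n_total`.
#' @export
pairwise_decode <- function(data, pair, task = NULL, spec = NULL) {
  spec <- as_decoding_spec(spec)
  stopifnot(length(pair) == 2)
  map_participants(data, function(d) {
    res <- decode_category_pair(d, pair, task, spec)
    tibble(participant = d$participant[1], region = d$region[1],
           accuracy = res$accuracy, n_correct = res$n_correct,
           n_total = res$n_total)
  })
}

decode_category_pair <- function(d, pair, task, spec) {
  if (!is.null(task)) d <- filter_blocks(d, .data$task == !!task)
  d <- dplyr::filter(d, .data$category %in% pair)
  if (!all(pair %in% d$category)) {
    abort(sprintf("condition(s) absent: %s",
                  paste(setdiff(pair, d$category), collapse = ", ")))
  }
  decode_over_folds(d$pattern, d$category, d$run, spec)
}

#' Mean pairwise category decoding within each task
#'
#' For every pair of categories, decodes the pair within each task with
#' leave-one-run-out cross-validation and averages the pairwise accuracies
#' (28 pairs for 8 categories), separately per task.
#'
#' @inheritParams pairwise_decode
#' @return tibble with one row per participant x task.
#' @export
category_decoding <- function(data, spec = NULL) {
  spec <- as_decoding_spec(spec)
  map_participants(data, function(d) {
    pairs <- category_pairs(d$category)
    list_rbind(map(sort(unique(d$task)), function(tk) {
      res <- sum_counts(map(pairs, function(p) {
        decode_category_pair(d, p, tk, spec)
      }))
      tibble(participant = d$participant[1], region = d$region[1], task = tk,
             accuracy = res$accuracy, n_correct = res$n_correct,
             n_total = res$n_total)
    }))
  })
}

#' Mean task decoding within each category
#'
#' Decodes the two task labels among blocks of a single category with
#' leave-one-adjacent-run-pair-out cross-validation, then averages over
#' categories.
#'
#' @inheritParams pairwise_decode
#' @return tibble with one row per participant.
#' @export
task_decoding <- function(data, spec = NULL) {
  spec <- as_decoding_spec(spec)
  map_participants(data, function(d) {
    folds <- adjacent_pair_folds(d)
    d <- left_join(d, folds, by = "run")
    res <- sum_counts(map(sort(unique(d$category)), function(k) {
      dk <- dplyr::filter(d, .data$category == k)
      decode_over_folds(dk$pattern, dk$task, dk$fold, spec)
    }))
    tibble(participant = d$participant[1], region = d$region[1],
           accuracy = res$accuracy, n_correct = res$n_correct,
           n_total = res$n_total)
  })
}

# cross-context decoding of one category pair: train within train_task,
# test on the same pair in test_task; averaged over both directions.
cross_decode_category_pair <- function(d, pair, spec) {
  tasks <- sort(unique(d$task))
  stopifnot(length(tasks) == 2)
  dp <- dplyr::filter(d, .data$category %in% pair)
  dir_acc <- map_dbl(1:2, function(i) {
    train_task <- tasks[i]; test_task <- tasks[3 - i]
    tr <- dplyr::filter(dp, .data$task == train_task)
    te <- dplyr::filter(dp, .data$task == test_task)
    if (spec$cross_train_all_runs) {
      pred <- svm_classify(tr$pattern, tr$category, te$pattern, spec)
      return(mean(pred == te$category))
    }
    runs <- sort(unique(tr$run))
    mean(map_dbl(runs, function(r) {
      use <- tr$run != r
      pred <- svm_classify(tr$pattern[use, , drop = FALSE], tr$category[use],
                           te$pattern, spec)
      mean(pred == te$category)
    }))
  })
  mean(dir_acc)
}

# cross-context decoding of task for one ordered category direction:
# train task discrimination on category `train_cat`, test on `test_cat`.
cross_decode_task_direction <- function(d, train_cat, test_cat, spec) {
  folds <- adjacent_pair_folds(d)
  d <- left_join(d, folds, by = "run")
  tr <- dplyr::filter(d, .data$category == train_cat)
  te <- dplyr::filter(d, .data$category == test_cat)
  if (spec$cross_train_all_runs) {
    pred <- svm_classify(tr$pattern, tr$task, te$pattern, spec)
    return(mean(pred == te$task))
  }
  mean(map_dbl(sort(unique(tr$fold)), function(f) {
    use <- tr$fold != f
    pred <- svm_classify(tr$pattern[use, , drop = FALSE], tr$task[use],
                         te$pattern, spec)
    mean(pred == te$task)
  }))
}

#' Cross-context decoding
#'
#' Trains a classifier under one value of a context variable and tests it
#' under the other, averaging over both train/test directions. For
#' `decode = "category"`, the classifier discriminates a category pair
#' trained in one task and tested on the other task; for `decode = "task"`,
#' it discriminates the two tasks trained on one category and tested on a
#' different category. By default training rotates over all-but-one run (or
#' run pair) of the training context so training-set size matches the
#' within-context analyses; the held-out context is tested in full.
#'
#' @inheritParams pairwise_decode
#' @param decode `"category"` or `"task"` — the variable the classifier must
#'   discriminate; the other variable is the generalization context.
#' @param pair two labels of `decode`'s context partner: a category pair.
#' @return tibble with one row per participant.
#' @export
cross_decode <- function(data, pair, decode = c("category", "task"),
                         spec = NULL) {
  decode <- match.arg(decode)
  spec <- as_decoding_spec(spec)
  stopifnot(length(pair) == 2)
  map_participants(data, function(d) {
    acc <- if (decode == "category") {
      cross_decode_category_pair(d, pair, spec)
    } else {
      mean(c(cross_decode_task_direction(d, pair[1], pair[2], spec),
             cross_decode_task_direction(d, pair[2], pair[1], spec)))
    }
    tibble(participant = d$participant[1], region = d$region[1],
           accuracy = acc)
  })
}

#' Mean category cross-decoding over all category pairs
#'
#' @inheritParams pairwise_decode
#' @return tibble with one row per participant.
#' @export
category_cross_decoding <- function(data, spec = NULL) {
  spec <- as_decoding_spec(spec)
  map_participants(data, function(d) {
    pairs <- category_pairs(d$category)
    tibble(participant = d$participant[1], region = d$region[1],
           accuracy = mean(map_dbl(pairs, function(p) {
             cross_decode_category_pair(d, p, spec)
           })))
  })
}

#' Mean task cross-decoding over all ordered category pairs
#'
#' @inheritParams pairwise_decode
#' @return tibble with one row per participant.
#' @export
task_cross_decoding <- function(data, spec = NULL) {
  spec <- as_decoding_spec(spec)
  map_participants(data, function(d) {
    pairs <- category_pairs(d$category)
    acc <- mean(map_dbl(pairs, function(p) {
      mean(c(cross_decode_task_direction(d, p[1], p[2], spec),
             cross_decode_task_direction(d, p[2], p[1], spec)))
    }))
    tibble(participant = d$participant[1], region = d$region[1],
           accuracy = acc)
  })
}

#' Pairwise accuracies among all category-by-task conditions
#'
#' Computes the decoding accuracy for every pair of the
#' `n_categories x 2` block conditions (120 pairs for 8 categories). Pairs
#' within one task use leave-one-run-out cross-validation; pairs spanning the
#' two tasks use leave-one-adjacent-run-pair-out. This is the input for the
#' condition dissimilarity matrix.
#'
#' @inheritParams pairwise_decode
#' @return long tibble: `participant`, `region`, `cond_a`, `cond_b`
#'   (labels `"category:task"`), `accuracy`.
#' @export
condition_pairwise_accuracies <- function(data, spec = NULL) {
  spec <- as_decoding_spec(spec)
  map_participants(data, function(d) {
    folds <- adjacent_pair_folds(d)
    d <- left_join(d, folds, by = "run")
    d$condition <- paste(d$category, d$task, sep = ":")
    conds <- sort(unique(d$condition))
    prs <- combn(conds, 2, simplify = FALSE)
    list_rbind(map(prs, function(p) {
      dp <- dplyr::filter(d, .data$condition %in% p)
      same_task <- length(unique(dp$task)) == 1
      fold <- if (same_task) dp$run else dp$fold
      res <- decode_over_folds(dp$pattern, dp$condition, fold, spec)
      tibble(participant = d$participant[1], region = d$region[1],
             cond_a = p[1], cond_b = p[2], accuracy = res$accuracy)
    }))
  })
}

#' Pairwise category decoding accuracies within each task
#'
#' The 28-per-task pairwise accuracies underlying category similarity
#' vectors and per-task dissimilarity matrices.
#'
#' @inheritParams pairwise_decode
#' @return long tibble: `participant`, `region`, `task`, `cat_a`, `cat_b`,
#'   `accuracy`.
#' @export
category_pair_accuracies <- function(data, spec = NULL) {
  spec <- as_decoding_spec(spec)
  map_participants(data, function(d) {
    pairs <- category_pairs(d$category)
    list_rbind(map(sort(unique(d$task)), function(tk) {
      list_rbind(map(pairs, function(p) {
        res <- decode_category_pair(d, p, tk, spec)
        tibble(participant = d$participant[1], region = d$region[1],
               task = tk, cat_a = p[1], cat_b = p[2],
               accuracy = res$accuracy)
      }))
    }))
  })
}
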