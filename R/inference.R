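#' One-sample and paired t-tests with explicit tails
#'
#' Thin wrappers over [stats::t.test()] returning tidy one-row tibbles.
#' One-tailed tests are used when only one direction of an effect is
#' meaningful (e.g. decoding above chance, a cross-decoding drop);
#' two-tailed tests when either direction would be of interest.
#'
#' @param values,a,b numeric vectors (per-participant statistics).
#' @param mu0 null value.
#' @param tail `"two"`, `"greater"` or `"less"` (direction of the
#'   alternative).
#' @return tibble: `statistic`, `df`, `p_value`, `tail`.
#' @export
one_sample_t <- function(values, mu0 = 0.5, tail = c("two", "greater",
                                                     "less")) {
  tail <- match.arg(tail)
  if (length(values) < 2) abort("need at least 2 values")
  if (sd(values) == 0) abort("zero variance; t statistic undefined")
  alt <- switch(tail, two = "two.sided", greater = "greater", less = "less")
  tt <- t.test(values, mu = mu0, alternative = alt)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, tail = tail)
}

#' @rdname one_sample_t
#' @export
paired_t <- function(a, b, tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  stopifnot(length(a) == length(b))
  d <- a - b
  if (length(d) < 2) abort("need at least 2 pairs")
  if (all(d == 0)) {
    # degenerate identical inputs: t = 0 by convention
    return(tibble(statistic = 0, df = length(d) - 1,
                  p_value = 1, tail = tail))
  }
  one_sample_t(d, mu0 = 0, tail = tail)
}

#' Benjamini–Hochberg rejection mask
#'
#' Step-up false-discovery-rate control: rejects the hypotheses with the
#' `k` smallest p-values, where `k` is the largest index with
#' `p_(k) <= k * q / m`.
#'
#' @param p_values numeric vector in [0, 1].
#' @param q target false discovery rate.
#' @return logical rejection mask aligned with `p_values`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  p.adjust(p_values, method = "BH") <= q
}

significance_marks <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
      labels = c("***", "**", "*", "†", ""))
}

# the canonical per-region test family: name, which columns feed it, tail
ledger_tests <- function() {
  tribble_names <- c("test", "type", "lhs", "rhs", "mu0", "tail", "label")
  rows <- list(
    list("category_oddball_vs_chance", "one", "category_acc_oddball", NA, 0.5,
         "greater", "category decoding (Oddball) vs chance"),
    list("category_oneback_vs_chance", "one", "category_acc_oneback", NA, 0.5,
         "greater", "category decoding (Oneback) vs chance"),
    list("category_oddball_vs_oneback", "paired", "category_acc_oddball",
         "category_acc_oneback", NA, "two",
         "category decoding: Oddball vs Oneback"),
    list("category_overall_vs_chance", "one", "category_acc_overall", NA, 0.5,
         "greater", "overall category decoding vs chance"),
    list("task_vs_chance", "one", "task_acc", NA, 0.5, "greater",
         "task decoding vs chance"),
    list("category_vs_task", "paired", "category_acc_overall", "task_acc", NA,
         "two", "category vs task decoding"),
    list("category_cross_vs_chance", "one", "category_cross_acc", NA, 0.5,
         "greater", "category cross-decoding vs chance"),
    list("category_within_vs_cross", "paired", "category_acc_overall",
         "category_cross_acc", NA, "greater",
         "category cross-decoding drop"),
    list("cross_ratio_vs_one", "one", "cross_ratio", NA, 1, "less",
         "cross-decoding ratio vs 1"),
    list("task_cross_vs_chance", "one", "task_cross_acc", NA, 0.5, "greater",
         "task cross-decoding vs chance"),
    list("task_within_vs_cross", "paired", "task_acc", "task_cross_acc", NA,
         "greater", "task cross-decoding drop"),
    list("pattern_difference_vs_chance", "one", "pdd_acc", NA, 0.5, "greater",
         "pattern difference decoding vs chance"))
  out <- as_tibble(do.call(rbind, lapply(rows, function(r) {
    stats::setNames(as.data.frame(r, stringsAsFactors = FALSE), tribble_names)
  })))
  out$mu0 <- as.numeric(out$mu0)
  out
}

#' The 12-test significance ledger for one region
#'
#' Runs the full family of per-region decoding tests — category decoding per
#' task and overall, task decoding, category and task comparisons, both
#' cross-decoding analyses and their drop tests, the cross-decoding ratio,
#' and pattern difference decoding — and applies Benjamini–Hochberg
#' correction across the 12 tests at `q`. Tails follow the direction that is
#' interpretable for each test (one-tailed against chance and for drops;
#' two-tailed for condition comparisons).
#'
#' @param region_results tibble with one row per participant and columns
#'   `category_acc_oddball`, `category_acc_oneback`, `category_acc_overall`,
#'   `task_acc`, `category_cross_acc`, `cross_ratio`, `task_cross_acc`,
#'   `pdd_acc`.
#' @param q false discovery rate for the within-region correction.
#' @return a 12-row tibble: `test`, `label`, `statistic`, `df`, `p_value`,
#'   `tail`, `significant` (BH-corrected), `marks` (uncorrected star
#'   convention, dagger for p < .1).
#' @export
region_test_ledger <- function(region_results, q = 0.05) {
  spec <- ledger_tests()
  needed <- stats::na.omit(unique(c(spec$lhs, spec$rhs)))
  missing_cols <- setdiff(needed, names(region_results))
  if (length(missing_cols) > 0) {
    bad <- spec$label[spec$lhs %in% missing_cols |
                        (!is.na(spec$rhs) & spec$rhs %in% missing_cols)]
    abort(sprintf("%s missing (need column(s): %s)",
                  paste(unique(bad), collapse = "; "),
                  paste(missing_cols, collapse = ", ")))
  }
  rows <- list_rbind(map(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    res <- if (s$type == "one") {
      vals <- region_results[[s$lhs]]
      vals <- vals[!is.na(vals)]   # e.g. undefined cross-decoding ratios
      one_sample_t(vals, mu0 = s$mu0, tail = s$tail)
    } else {
      ok <- !is.na(region_results[[s$lhs]]) & !is.na(region_results[[s$rhs]])
      paired_t(region_results[[s$lhs]][ok], region_results[[s$rhs]][ok],
               tail = s$tail)
    }
    dplyr::bind_cols(tibble(test = s$test, label = s$label), res)
  }))
  rows$significant <- bh_fdr(rows$p_value, q = q)
  rows$marks <- as.character(significance_marks(rows$p_value))
  class(rows) <- c("mixsel_ledger", class(rows))
  rows
}

#' Average per-region statistics into sectors
#'
#' A sector is a fixed group of regions whose *final* per-participant
#' statistics are averaged with equal weight, so that each region
#' contributes equally regardless of size (averaging always happens at the
#' last stage of an analysis — e.g. cross-decoding ratios are averaged, not
#' recomputed from averaged accuracies).
#'
#' @param per_region tibble with columns `participant`, `region`, `value`.
#' @param sectors named list mapping sector id to a character vector of
#'   region ids; a region may belong to at most one sector.
#' @return tibble: `participant`, `sector`, `value`.
#' @export
sector_aggregate <- function(per_region, sectors) {
  stopifnot(all(c("participant", "region", "value") %in% names(per_region)))
  if (length(sectors) == 0 || any(lengths(sectors) == 0)) {
    abort("sectors must be non-empty region lists")
  }
  all_members <- unlist(sectors)
  if (anyDuplicated(all_members) > 0) {
    abort("a region may belong to at most one sector")
  }
  list_rbind(imap(sectors, function(members, sector_id) {
    list_rbind(map(sort(unique(per_region$participant)), function(p) {
      sub <- dplyr::filter(per_region, .data$participant == p,
                           .data$region %in% members)
      if (!setequal(sub$region, members)) {
        abort(sprintf("participant %s missing region(s) %s for sector %s", p,
                      paste(setdiff(members, sub$region), collapse = ", "),
                      sector_id))
      }
      tibble(participant = p, sector = sector_id, value = mean(sub$value))
    }))
  }))
}
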