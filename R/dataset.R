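#' Construct a block-wise pattern dataset
#'
#' A pattern dataset holds the block-wise voxel activity estimates ("betas")
#' for one or more participants in one region, together with the per-block
#' design labels. It is an ordinary tibble with one row per block and a matrix
#' column `pattern` (blocks x voxels), so it composes with dplyr verbs.
#'
#' Design invariants enforced here: every run carries exactly one task, a
#' category occurs at most once per run, the voxel count is constant, and no
#' label is missing. Tasks and categories must be character (integer codes are
#' rejected to prevent silent misalignment between label and array files).
#'
#' @param labels data frame with columns `participant`, `region`, `run`,
#'   `task`, `category`, `block_position`.
#' @param betas numeric matrix, one row per label row, columns are voxels.
#' @return a `pattern_data` tibble.
#' @export
pattern_data <- function(labels, betas) {
  labels <- as_tibble(labels)
  required <- c("participant", "region", "run", "task", "category",
                "block_position")
  missing_cols <- setdiff(required, names(labels))
  if (length(missing_cols) > 0) {
    abort(paste0("labels are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  betas <- as.matrix(betas)
  storage.mode(betas) <- "double"
  if (nrow(betas) != nrow(labels)) {
    abort(sprintf(
      "label/array row mismatch: %d label rows but %d pattern rows",
      nrow(labels), nrow(betas)))
  }
  if (!is.character(labels$task) || !is.character(labels$category)) {
    abort("task and category must be character labels, not numeric codes")
  }
  dat <- labels[required]
  dat$run <- as.integer(dat$run)
  dat$block_position <- as.integer(dat$block_position)
  dat$pattern <- betas
  dat <- as_tibble(dat)
  validate_pattern_data(dat)
  dat
}

#' Validate the structural invariants of a pattern dataset
#'
#' @param data a pattern tibble as built by [pattern_data()].
#' @return `data`, invisibly, after checking invariants.
#' @export
validate_pattern_data <- function(data) {
  required <- c("participant", "region", "run", "task", "category",
                "block_position", "pattern")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("pattern data missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.matrix(data$pattern)) abort("`pattern` must be a matrix column")
  lab <- data[c("participant", "region", "run", "task", "category",
                "block_position")]
  if (anyNA(lab)) abort("missing values in block labels")
  if (anyNA(data$pattern)) abort("missing values in beta patterns")
  if (ncol(data$pattern) < 2) abort("need at least 2 voxels")

  per_pr <- dplyr::group_split(group_by(data, .data$participant, .data$region))
  for (d in per_pr) {
    tasks_per_run <- tapply(d$task, d$run, function(x) length(unique(x)))
    if (any(tasks_per_run > 1)) {
      bad <- names(tasks_per_run)[tasks_per_run > 1][1]
      abort(sprintf("run %s carries more than one task (participant %s)",
                    bad, d$participant[1]))
    }
    dup <- duplicated(d[c("run", "category")])
    if (any(dup)) {
      i <- which(dup)[1]
      abort(sprintf(
        "category '%s' appears more than once in run %d (participant %s)",
        d$category[i], d$run[i], d$participant[1]))
    }
  }
  invisible(data)
}

#' Z-normalize each block across voxels
#'
#' Each block (row of the pattern matrix) is centered and scaled to mean 0 and
#' sample standard deviation 1 (divisor n - 1) across its voxels. This removes
#' per-block additive and multiplicative amplitude confounds before decoding;
#' it is idempotent, so already-normalized data pass through unchanged.
#'
#' @param data a pattern tibble.
#' @return the tibble with normalized `pattern` rows; labels untouched.
#' @export
znormalize_blocks <- function(data) {
  validate_pattern_data(data)
  p <- data$pattern
  m <- rowMeans(p)
  centered <- p - m
  s <- sqrt(rowSums(centered^2) / (ncol(p) - 1))
  if (any(s == 0)) {
    i <- which(s == 0)[1]
    abort(sprintf(
      "block with zero voxel variance (participant %s, run %d, category %s)",
      data$participant[i], data$run[i], data$category[i]))
  }
  data$pattern <- centered / s
  data
}

#' Subset blocks by a label predicate
#'
#' Thin wrapper around [dplyr::filter()] that refuses to return an empty
#' dataset, so downstream analyses fail at the selection step rather than
#' deep inside a fold loop.
#'
#' @param data a pattern tibble.
#' @param ... predicates on the label columns, as in `dplyr::filter()`.
#' @return the filtered pattern tibble.
#' @export
filter_blocks <- function(data, ...) {
  out <- dplyr::filter(data, ...)
  if (nrow(out) == 0) abort("block selection matched no blocks")
  out
}

#' Read / write a pattern dataset as paired text files
#'
#' Labels travel as a CSV with header (participant, region, run, task,
#' category, block_position); the beta array travels as a headerless CSV
#' matrix whose row order equals the label row order.
#'
#' @param label_path path to the label CSV.
#' @param array_path path to the beta matrix CSV.
#' @return `read_pattern_data()` returns a pattern tibble;
#'   `write_pattern_data()` returns the paths invisibly.
#' @export
read_pattern_data <- function(label_path, array_path) {
  for (p in c(label_path, array_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  labels <- readr::read_csv(
    label_path,
    col_types = readr::cols(
      participant = readr::col_character(),
      region = readr::col_character(),
      run = readr::col_integer(),
      task = readr::col_character(),
      category = readr::col_character(),
      block_position = readr::col_integer()
    ))
  betas <- as.matrix(readr::read_csv(
    array_path, col_names = FALSE, col_types = readr::cols(
      .default = readr::col_double())))
  dimnames(betas) <- NULL
  pattern_data(labels, betas)
}

#' @param data a pattern tibble.
#' @rdname read_pattern_data
#' @export
write_pattern_data <- function(data, label_path, array_path) {
  validate_pattern_data(data)
  for (p in c(label_path, array_path)) {
    if (!dir.exists(dirname(p))) {
      abort(sprintf("directory does not exist: %s", dirname(p)))
    }
  }
  labels <- data[c("participant", "region", "run", "task", "category",
                   "block_position")]
  readr::write_csv(labels, label_path)
  # fixed 17-digit formatting keeps writes byte-identical and round-trips
  # doubles exactly
  m <- format(data$pattern, digits = 17, scientific = TRUE, trim = TRUE)
  lines <- apply(m, 1, paste, collapse = ",")
  writeLines(lines, array_path)
  invisible(c(label_path, array_path))
}

# ---- internal label helpers ------------------------------------------------

# run -> task lookup for one participant's data
run_task_table <- function(data) {
  distinct(data[c("run", "task")]) |> arrange(.data$run)
}

# adjacent run pairs (1,2), (3,4), ...; with the alternating-with-repeat task
# order each pair contains one run of each task. Returns tibble(run, fold).
adjacent_pair_folds <- function(data, require_both_tasks = TRUE) {
  rt <- run_task_table(data)
  if (nrow(rt) %% 2 != 0) {
    abort("adjacent-pair cross-validation needs an even number of runs")
  }
  rt$fold <- rep(seq_len(nrow(rt) / 2), each = 2)
  if (require_both_tasks) {
    per_fold <- tapply(rt$task, rt$fold, function(x) length(unique(x)))
    if (any(per_fold != 2)) {
      abort("an adjacent run pair does not contain both tasks")
    }
  }
  rt[c("run", "fold")]
}

split_participants <- function(data) {
  dplyr::group_split(group_by(data, .data$participant, .data$region))
}
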