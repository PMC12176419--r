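#' Configuration for the synthetic pattern generator
#'
#' Describes a factorial (category x task) block design with known tuning
#' structure. The defaults mirror the design this package targets: 13
#' participants, 2 tasks (Oddball / Oneback) of 10 runs each, tasks
#' alternating run by run except for a repeat at the session midpoint, and 8
#' analyzed category blocks per run.
#'
#' `geometry_mode` selects how task context modulates the category code:
#' \describe{
#'   \item{additive}{category and task contribute independent pattern
#'     components; no interaction. `interaction_gain` must be 0.}
#'   \item{rotation}{task 2 category templates are a distance-preserving
#'     planar rotation (angle `interaction_gain`, radians, within the span of
#'     the category templates) of the task 1 templates: an interaction is
#'     present but the representational geometry is unchanged.}
#'   \item{reshape}{category k's template is scaled by `1 + interaction_gain *
#'     l_k` in task 2, with `l_k` a fixed linear grid on [-1, 1]: the pairwise
#'     distance profile itself changes between tasks.}
#'   \item{oblique}{additive, but the between-task shift has a component
#'     along the difference axis of the first and last categories of 1.5
#'     times that pair's half separation, so a max-margin boundary trained
#'     on that pair in one task misclassifies in the other despite purely
#'     additive coding. `interaction_gain` must be 0.}
#' }
#'
#' When `normalize_additivity_domain = "znormed"` (the default) the code is
#' calibrated to the z-scored analysis space: all templates are centered,
#' category templates are normalized to exactly equal norms, task templates
#' are orthogonalized against every category template and equalized in norm,
#' and the i.i.d. voxel noise variance is set so each block has unit variance
#' in expectation. Equal condition norms make the per-block z-normalization
#' statistically neutral (its scale does not depend on condition), so the
#' additive null holds in the analyzed space. In this domain `noise_sd` is
#' ignored — noise fills whatever share of the unit block variance the
#' templates do not occupy, and the gains are template standard deviations as
#' fractions of total block variation.
#'
#' `interaction_gain` may be a single value or one value per participant
#' (a graded cohort).
#'
#' @param n_participants,n_runs_per_task,n_categories,n_tasks,n_voxels design
#'   counts. `n_runs_per_task` must be even so that adjacent run pairs each
#'   contain one run per task; `n_tasks` must be 2.
#' @param category_gain,task_gain per-voxel standard deviation of the shared
#'   category / task template components.
#' @param interaction_gain the nonlinear-mixed-selectivity dial (see above).
#' @param geometry_mode one of "additive", "rotation", "reshape", "oblique".
#' @param noise_sd i.i.d. Gaussian voxel noise (raw domain only).
#' @param normalize_additivity_domain "znormed" or "raw".
#' @param participant_jitter participant-level template deviation, as a
#'   fraction of the corresponding gain; controls the across-participant
#'   reliability (noise ceiling) of the representational geometry.
#' @param seed integer seed; identical config + seed gives an identical
#'   cohort.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_participants = 13, n_runs_per_task = 10,
                       n_categories = 8, n_tasks = 2, n_voxels = 100,
                       category_gain = 0.33, task_gain = 0.12,
                       interaction_gain = 0,
                       geometry_mode = c("additive", "rotation", "reshape",
                                         "oblique"),
                       noise_sd = 1,
                       normalize_additivity_domain = c("znormed", "raw"),
                       participant_jitter = 0.15, seed = 1) {
  geometry_mode <- match.arg(geometry_mode)
  normalize_additivity_domain <- match.arg(normalize_additivity_domain)
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_runs_per_task = as.integer(n_runs_per_task),
    n_categories = as.integer(n_categories),
    n_tasks = as.integer(n_tasks),
    n_voxels = as.integer(n_voxels),
    category_gain = category_gain, task_gain = task_gain,
    interaction_gain = interaction_gain, geometry_mode = geometry_mode,
    noise_sd = noise_sd,
    normalize_additivity_domain = normalize_additivity_domain,
    participant_jitter = participant_jitter, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_categories < 2) abort("need at least 2 categories")
  if (cfg$n_tasks != 2) abort("the design has exactly 2 tasks")
  if (cfg$n_voxels < cfg$n_categories + 4) {
    abort("n_voxels must exceed n_categories + 3 (template orthogonalization)")
  }
  if (cfg$n_runs_per_task < 2 || cfg$n_runs_per_task %% 2 != 0) {
    abort("n_runs_per_task must be an even number >= 2")
  }
  if (any(c(cfg$category_gain, cfg$task_gain, cfg$interaction_gain,
            cfg$noise_sd) < 0)) {
    abort("gains and noise_sd must be nonnegative")
  }
  if (!length(cfg$interaction_gain) %in% c(1L, cfg$n_participants)) {
    abort("interaction_gain must have length 1 or n_participants")
  }
  if (cfg$geometry_mode %in% c("additive", "oblique") &&
      any(cfg$interaction_gain != 0)) {
    abort(sprintf("interaction_gain must be 0 in %s mode", cfg$geometry_mode))
  }
  invisible(cfg)
}

task_levels <- function() c("Oddball", "Oneback")

# Task order over the session: alternating, except the two runs at the session
# midpoint share a task, so neither task is on average earlier or later.
run_task_schedule <- function(n_runs_per_task, start_task = "Oddball") {
  tasks <- task_levels()
  other <- function(t) setdiff(tasks, t)
  n_total <- 2L * n_runs_per_task
  out <- character(n_total)
  out[1] <- start_task
  for (i in seq(2L, n_total)) {
    out[i] <- if (i == n_runs_per_task + 1L) out[i - 1] else other(out[i - 1])
  }
  out
}

category_levels <- function(n) sprintf("cat%02d", seq_len(n))

# evaluate with a private RNG stream, restoring the caller's state
with_sim_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

center_rows <- function(m) m - rowMeans(m)

# orthogonalize rows of `m` against the row space of `basis_rows`
orthogonalize_rows <- function(m, basis_rows) {
  q <- qr.Q(qr(t(basis_rows)))
  m - m %*% q %*% t(q)
}

scale_rows_to_norm <- function(m, norm) {
  nr <- sqrt(rowSums(m^2))
  keep <- nr > 0
  m[keep, ] <- m[keep, , drop = FALSE] * (norm / nr[keep])
  m
}

# distance-preserving rotation of the category templates: planar rotations by
# `angle` within the span of the templates themselves
rotate_in_span <- function(templates, angle) {
  if (angle == 0) return(templates)
  e <- qr.Q(qr(t(templates)))              # n_voxels x K orthonormal basis
  k <- ncol(e)
  out <- templates
  for (p in seq_len(k %/% 2)) {
    u <- e[, 2 * p - 1]; v <- e[, 2 * p]
    cu <- templates %*% u; cv <- templates %*% v
    out <- out +
      (cos(angle) - 1) * (cu %*% t(u) + cv %*% t(v)) +
      sin(angle) * (cu %*% t(v) - cv %*% t(u))
  }
  out
}

# Shared category geometry: a hierarchical similarity structure (sibling
# category pairs nested in clusters of four), as object categories show in
# visual cortex. Latent-factor construction guarantees a valid correlation
# structure: rho ~ .9 within a sibling pair, ~ .5 within a cluster, ~ 0
# across clusters. All templates are centered and normalized to exactly
# equal norms: with equal condition norms the analyzed (z-scored) noise
# scale is condition-independent, which is what makes the additive null
# exact — unequal norms would let the interaction test read out
# category-dependent noise magnitude instead of genuine interactions.
shared_category_templates <- function(k, v, gain) {
  supercl <- ceiling(seq_len(k) / 4)
  sibling <- ceiling(seq_len(k) / 2)
  sup_lat <- matrix(rnorm(max(supercl) * v), max(supercl), v)
  sib_lat <- matrix(rnorm(max(sibling) * v), max(sibling), v)
  uni_lat <- matrix(rnorm(k * v), k, v)
  m <- sqrt(0.5) * sup_lat[supercl, , drop = FALSE] +
    sqrt(0.4) * sib_lat[sibling, , drop = FALSE] +
    sqrt(0.1) * uni_lat
  scale_rows_to_norm(center_rows(m), gain * sqrt(v - 1))
}

# noiseless condition means for one participant: K x V matrices per task
participant_templates <- function(cfg, shared_cat, gain_p) {
  v <- cfg$n_voxels
  k <- cfg$n_categories
  jit <- cfg$participant_jitter
  cat_t <- center_rows(shared_cat +
    matrix(rnorm(k * v, 0, jit * cfg$category_gain), k, v))
  # re-equalize norms exactly after participant jitter (see above)
  cat_t <- scale_rows_to_norm(cat_t, cfg$category_gain * sqrt(v - 1))
  # task axes are participant-specific: voxel-level task directions need not
  # align across brains, and a shared task axis would couple with the
  # unit-variance noise geometry to create a spurious task-specific profile
  # component shared across participants
  task_t <- center_rows(matrix(rnorm(2 * v, 0, cfg$task_gain), 2, v))
  # task axes orthogonal to every category-difference axis, equal norms:
  # the between-task shift then carries no category information
  task_t <- orthogonalize_rows(task_t, cat_t)
  task_t <- scale_rows_to_norm(task_t, cfg$task_gain * sqrt(v - 1))

  cat_by_task <- list(cat_t, cat_t)
  if (cfg$geometry_mode == "rotation") {
    cat_by_task[[2]] <- rotate_in_span(cat_t, gain_p)
  } else if (cfg$geometry_mode == "reshape") {
    l <- seq(-1, 1, length.out = k)
    cat_by_task[[2]] <- cat_t * (1 + gain_p * l)
  } else if (cfg$geometry_mode == "oblique") {
    # shift along the axis separating the first and last categories (the
    # best-separated pair under the hierarchical structure), 1.5x that
    # pair's half-separation: their cross-decoding fails geometrically
    d1k <- cat_t[1, ] - cat_t[k, ]
    task_t[2, ] <- task_t[2, ] + 1.5 * (sqrt(sum(d1k^2)) / 2) *
      d1k / sqrt(sum(d1k^2))
  }
  means <- lapply(1:2, function(m) cat_by_task[[m]] + rep(task_t[m, ],
                                                          each = k))
  names(means) <- task_levels()
  means
}

# draw one block: condition mean plus i.i.d. Gaussian noise. In the znormed
# domain the noise variance is calibrated per condition so the block has unit
# voxel variance in expectation (templates are variance shares); together
# with the centered, norm-equalized templates this keeps the per-block
# z-normalization statistically neutral: its random scale depends on the
# condition only through the template norm, which is equalized across tasks.
# A hard per-block norm constraint would instead make the noise anisotropic
# around the condition mean and leak task identity into the noise geometry.
draw_block <- function(mean_vec, cfg) {
  v <- cfg$n_voxels
  if (cfg$normalize_additivity_domain == "raw") {
    return(mean_vec + rnorm(v, 0, cfg$noise_sd))
  }
  resid <- (v - 1) - sum(mean_vec^2)
  if (resid <= 0.05 * (v - 1)) {
    abort("template gains too large for unit-variance blocks; reduce gains")
  }
  mean_vec + rnorm(v, 0, sqrt(resid / v))
}

#' Generate a synthetic cohort of labeled pattern datasets
#'
#' Produces one pattern dataset per simulated participant under the factorial
#' design described in [sim_config()], together with the generative ground
#' truth. Participants share group-level category and task templates (with
#' participant-level jitter), so representational-geometry analyses that rely
#' on across-participant consistency have a nonzero noise ceiling.
#'
#' The generative model is a stand-in: the per-voxel tuning distribution is
#' Gaussian by choice, not derived from any receptive-field model.
#'
#' @param config a [sim_config()].
#' @return a list of class `mixsel_cohort` with elements `data` (a single
#'   pattern tibble covering all participants), `truth` (per-participant
#'   noiseless templates and within-task pairwise distance tables, plus
#'   `interaction_present`), and `config`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  with_sim_seed(cfg$seed, {
    cats <- category_levels(cfg$n_categories)
    gains <- rep(cfg$interaction_gain, length.out = cfg$n_participants)
    shared_cat <- shared_category_templates(cfg$n_categories, cfg$n_voxels,
                                            cfg$category_gain)

    truth <- list(participants = list(),
                  interaction_present =
                    cfg$geometry_mode %in% c("rotation", "reshape") &&
                    any(gains > 0))
    rows <- vector("list", cfg$n_participants)
    for (p in seq_len(cfg$n_participants)) {
      pid <- sprintf("sub%02d", p)
      means <- participant_templates(cfg, shared_cat, gains[p])
      dist_tab <- lapply(means, function(m) {
        d <- as.matrix(dist(m)); dimnames(d) <- list(cats, cats); d
      })
      truth$participants[[pid]] <- list(
        category_templates_per_task = means,
        pairwise_distance_table = dist_tab,
        interaction_gain = gains[p])

      schedule <- run_task_schedule(
        cfg$n_runs_per_task,
        start_task = task_levels()[1 + (p - 1) %% 2])
      run_rows <- vector("list", length(schedule))
      for (r in seq_along(schedule)) {
        task_r <- schedule[r]
        order_r <- sample(cats)
        betas <- t(vapply(order_r, function(k) {
          draw_block(means[[task_r]][match(k, cats), ], cfg)
        }, numeric(cfg$n_voxels)))
        run_rows[[r]] <- tibble(
          participant = pid, region = "simulated", run = r, task = task_r,
          category = order_r, block_position = seq_along(order_r),
          pattern = betas)
      }
      rows[[p]] <- list_rbind(run_rows)
    }
    data <- list_rbind(rows)
    validate_pattern_data(data)
    structure(list(data = data, truth = truth, config = cfg),
              class = "mixsel_cohort")
  })
}

#' @export
print.mixsel_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic cohort: %d participants, %d runs/task, %d categories, %d voxels\n",
    cfg$n_participants, cfg$n_runs_per_task, cfg$n_categories, cfg$n_voxels))
  cat(sprintf("geometry: %s (interaction gain %s), domain: %s, seed %d\n",
              cfg$geometry_mode,
              paste(format(unique(cfg$interaction_gain)), collapse = "/"),
              cfg$normalize_additivity_domain, cfg$seed))
  invisible(x)
}

#' Deterministic two-category toy geometries
#'
#' Four small two-signal-dimension datasets realizing the canonical scenarios
#' relating cross-decoding to interactive coding. Category A and B occupy
#' known planar coordinates per task (unit category separation along the first
#' signal dimension), embedded in `n_voxels` voxels whose remaining dimensions
#' carry only zero-mean noise:
#'
#' \describe{
#'   \item{additive_orthogonal}{task shift orthogonal to the category axis:
#'     cross-decoding matches within-decoding, no interaction signal.}
#'   \item{oblique}{additive but the task shift runs 1.5 units along the
#'     category axis: one test class lands across the trained boundary, so
#'     cross-decoding falls to chance while within-task decoding is perfect
#'     and the interaction signal is still absent.}
#'   \item{interaction_generalizing}{the category difference vector stretches
#'     between tasks but keeps its sign: cross-decoding still succeeds while
#'     the interaction is decodable.}
#'   \item{interaction_reversing}{the category difference vector reverses
#'     between tasks: cross-decoding is below chance and the interaction is
#'     perfectly decodable.}
#' }
#'
#' These fixtures must be analyzed without per-block z-normalization:
#' z-scoring a 2-informative-dimension pattern destroys the constructed
#' geometry.
#'
#' @param n_runs_per_task runs per task (even, >= 8).
#' @param n_voxels total voxels (>= 10).
#' @param noise_sd small i.i.d. noise added to every coordinate.
#' @param seed integer seed.
#' @return named list of four pattern tibbles.
#' @export
scenario_fixtures <- function(n_runs_per_task = 12, n_voxels = 12,
                              noise_sd = 0.05, seed = 7) {
  stopifnot(n_runs_per_task >= 8, n_runs_per_task %% 2 == 0, n_voxels >= 10)
  base <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), NULL))
  task2 <- lapply(list(
    additive_orthogonal = c(0, 1, 1, 1),
    oblique = c(1.5, 1, 2.5, 1),
    interaction_generalizing = c(0, 1, 1.6, 1),
    interaction_reversing = c(1, 1, 0, 1)),
    function(v) matrix(v, 2, 2, byrow = TRUE,
                       dimnames = list(c("A", "B"), NULL)))
  with_sim_seed(seed, {
    out <- lapply(names(task2), function(nm) {
      coords <- list(Oddball = base, Oneback = task2[[nm]])
      schedule <- run_task_schedule(n_runs_per_task)
      rows <- lapply(seq_along(schedule), function(r) {
        task_r <- schedule[r]
        order_r <- sample(c("A", "B"))
        betas <- t(vapply(order_r, function(k) {
          x <- numeric(n_voxels)
          x[1:2] <- coords[[task_r]][k, ]
          x + rnorm(n_voxels, 0, noise_sd)
        }, numeric(n_voxels)))
        tibble(participant = "toy", region = nm, run = r, task = task_r,
               category = order_r, block_position = seq_along(order_r),
               pattern = betas)
      })
      validate_pattern_data(list_rbind(rows))
    })
    names(out) <- names(task2)
    out
  })
}

#' Write / read a simulated cohort as plain-text fixture files
#'
#' Labels and beta arrays go through [write_pattern_data()] (one CSV pair per
#' participant); the ground truth is serialized as JSON. Reading back
#' reproduces labels and arrays exactly.
#'
#' @param cohort a `mixsel_cohort`.
#' @param dir output directory (must exist).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mixsel_cohort"))
  if (!dir.exists(dir)) abort(sprintf("directory does not exist: %s", dir))
  for (d in split_participants(cohort$data)) {
    pid <- d$participant[1]
    write_pattern_data(d, file.path(dir, paste0(pid, "_labels.csv")),
                       file.path(dir, paste0(pid, "_betas.csv")))
  }
  truth <- cohort$truth
  truth$participants <- lapply(truth$participants, function(tp) {
    list(category_templates_per_task =
           lapply(tp$category_templates_per_task, unclass),
         pairwise_distance_table =
           lapply(tp$pairwise_distance_table, unclass),
         interaction_gain = tp$interaction_gain)
  })
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort_data <- function(dir) {
  labels <- sort(list.files(dir, pattern = "_labels\\.csv$",
                            full.names = TRUE))
  if (length(labels) == 0) abort(sprintf("no label files found in %s", dir))
  arrays <- sub("_labels\\.csv$", "_betas.csv", labels)
  list_rbind(map2(labels, arrays, read_pattern_data))
}
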