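# Small shared configurations and hand-built datasets. Everything is built
# in code at test time; sizes are kept small so the whole suite stays fast.

small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_participants = 2, n_runs_per_task = 4, n_categories = 4,
                   n_voxels = 30, seed = 101)
  do.call(sim_config, utils::modifyList(defaults, args))
}

small_cohort <- function(...) simulate_cohort(small_config(...))

# a tiny hand-built two-category dataset: category A at -mu, B at +mu on one
# informative voxel (plus inert voxels), `n_runs` runs per task
toy_two_class <- function(n_runs_per_task = 4, n_voxels = 5, mu = 1,
                          noise_sd = 0, seed = 1) {
  set.seed(seed)
  tasks <- rep(c("Oddball", "Oneback"), n_runs_per_task)
  tasks[n_runs_per_task + 1] <- tasks[n_runs_per_task]
  if (n_runs_per_task %% 2 == 0) {
    tasks <- mixsel:::run_task_schedule(n_runs_per_task)
  }
  rows <- lapply(seq_along(tasks), function(r) {
    betas <- rbind(c(-mu, rep(0, n_voxels - 1)),
                   c(mu, rep(0, n_voxels - 1))) +
      matrix(rnorm(2 * n_voxels, 0, noise_sd), 2)
    tibble::tibble(participant = "p1", region = "toy", run = r,
                   task = tasks[r], category = c("A", "B"),
                   block_position = 1:2, pattern = betas)
  })
  validate_pattern_data(dplyr::bind_rows(rows))
}

expect_tibble_cols <- function(tbl, cols) {
  testthat::expect_s3_class(tbl, "tbl_df")
  testthat::expect_true(all(cols %in% names(tbl)))
}
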