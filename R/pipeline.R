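#' Full analysis pipeline configuration
#'
#' Bundles the simulation recipe, the decoding contract, and the analysis
#' toggles into a single validated object. One `seed` governs every source
#' of randomness: the simulator consumes `seed` and the permutation test a
#' fixed offset of it, so any stage can be re-run independently and two runs
#' with the same config are numerically identical.
#'
#' @param simulation a [sim_config()]; ignored when `input_dir` is given.
#' @param spec a [decoding_spec()].
#' @param input_dir optional directory of fixture files (see
#'   [write_cohort()]) to analyze instead of simulating.
#' @param n_perm permutations for the per-participant interaction test.
#' @param ratio_transform `"subtract_half"` or `"probit"`.
#' @param run_permutation,run_bayes,run_rsa stage toggles.
#' @param q false discovery rate for the significance ledger.
#' @param out_dir optional directory; results are additionally written there
#'   as CSV/JSON.
#' @param seed master seed; overrides `simulation$seed` when supplied.
#' @return a `pipeline_config` list with all defaults materialized.
#' @export
pipeline_config <- function(simulation = sim_config(), spec = decoding_spec(),
                            input_dir = NULL, n_perm = 200,
                            ratio_transform = c("subtract_half", "probit"),
                            run_permutation = TRUE, run_bayes = TRUE,
                            run_rsa = TRUE, q = 0.05, out_dir = NULL,
                            seed = NULL) {
  ratio_transform <- match.arg(ratio_transform)
  if (!is.null(seed)) simulation$seed <- as.integer(seed)
  validate_sim_config(simulation)
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    abort(sprintf("input_dir does not exist: %s", input_dir))
  }
  structure(list(simulation = simulation, spec = spec, input_dir = input_dir,
                 n_perm = as.integer(n_perm),
                 ratio_transform = ratio_transform,
                 run_permutation = isTRUE(run_permutation),
                 run_bayes = isTRUE(run_bayes), run_rsa = isTRUE(run_rsa),
                 q = q, out_dir = out_dir, seed = simulation$seed),
            class = "pipeline_config")
}

#' Run the simulate–decode–interaction–geometry pipeline
#'
#' Executes, in order: data acquisition (simulation or fixture read),
#' per-block z-normalization, category/task decoding, both cross-decoding
#' analyses and the generalization ratio, pattern difference decoding with
#' (optionally) its permutation test and Bayesian group posterior odds,
#' the representational-geometry analyses, and the per-region significance
#' ledger. Deterministic for a fixed config.
#'
#' @param config a [pipeline_config()].
#' @return a `mixsel_results` list; see the elements' own documentation.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- NULL
  if (is.null(config$input_dir)) {
    cohort <- simulate_cohort(config$simulation)
    raw <- cohort$data
  } else {
    raw <- read_cohort_data(config$input_dir)
  }
  dat <- znormalize_blocks(raw)
  spec <- config$spec

  cat_acc <- category_decoding(dat, spec)
  cat_overall <- cat_acc |>
    group_by(.data$participant, .data$region) |>
    summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  task_acc <- task_decoding(dat, spec)
  cat_cross <- category_cross_decoding(dat, spec)
  task_cross <- task_cross_decoding(dat, spec)

  ratio_tbl <- cat_overall |>
    rename(within = "accuracy") |>
    left_join(rename(cat_cross, between = "accuracy"),
              by = c("participant", "region"))
  ratio_tbl$ratio <- cross_decoding_ratio(
    ratio_tbl$within, ratio_tbl$between, transform = config$ratio_transform)

  pdd <- pattern_difference_decoding(dat, spec)

  perm <- NULL
  if (config$run_permutation) {
    perm <- pdd_permutation_test(dat, spec, n_perm = config$n_perm,
                                 seed = config$seed + 100003L)
  }
  odds <- NULL
  if (config$run_bayes) {
    odds <- map(split(pdd, pdd$region), function(g) {
      posterior_odds(g$n_correct, g$n_total)
    })
  }

  rsa <- NULL
  if (config$run_rsa) {
    pair_acc <- category_pair_accuracies(dat, spec)
    sim_vec <- category_similarity_vectors(pair_acc)
    rsa <- list(
      pair_accuracies = pair_acc,
      variance_explained = geometry_variance_explained(sim_vec),
      between_task_r = between_task_rdm_correlation(sim_vec),
      second_order = second_order_rdm(sim_vec))
    cond_acc <- condition_pairwise_accuracies(dat, spec)
    rsa$condition_rdms <- map(split(cond_acc, cond_acc$region), condition_rdm)
    rsa$mds <- map(rsa$condition_rdms,
                   function(r) mds_embed(clip_chance_distances(r)))
    ve_mean <- rsa$variance_explained |>
      group_by(.data$participant, .data$region) |>
      summarise(value = mean(.data$variance_explained), .groups = "drop")
    pdd_acc_v <- pdd$accuracy[order(pdd$participant)]
    btr <- rsa$between_task_r
    rsa$interaction_geometry <- interaction_geometry_correlation(
      pdd_acc_v, btr$between_task_r[order(btr$participant)])
  }

  # assemble the per-region ledgers
  wide <- tidyr::pivot_wider(
    cat_acc |> select("participant", "region", "task", "accuracy"),
    names_from = "task", values_from = "accuracy",
    names_prefix = "category_acc_")
  names(wide) <- sub("category_acc_Oddball", "category_acc_oddball",
                     names(wide))
  names(wide) <- sub("category_acc_Oneback", "category_acc_oneback",
                     names(wide))
  wide <- wide |>
    left_join(rename(cat_overall, category_acc_overall = "accuracy"),
              by = c("participant", "region")) |>
    left_join(rename(task_acc[c("participant", "region", "accuracy")],
                     task_acc = "accuracy"),
              by = c("participant", "region")) |>
    left_join(rename(cat_cross, category_cross_acc = "accuracy"),
              by = c("participant", "region")) |>
    left_join(ratio_tbl |> select("participant", "region",
                                  cross_ratio = "ratio"),
              by = c("participant", "region")) |>
    left_join(rename(task_cross, task_cross_acc = "accuracy"),
              by = c("participant", "region")) |>
    left_join(pdd |> select("participant", "region", pdd_acc = "accuracy"),
              by = c("participant", "region"))
  ledgers <- map(split(wide, wide$region),
                 function(g) region_test_ledger(g, q = config$q))

  results <- structure(list(
    accuracy = list(category = cat_acc, category_overall = cat_overall,
                    task = task_acc, category_cross = cat_cross,
                    task_cross = task_cross),
    cross_decoding_ratio = ratio_tbl,
    pattern_difference = pdd,
    permutation = perm, posterior_odds = odds, rsa = rsa,
    ledgers = ledgers, participant_table = wide,
    ground_truth = if (!is.null(cohort)) cohort$truth else NULL,
    config = config, seed = config$seed,
    package_version = as.character(utils::packageVersion("mixsel"))),
    class = "mixsel_results")
  if (!is.null(config$out_dir)) write_results(results, config$out_dir)
  results
}

write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(results$participant_table, file.path(dir,
                                                        "participants.csv"))
  readr::write_csv(
    list_rbind(imap(results$ledgers,
                    ~ dplyr::bind_cols(tibble(region = .y), .x))),
    file.path(dir, "ledgers.csv"))
  if (!is.null(results$permutation)) {
    readr::write_csv(results$permutation, file.path(dir, "permutation.csv"))
  }
  if (!is.null(results$posterior_odds)) {
    jsonlite::write_json(
      imap(results$posterior_odds,
           ~ c(as.list(glance(.x)), .x$diagnostics["log_odds_drift"])),
      file.path(dir, "posterior_odds.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(results$rsa)) {
    readr::write_csv(results$rsa$variance_explained,
                     file.path(dir, "geometry_variance_explained.csv"))
    for (nm in names(results$rsa$mds)) {
      readr::write_csv(results$rsa$mds[[nm]],
                       file.path(dir, sprintf("mds_%s.csv", nm)))
    }
  }
  cfg <- results$config
  cfg$simulation <- unclass(cfg$simulation)
  cfg$spec <- unclass(cfg$spec)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Summarize a results bundle
#'
#' Produces the headline tables: per region, the number of participants with
#' an individually significant interaction effect (permutation test,
#' BH-corrected across participants) alongside the Bayesian posterior odds,
#' the geometry-change summary, and the significance ledger.
#'
#' @param results a `mixsel_results` bundle from [run_pipeline()].
#' @return a `mixsel_summary` list with `interaction_table`, `geometry`,
#'   `ledgers`, and `notes`.
#' @export
summarize_results <- function(results) {
  stopifnot(inherits(results, "mixsel_results"))
  regions <- sort(unique(results$pattern_difference$region))
  if (length(regions) == 0) abort("results bundle contains no regions")

  interaction_table <- list_rbind(map(regions, function(rg) {
    n_sig <- NA_integer_
    if (!is.null(results$permutation)) {
      pp <- dplyr::filter(results$permutation, .data$region == rg)
      n_sig <- sum(bh_fdr(pp$p_value, q = 0.05))
    }
    odds <- if (!is.null(results$posterior_odds)) {
      results$posterior_odds[[rg]]$odds
    } else NA_real_
    tibble(region = rg, n_significant_participants = n_sig,
           posterior_odds = odds,
           mean_pdd_accuracy =
             mean(results$pattern_difference$accuracy[
               results$pattern_difference$region == rg]))
  }))

  geometry <- NULL
  notes <- character()
  for (rg in regions) {
    led <- results$ledgers[[rg]]
    sig12 <- led$significant[led$test == "pattern_difference_vs_chance"]
    notes <- c(notes, sprintf(
      "%s: interaction (pattern difference) decoding %s", rg,
      if (isTRUE(sig12)) "significant" else "not significant"))
  }
  if (!is.null(results$rsa)) {
    geometry <- results$rsa$variance_explained |>
      group_by(.data$region) |>
      summarise(mean_variance_explained = mean(.data$variance_explained),
                .groups = "drop")
    geometry$p_value <- NA_real_
    for (rg in geometry$region) {
      ve <- dplyr::filter(results$rsa$variance_explained,
                          .data$region == rg)
      gt <- one_sample_t(ve$variance_explained, mu0 = 1, tail = "less")
      geometry$p_value[geometry$region == rg] <- gt$p_value
      notes <- c(notes, sprintf(
        "%s: between-task geometry change %s (variance explained %.2f)",
        rg, if (gt$p_value < 0.05) "significant" else "not significant",
        geometry$mean_variance_explained[geometry$region == rg]))
    }
  }
  structure(list(interaction_table = interaction_table, geometry = geometry,
                 ledgers = results$ledgers, notes = notes),
            class = "mixsel_summary")
}

#' @export
print.mixsel_summary <- function(x, ...) {
  cat("Interaction (nonlinear mixed selectivity) summary\n")
  print(x$interaction_table)
  if (!is.null(x$geometry)) {
    cat("\nBetween-task geometry change\n")
    print(x$geometry)
  }
  cat("\n")
  for (n in x$notes) cat("- ", n, "\n", sep = "")
  invisible(x)
}

#' Default sector map for the visual hierarchy
#'
#' Early visual (V1–V4), ventral (LOT/VOT) and dorsal (IPS2–4) sectors used
#' when analyzing multi-region datasets.
#'
#' @return named list of region id vectors.
#' @export
default_sectors <- function() {
  list(`V1-V4` = c("V1", "V2", "V3", "V4"),
       `LOT/VOT` = c("LOT", "VOT"),
       `IPS2-4` = c("IPS2", "IPS3", "IPS4"))
}
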