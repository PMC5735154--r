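#' @importFrom rlang .data
NULL

# short stable hash of a configuration object (provenance header)
.config_hash <- function(x) {
  sprintf("%08x", .string_seed(paste(deparse(x), collapse = ""))[1])
}

.write_stage <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Run the full choice-consistency analysis pipeline
#'
#' Composes the package's stages in order: design validation, triplet
#' scoring, group summary, log-transform with variance-homogeneity
#' diagnostics, the mixed-effects group-by-task contrast model, the
#' trial-position and response-time regressions, the item-heterogeneity
#' test, the lesion-index correlation (when lesion volumes are available),
#' and the noise sweep with inversion of each group's mean intransitivity
#' to a noise fraction. Every output file carries a provenance header
#' (package version, seed, config hash) and the run is a pure function of
#' (input, config, seed).
#'
#' @param input a `synthetic_cohort` from [generate_cohort()], or a
#'   [choice_dataset()].
#' @param output_dir directory for the stage outputs (created if needed);
#'   `NULL` skips all file output.
#' @param lesions optional volumes table (`subject_id`, `vol_left`,
#'   `vol_right`); taken from the cohort when `input` is a
#'   `synthetic_cohort`.
#' @param seed master seed for the sweep stage.
#' @param sweep_grid,sweep_replicates noise-fraction grid and replicates
#'   per grid point for the alpha sweep.
#' @param sim_config [simulation_config()] for the sweep; defaults to the
#'   reference configuration.
#' @return Invisibly, a list with every stage's result (`validation`,
#'   `scores`, `group_summary`, `bartlett_pre`, `bartlett_post`,
#'   `group_task_model`, `triplet_regressions`, `rt`, `item_test`,
#'   `lesion_correlation`, `sweep`, `alpha_estimates`, `files`). When
#'   `output_dir` is set, the resolved run configuration is written to
#'   `config.json` and a one-line-per-stage log (row and exclusion counts)
#'   to `log.txt` alongside the stage tables.
#' @export
run_full_pipeline <- function(input, output_dir = NULL, lesions = NULL,
                              seed = 1L,
                              sweep_grid = seq(0, 1, by = 0.05),
                              sweep_replicates = 300L,
                              sim_config = NULL) {
  if (inherits(input, "synthetic_cohort")) {
    ds <- input$dataset
    if (is.null(lesions)) lesions <- input$lesions
  } else if (inherits(input, "choice_dataset")) {
    ds <- input
  } else {
    stop("input must be a synthetic_cohort or a choice_dataset", call. = FALSE)
  }
  if (nrow(ds$trials) == 0) stop("input dataset is empty", call. = FALSE)

  validation <- validate_design(ds)

  scored <- score_all(ds)
  scores <- scored$scores

  group_summary <- dplyr::summarise(
    dplyr::group_by(scores, .data$group, .data$task),
    n = dplyr::n(),
    mean_pct = mean(.data$pct_intransitive),
    sd_pct = stats::sd(.data$pct_intransitive),
    median_pct = stats::median(.data$pct_intransitive),
    .groups = "drop")

  by_task_raw <- split(scores$pct_intransitive, scores$task)
  bartlett_pre <- variance_homogeneity_check(by_task_raw)
  scores_t <- log_transform_scores(scores)
  bartlett_post <- variance_homogeneity_check(split(scores_t$log_pct,
                                                    scores_t$task))

  group_task_model <- fit_group_task_model(scores_t)

  pref_trip <- scored$triplets[scored$triplets$task == "preference", ]
  triplet_regressions <- triplet_level_regressions(pref_trip)

  # annotate preference trials with involvement flags, per subject
  pref_trials <- ds$trials[ds$trials$task == "preference", ]
  annotated <- lapply(unique(pref_trials$subject_id), function(sid) {
    trial_involvement(pref_trip[pref_trip$subject_id == sid, ],
                      pref_trials[pref_trials$subject_id == sid, ])
  })
  pref_trials <- dplyr::bind_rows(annotated)
  rt_res <- if (all(is.na(pref_trials$rt))) NULL else rt_analyses(pref_trials)

  item_test <- item_involvement_test(
    item_involvement_counts(pref_trip, ds$n_items))

  lesion_correlation <- NULL
  if (!is.null(lesions) && nrow(lesions) >= 4) {
    recs <- lesion_records(lesions)
    mtl_pref <- scores[scores$task == "preference" &
                         scores$subject_id %in% recs$subject_id, ]
    lesion_correlation <- ldi_behavior_correlation(recs, mtl_pref)
  }

  if (is.null(sim_config)) {
    sim_config <- simulation_config(n_items = ds$n_items, seed = seed)
  }
  sweep <- sweep_alpha(sim_config, sweep_grid,
                       n_replicates = sweep_replicates, seed = seed)
  pref_means <- group_summary[group_summary$task == "preference", ]
  alpha_estimates <- dplyr::bind_rows(lapply(seq_len(nrow(pref_means)), function(r) {
    est <- invert_alpha(pref_means$mean_pct[r], sweep)
    tibble::tibble(group = pref_means$group[r],
                   mean_pct = pref_means$mean_pct[r],
                   alpha = est$alpha, lower = est$lower, upper = est$upper,
                   flag = est$flag)
  }))

  files <- character()
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- c(
      paste0("package: intrans ", as.character(utils::packageVersion("intrans"))),
      paste0("seed: ", seed),
      paste0("config_hash: ", .config_hash(list(sweep_grid, sweep_replicates,
                                                sim_config[c("n_items", "alpha",
                                                             "error_spec")])))
    )
    out <- function(df, name) {
      p <- file.path(output_dir, name)
      .write_stage(df, p, hdr)
      p
    }
    model_tbl <- function(mr) cbind(tibble::tibble(model = mr$description),
                                    mr$tidy)
    files <- c(
      out(scores, "scores.csv"),
      out(group_summary, "group_summary.csv"),
      out(tibble::tibble(
        stage = c("pre_transform", "post_transform"),
        bartlett_k2 = c(bartlett_pre$statistic, bartlett_post$statistic),
        df = c(bartlett_pre$df, bartlett_post$df),
        p = c(bartlett_pre$p, bartlett_post$p)), "bartlett.csv"),
      out(model_tbl(group_task_model), "group_task_model.csv"),
      out(dplyr::bind_rows(model_tbl(triplet_regressions$last_trial),
                           model_tbl(triplet_regressions$trial_variance)),
          "triplet_regressions.csv"),
      out(tibble::tibble(statistic = item_test$statistic,
                         df1 = item_test$df1, df2 = item_test$df2,
                         p = item_test$p), "item_test.csv"),
      out(sweep$table, "sweep.csv"),
      out(alpha_estimates, "alpha_estimates.csv"))
    if (!is.null(rt_res)) {
      files <- c(files, out(dplyr::bind_rows(model_tbl(rt_res$involvement),
                                             model_tbl(rt_res$group_rt)),
                            "rt_analyses.csv"))
    }
    if (!is.null(lesion_correlation)) {
      files <- c(files, out(tibble::tibble(
        rho = lesion_correlation$rho, statistic = lesion_correlation$statistic,
        p = lesion_correlation$p, n = lesion_correlation$n), "lesion_correlation.csv"))
    }
    resolved <- list(
      package = as.character(utils::packageVersion("intrans")),
      seed = seed, sweep_grid = sweep_grid,
      sweep_replicates = sweep_replicates,
      sim_config = sim_config[c("n_items", "utilities", "alpha",
                                "error_spec", "shared_error", "drift_sd")],
      log_offset = attr(scores_t, "offset"),
      log_offset_policy = attr(scores_t, "offset_policy"))
    cfgp <- file.path(output_dir, "config.json")
    jsonlite::write_json(resolved, cfgp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    logp <- file.path(output_dir, "log.txt")
    writeLines(c(
      sprintf("validate: %d trials, complete=%s, missing=%d, duplicate=%d, irregular=%d",
              nrow(ds$trials), validation$is_complete,
              nrow(validation$missing_pairs), nrow(validation$duplicate_pairs),
              nrow(validation$irregular_trials)),
      sprintf("score: %d subject-tasks, %d triplets, %d excluded",
              nrow(scores), nrow(scored$triplets), sum(scores$n_excluded)),
      sprintf("transform: offset=%.6g policy=%s bartlett %.3g -> %.3g",
              attr(scores_t, "offset"), attr(scores_t, "offset_policy"),
              bartlett_pre$statistic, bartlett_post$statistic),
      sprintf("group_model: %d rows, %d fixed effects",
              nrow(scores_t), nrow(group_task_model$tidy)),
      sprintf("triplet_regressions: %d triplets", nrow(pref_trip)),
      sprintf("rt: %s", if (is.null(rt_res)) "skipped (no response times)" else
        sprintf("%d trials, %d excluded", nrow(pref_trials), rt_res$n_excluded_rt)),
      sprintf("item_test: F(%d, %d) = %.4g", item_test$df1, item_test$df2,
              item_test$statistic),
      sprintf("lesion: %s", if (is.null(lesion_correlation)) "skipped" else
        sprintf("n=%d rho=%.3f", lesion_correlation$n, lesion_correlation$rho)),
      sprintf("sweep: %d grid points x %d replicates", length(sweep_grid),
              sweep_replicates)), logp)
    files <- c(files, cfgp, logp)
    summary_lines <- c(
      paste0("# ", hdr),
      "",
      "Group means (percent intransitive):",
      utils::capture.output(print(as.data.frame(group_summary), digits = 3)),
      "",
      sprintf("Bartlett K2 pre-transform: %.2f (p = %.3g); post-transform: %.2f (p = %.3g)",
              bartlett_pre$statistic, bartlett_pre$p,
              bartlett_post$statistic, bartlett_post$p),
      "",
      "Group x task mixed model (log percentages):",
      utils::capture.output(print(as.data.frame(group_task_model$tidy), digits = 3)),
      "",
      "Noise-fraction estimates (preference task):",
      utils::capture.output(print(as.data.frame(alpha_estimates), digits = 3))
    )
    sp <- file.path(output_dir, "summary.txt")
    writeLines(summary_lines, sp)
    files <- c(files, sp)
  }

  invisible(list(
    validation = validation, scores = scores, triplets = scored$triplets,
    group_summary = group_summary, bartlett_pre = bartlett_pre,
    bartlett_post = bartlett_post, group_task_model = group_task_model,
    triplet_regressions = triplet_regressions, rt = rt_res,
    item_test = item_test, lesion_correlation = lesion_correlation,
    sweep = sweep, alpha_estimates = alpha_estimates, files = files))
}
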