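# Trial-log I/O, run configuration and full-study orchestration.

trial_log_schema <- function() {
  list(
    version = "1.0",
    columns = readr::cols(
      participant_id = readr::col_integer(),
      experiment = readr::col_character(),
      block_index = readr::col_integer(),
      trial_index = readr::col_integer(),
      task = readr::col_character(),
      motion_coherence = readr::col_double(),
      direction = readr::col_character(),
      color_coherence = readr::col_double(),
      majority_color = readr::col_character(),
      csi_ms = readr::col_double(),
      sequence_type = readr::col_character(),
      congruent = readr::col_logical(),
      congruency_n_minus_1 = readr::col_logical(),
      correct_response = readr::col_character(),
      block_first = readr::col_logical(),
      response = readr::col_character(),
      rt_ms = readr::col_double(),
      correct = readr::col_logical(),
      timeout = readr::col_logical()
    )
  )
}

#' Read / write trial logs
#'
#' Trial logs are plain CSV files with the fixed column schema used
#' throughout the package (one row per trial). The writer always emits the
#' full schema in canonical order; the reader rejects files missing required
#' columns, naming them. Writing then reading a log is the identity on
#' values and column order.
#'
#' @param path File path (CSV).
#' @return `read_trial_log()`: the trial-log tibble.
#' @export
read_trial_log <- function(path) {
  schema <- trial_log_schema()
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (length(header) == 0) abort("empty trial log file")
  required <- required_log_columns()
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    abort(paste0("trial log is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  keep <- schema$columns
  keep$cols <- keep$cols[intersect(names(keep$cols), header)]
  out <- readr::read_csv(path, col_types = keep, show_col_types = FALSE)
  if (nrow(out) == 0) abort("trial log contains no trials")
  out
}

#' @rdname read_trial_log
#' @param log Trial-log tibble.
#' @export
write_trial_log <- function(log, path) {
  check_log_schema(log)
  order <- names(trial_log_schema()$columns$cols)
  cols <- c(intersect(order, names(log)), setdiff(names(log), order))
  readr::write_csv(as_tibble(log)[, cols], path)
  invisible(path)
}

#' Run configuration for a full synthetic study
#'
#' @param seed Master seed; all per-stage seeds derive from it.
#' @param n_single_task Number of synthetic participants for the single-task
#'   designs (psychometric and orthogonal target/distractor experiments).
#' @param n_switching Number of synthetic participants for the
#'   task-switching experiment.
#' @param observer An [observer_params()].
#' @param cleaning A [cleaning_config()].
#' @return A list of class `rsk_run_config` carrying a config hash.
#' @export
run_config <- function(seed = 1L, n_single_task = 42L, n_switching = 30L,
                       observer = observer_params(),
                       cleaning = cleaning_config()) {
  cfg <- list(seed = as.integer(seed),
              n_single_task = as.integer(n_single_task),
              n_switching = as.integer(n_switching),
              observer = observer, cleaning = cleaning)
  cfg$hash <- rlang::hash(cfg[c("seed", "n_single_task", "n_switching",
                                "observer", "cleaning")])
  structure(cfg, class = "rsk_run_config")
}

# Simulate one experiment across counterbalanced participants.
simulate_study <- function(experiment = c("1a", "1b", "2", "3"),
                           n_participants, seed,
                           observer = observer_params(),
                           csi_order = c(200, 800)) {
  experiment <- match.arg(experiment)
  cb <- counterbalance_participants(n_participants)
  logs <- purrr::map(seq_len(n_participants), function(i) {
    pseed <- derive_seed(seed, i)
    flip <- cb$color_mapping_flipped[i]
    plan <- switch(
      experiment,
      "1a" = build_exp1a_design(pseed, color_mapping_flipped = flip),
      "1b" = build_exp1b_design(pseed, color_mapping_flipped = flip),
      "2" = build_exp2_design(pseed, first_task = cb$first_task[i],
                              color_mapping_flipped = flip),
      "3" = build_exp3_design(
        pseed, first_task = cb$first_task[i],
        csi_order = if (cb$csi_first[i] == csi_order[1]) csi_order else rev(csi_order),
        color_mapping_flipped = flip))
    simulate_participant(plan, observer, seed = derive_seed(pseed, 7L),
                         participant_id = i)
  })
  # mappings differ across participants; keep them per participant
  log <- dplyr::bind_rows(purrr::map(logs, function(l) {
    l2 <- as_tibble(l)
    l2$color_mapping_flipped <- attr(l, "metadata")$mapping$color_mapping_flipped
    l2
  }))
  log
}

# Signed congruence respecting per-participant color mappings.
signed_congruence_by_participant <- function(log) {
  flips <- unique(log$color_mapping_flipped)
  out <- rep(NA_real_, nrow(log))
  for (fl in flips) {
    sel <- log$color_mapping_flipped == fl
    out[sel] <- signed_distractor_congruence(log[sel, ], response_mapping(fl))
  }
  out
}

#' Run the full synthetic study and analysis pipeline
#'
#' Generates designs, simulates synthetic observers (42 participants for the
#' single-task experiments, 30 for the task-switching experiment, at the
#' defaults), runs the complete analysis pipeline, and (optionally) writes
#' tidy result tables plus a JSON run report. Fully deterministic given the
#' config.
#'
#' @param config An [run_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param experiments Which experiments to run.
#' @return A list of class `rsk_study`: trial logs, regression results,
#'   chance tests, cost tables, ANOVAs, asymmetry analysis, sign-pattern
#'   table, and the run report.
#' @export
run_full_study <- function(config = run_config(), out_dir = NULL,
                           experiments = c("1a", "1b", "2", "3")) {
  if (config$n_single_task < 4 || config$n_switching < 4) {
    warn("very small participant numbers: analyses will be low-powered")
  }
  res <- list(config = config)
  seed <- config$seed
  obs <- config$observer

  if ("1a" %in% experiments) {
    res$log_1a <- simulate_study("1a", config$n_single_task,
                                 derive_seed(seed, 101L), obs)
    cl <- clean_trials(res$log_1a, config$cleaning)
    cells <- cell_summary(cl, .data$participant_id, .data$motion_coherence,
                          .data$majority_color)
    res$anova_1a_rt <- rm_anova(cells, "mean_log_rt",
                                within = c("motion_coherence", "majority_color"))
    res$anova_1a_acc <- rm_anova(cells, "arcsine_acc",
                                 within = c("motion_coherence", "majority_color"))
  }
  if ("1b" %in% experiments) {
    res$log_1b <- simulate_study("1b", config$n_single_task,
                                 derive_seed(seed, 102L), obs)
    cl <- clean_trials(res$log_1b, config$cleaning)
    cells <- cell_summary(cl, .data$participant_id, .data$color_coherence,
                          .data$majority_color)
    res$anova_1b_rt <- rm_anova(cells, "mean_log_rt",
                                within = c("color_coherence", "majority_color"))
    res$anova_1b_acc <- rm_anova(cells, "arcsine_acc",
                                 within = c("color_coherence", "majority_color"))
  }
  if ("2" %in% experiments) {
    res$log_2 <- simulate_study("2", config$n_single_task,
                                derive_seed(seed, 103L), obs)
    # regressions are run per color-mapping group and reported pooled via the
    # per-participant signed congruence, so flipped mappings stay coherent
    log2 <- res$log_2
    cl2 <- clean_trials(log2, config$cleaning)
    res$regressions_2 <- purrr::map(
      tidyr::expand_grid(task = c("motion", "color"),
                         outcome = c("rt", "accuracy")) |>
        purrr::transpose(),
      function(cell) {
        # use the unflipped-mapping subset plus the flipped subset with its
        # own mapping by recomputing congruence per participant
        regress_pooled(cl2, cell$task, cell$outcome)
      })
    names(res$regressions_2) <- c("motion_rt", "motion_accuracy",
                                  "color_rt", "color_accuracy")
    res$chance_2 <- chance_tests_exp2(cl2)
  }
  if ("3" %in% experiments) {
    res$log_3 <- simulate_study("3", config$n_switching,
                                derive_seed(seed, 104L), obs)
    res$costs_3 <- compute_costs(res$log_3, config$cleaning)
    res$sign_pattern_3 <- cost_sign_pattern(res$log_3, config$cleaning)
    res$asymmetry_3 <- asymmetry_analysis(res$log_3, config$cleaning)
    cl3 <- clean_trials(res$log_3, config$cleaning)
    cells3 <- cell_summary(cl3, .data$participant_id, .data$csi_ms,
                           .data$sequence_type, .data$congruent)
    res$anova_3_rt <- rm_anova(cells3, "mean_log_rt",
                               within = c("csi_ms", "sequence_type", "congruent"))
    res$anova_3_er <- rm_anova(
      cells3 |> mutate(er = 100 * (1 - .data$accuracy)), "er",
      within = c("csi_ms", "sequence_type", "congruent"))
  }
  res$report <- list(
    config_hash = config$hash, seed = config$seed,
    n_single_task = config$n_single_task, n_switching = config$n_switching,
    experiments = experiments,
    generated_at = "deterministic; see seed"
  )
  if (!is.null(out_dir)) write_study(res, out_dir)
  structure(res, class = "rsk_study")
}

# Pooled target/distractor regression across counterbalanced participants:
# compute per-participant signed congruence with that participant's own
# mapping, then fit the standard pooled OLS.
regress_pooled <- function(cleaned, task, outcome) {
  pick <- if (outcome == "rt") cleaned$rt_log else cleaned$accuracy_log
  pick <- pick[pick$task == task, , drop = FALSE]
  pick$target_coherence <- 100 * ifelse(pick$task == "motion",
                                        pick$motion_coherence,
                                        pick$color_coherence)
  pick$distractor_congruence <- signed_congruence_by_participant(pick)
  cells <- if (outcome == "rt") {
    pick |>
      group_by(.data$participant_id, .data$target_coherence,
               .data$distractor_congruence) |>
      summarise(y = mean(transform_rt(.data$rt_ms)), .groups = "drop")
  } else {
    pick |>
      group_by(.data$participant_id, .data$target_coherence,
               .data$distractor_congruence) |>
      summarise(y = transform_acc(mean(.data$correct)), .groups = "drop")
  }
  z <- function(x) (x - mean(x)) / sd(x)
  d <- tibble(y = z(cells$y), target = z(cells$target_coherence),
              distractor = z(cells$distractor_congruence))
  fit <- lm(y ~ target + distractor, data = d)
  sm <- summary(fit)
  coefs <- sm$coefficients[c("target", "distractor"), , drop = FALSE]
  fstat <- sm$fstatistic
  structure(
    list(terms = tibble(term = c("target_coherence", "distractor_congruence"),
                        beta = unname(coefs[, 1]),
                        statistic = unname(coefs[, 3]),
                        p.value = unname(coefs[, 4])),
         overall = tibble(statistic = unname(fstat[1]), df = unname(fstat[2]),
                          df.residual = unname(fstat[3]),
                          p.value = pf(fstat[1], fstat[2], fstat[3],
                                       lower.tail = FALSE),
                          r.squared = sm$r.squared,
                          adj.r.squared = sm$adj.r.squared, n = nrow(d)),
         task = task, outcome = outcome, fit = fit),
    class = "rsk_regression")
}

# Chance tests at minimal target coherence, by congruency.
chance_tests_exp2 <- function(cleaned) {
  acc <- cleaned$accuracy_log
  acc$target_coherence <- 100 * ifelse(acc$task == "motion",
                                       acc$motion_coherence,
                                       acc$color_coherence)
  rows <- list()
  for (tk in c("motion", "color")) {
    sub <- acc[acc$task == tk, ]
    min_c <- min(sub$target_coherence)
    for (cong in c(TRUE, FALSE)) {
      pp <- sub |>
        filter(.data$target_coherence == min_c, .data$congruent == cong) |>
        group_by(.data$participant_id) |>
        summarise(acc = mean(.data$correct), .groups = "drop")
      ct <- chance_level_test(pp$acc)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(task = tk, target_coherence = min_c, congruent = cong), ct)
    }
  }
  dplyr::bind_rows(rows)
}

write_study <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- res$config$hash
  wr <- function(df, name) {
    readr::write_csv(as_tibble(df), file.path(out_dir, paste0(name, ".csv")))
  }
  for (nm in c("log_1a", "log_1b", "log_2", "log_3")) {
    if (!is.null(res[[nm]])) write_trial_log(res[[nm]],
                                             file.path(out_dir, paste0(nm, ".csv")))
  }
  if (!is.null(res$costs_3)) wr(res$costs_3, "costs_3")
  if (!is.null(res$sign_pattern_3)) wr(res$sign_pattern_3, "sign_pattern_3")
  if (!is.null(res$asymmetry_3)) wr(res$asymmetry_3$cost_table, "asymmetry_costs_3")
  for (nm in grep("^anova_", names(res), value = TRUE)) {
    wr(tidy(res[[nm]]), nm)
  }
  if (!is.null(res$regressions_2)) {
    reg <- purrr::imap(res$regressions_2, function(r, nm) {
      dplyr::bind_cols(tibble(model = nm), tidy(r))
    }) |> dplyr::bind_rows()
    wr(reg, "regressions_2")
  }
  if (!is.null(res$chance_2)) wr(res$chance_2, "chance_tests_2")
  report <- res$report
  report$config_hash <- stamp
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
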