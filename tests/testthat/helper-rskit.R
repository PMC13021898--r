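# Shared fixtures, generated in code.

# A minimal bivalent trial row for constructing drift/congruence cases.
make_trial <- function(task = "color", motion_coherence = 0.95,
                       direction = "leftward", color_coherence = 0.75,
                       majority_color = "khaki", correct_response = NULL,
                       sequence_type = "single", csi_ms = NA_real_,
                       congruent = NA, congruency_n_minus_1 = NA,
                       mapping = response_mapping()) {
  if (is.null(correct_response)) {
    correct_response <- correct_response_for(task, direction, majority_color,
                                             mapping)
  }
  tibble::tibble(
    participant_id = 1L, experiment = "x", block_index = 1L, trial_index = 2L,
    task = task, motion_coherence = motion_coherence, direction = direction,
    color_coherence = color_coherence, majority_color = majority_color,
    csi_ms = csi_ms, sequence_type = sequence_type, congruent = congruent,
    congruency_n_minus_1 = congruency_n_minus_1,
    correct_response = correct_response, block_first = FALSE
  )
}

# A deterministic hand-built switching log: constant RTs by sequence type so
# cost estimators have known exact values.
make_constant_cost_log <- function(rt_single = 500, rt_repeat = 600,
                                   rt_switch = 700, n_per_cell = 4,
                                   n_participants = 3) {
  grid <- tidyr::expand_grid(
    participant_id = seq_len(n_participants),
    csi_ms = c(200, 800),
    congruent = c(TRUE, FALSE),
    sequence_type = c("single", "repeat", "switch"),
    rep = seq_len(n_per_cell)
  )
  rt_map <- c(single = rt_single, `repeat` = rt_repeat, switch = rt_switch)
  grid |>
    dplyr::group_by(participant_id) |>
    dplyr::mutate(
      experiment = "3", block_index = 1L,
      trial_index = dplyr::row_number() + 1L,  # no block-first rows
      task = "motion", motion_coherence = 0.75, direction = "rightward",
      color_coherence = 0.75, majority_color = "white",
      congruency_n_minus_1 = congruent,
      correct_response = "right", block_first = FALSE,
      response = "right", rt_ms = unname(rt_map[sequence_type]),
      correct = TRUE, timeout = FALSE
    ) |>
    dplyr::ungroup()
}

# Synthetic cleaned object for regression tests: per-participant cell means
# over the orthogonal stimulus grid with a known generative slope.
make_regression_log <- function(n_participants, beta_target = -0.5,
                                noise_sd = 1, task = "motion", seed = 1) {
  rskit:::with_rng_seed(seed, make_regression_log_impl(
    n_participants, beta_target, noise_sd, task))
}

make_regression_log_impl <- function(n_participants, beta_target,
                                     noise_sd, task) {
  grid <- rskit:::exp2_stimulus_grid()
  log <- tidyr::expand_grid(participant_id = seq_len(n_participants), grid)
  log$task <- task
  log$experiment <- "2"
  log$block_index <- 1L
  log$trial_index <- seq_len(nrow(log)) + 1L
  log$sequence_type <- "single"
  log$csi_ms <- NA_real_
  log$correct_response <- correct_response_for(
    log$task, log$direction, log$majority_color, response_mapping())
  log <- rskit:::add_congruent(log, response_mapping())
  target <- 100 * if (task == "motion") log$motion_coherence else log$color_coherence
  zt <- (target - mean(target)) / stats::sd(target)
  log$rt_ms <- exp(6 + beta_target * 0.1 * zt + 0.1 * noise_sd * rnorm(nrow(log)))
  log$response <- log$correct_response
  log$correct <- TRUE
  log$timeout <- FALSE
  log$block_first <- FALSE
  structure(list(rt_log = log, accuracy_log = log,
                 exclusions = tibble::tibble(), config = cleaning_config()),
            class = "rsk_cleaned")
}
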