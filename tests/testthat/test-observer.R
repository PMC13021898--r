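test_that("drift rate combines signed target and distractor evidence", {
  p <- observer_params()
  # motion task at defaults: drift independent of color coherence
  m1 <- make_trial(task = "motion", direction = "rightward",
                   color_coherence = 0.55, majority_color = "khaki",
                   congruent = FALSE)
  m2 <- make_trial(task = "motion", direction = "rightward",
                   color_coherence = 0.95, majority_color = "khaki",
                   congruent = FALSE)
  expect_equal(drift_rate(m1, p), drift_rate(m2, p))
  expect_equal(drift_rate(m1, p), p$k_target_motion * 0.95)
  # color task: congruent distractor raises |v|, incongruent lowers it
  cong <- make_trial(task = "color", majority_color = "khaki",
                     direction = "leftward", motion_coherence = 0.75,
                     color_coherence = 0.75, congruent = TRUE)
  incong <- make_trial(task = "color", majority_color = "khaki",
                       direction = "rightward", motion_coherence = 0.75,
                       color_coherence = 0.75, congruent = FALSE)
  expect_gt(abs(drift_rate(cong, p)), abs(drift_rate(incong, p)))
  expect_equal(drift_rate(cong, p),
               -(p$k_target_color * 0.75 + p$k_distractor_in_color_task * 0.75))
  # no evidence, no distractor gain: zero drift
  null_p <- observer_params(k_distractor_in_motion_task = 0)
  z <- make_trial(task = "motion", motion_coherence = 0,
                  direction = "rightward", congruent = FALSE)
  expect_equal(drift_rate(z, null_p), 0)
})

test_that("the noiseless limit matches the closed-form decision time within 1 ms", {
  p <- observer_params(noise_sd = 0, lapse_rate = 0,
                       switch_lapse_rate = 0, mixing_lapse_rate_short = 0,
                       mixing_lapse_rate_long = 0)
  trial <- make_trial(task = "motion", direction = "rightward",
                      motion_coherence = 0.75, color_coherence = 0.75,
                      majority_color = "white", congruent = TRUE)
  out <- simulate_trial(trial, p, seed = 1)
  v <- drift_rate(trial, p)
  expect_equal(out$response, "right")
  expect_true(out$correct)
  expect_lte(abs(out$rt_ms - (p$boundary / v * 1000 + p$t0_ms)), 1)
  # additive penalties shift the noiseless RT exactly
  sw <- make_trial(task = "motion", direction = "rightward",
                   motion_coherence = 0.75, color_coherence = 0.75,
                   majority_color = "white", congruent = TRUE,
                   sequence_type = "switch", csi_ms = 200)
  out_sw <- simulate_trial(sw, p, seed = 1)
  expect_equal(out_sw$rt_ms - out$rt_ms,
               p$mixed_block_penalty_ms + p$switch_penalty_ms)
})

test_that("zero drift yields chance accuracy and RT never undercuts t0", {
  p <- observer_params(lapse_rate = 0, switch_lapse_rate = 0,
                       mixing_lapse_rate_short = 0, mixing_lapse_rate_long = 0)
  one <- make_trial(task = "motion", motion_coherence = 0,
                    direction = "rightward", color_coherence = 0.75,
                    majority_color = "khaki", congruent = FALSE)
  trials <- one[rep(1, 10000), ]
  p0 <- observer_params(k_distractor_in_motion_task = 0, lapse_rate = 0,
                        switch_lapse_rate = 0, mixing_lapse_rate_short = 0,
                        mixing_lapse_rate_long = 0)
  out <- rskit:::with_rng_seed(99, rskit:::simulate_trials_impl(trials, p0))
  responded <- out[!out$timeout, ]
  expect_equal(mean(responded$response == "right"), 0.5, tolerance = 0.02)
  expect_true(all(responded$rt_ms >= p$t0_ms))
})

test_that("participant simulation is deterministic and fills every trial", {
  plan <- build_exp3_design(seed = 4)
  log1 <- simulate_participant(plan, observer_params(), seed = 10)
  log2 <- simulate_participant(plan, observer_params(), seed = 10)
  expect_identical(tibble::as_tibble(log1), tibble::as_tibble(log2))
  expect_equal(nrow(log1), 768)
  expect_false(any(is.na(log1$rt_ms) & !log1$timeout))
  log3 <- simulate_participant(plan, observer_params(), seed = 11)
  expect_false(identical(log1$rt_ms, log3$rt_ms))
})

test_that("a null observer produces near-zero switch costs", {
  p0 <- observer_params(mixed_block_penalty_ms = 0, switch_penalty_ms = 0,
                        inertia_penalty_ms = 0, csi_benefit_ms = 0,
                        switch_lapse_rate = 0, mixing_lapse_rate_short = 0,
                        mixing_lapse_rate_long = 0,
                        k_target_color = 10)  # equal task gains
  logs <- purrr::map(1:6, function(i) {
    plan <- build_exp3_design(seed = 100 + i)
    simulate_participant(plan, p0, seed = 200 + i, participant_id = i)
  })
  log <- dplyr::bind_rows(purrr::map(logs, tibble::as_tibble))
  costs <- compute_costs(log, by_congruency = FALSE)
  sw <- costs$switch_cost_ms
  expect_lt(abs(mean(sw)), 2 * stats::sd(sw) / sqrt(length(sw)) + 5)
})

test_that("accuracy rises and RT falls with target coherence (psychometric law)", {
  # at the defaults accuracy saturates quickly (high drift gains); check
  # RT monotonicity by rank and accuracy nondecreasing within binomial noise
  params <- observer_params()
  logs <- purrr::map(1:13, function(i) {
    plan <- build_exp2_design(seed = 300 + i, first_task = "motion")
    simulate_participant(plan, params, seed = 400 + i, participant_id = i)
  })
  log <- dplyr::bind_rows(purrr::map(logs, tibble::as_tibble))
  s <- psychometric_summary(clean_trials(log), "motion")
  expect_equal(nrow(s), 10)
  expect_true(all(s$n_acc >= 500))
  expect_lte(cor(s$target_coherence, s$rt_ms, method = "spearman"), -0.9)
  # adjusted proportion keeps the SE bound positive at observed ceilings
  p_adj <- (s$accuracy * s$n_acc + 1) / (s$n_acc + 2)
  se <- sqrt(p_adj * (1 - p_adj) / s$n_acc)
  drop_beyond_noise <- diff(s$accuracy) < -2 * sqrt(se[-1]^2 + se[-10]^2)
  expect_false(any(drop_beyond_noise))

  # with shallower gains the psychometric range is fully spanned and both
  # measures are rank-monotone across all 10 bins
  shallow <- observer_params(k_target_motion = 3, k_target_color = 2)
  logs2 <- purrr::map(1:13, function(i) {
    plan <- build_exp2_design(seed = 500 + i, first_task = "motion")
    simulate_participant(plan, shallow, seed = 600 + i, participant_id = i)
  })
  log2 <- dplyr::bind_rows(purrr::map(logs2, tibble::as_tibble))
  s2 <- psychometric_summary(clean_trials(log2), "motion")
  expect_true(all(s2$n_acc >= 500))
  expect_gte(cor(s2$target_coherence, s2$accuracy, method = "spearman"), 0.9)
  expect_lte(cor(s2$target_coherence, s2$rt_ms, method = "spearman"), -0.9)
})
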