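test_that("cleaning separates RT and accuracy logs per the trimming rules", {
  log <- tibble::tibble(
    participant_id = 1L, experiment = "3", block_index = 1L,
    trial_index = 1:5, task = "motion", sequence_type = "single",
    rt_ms = c(600, 150, 600, 800, NA), correct = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    timeout = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    block_first = c(TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  cl <- clean_trials(log)
  # block-first and fast-guess trials leave both logs
  expect_false(1L %in% cl$rt_log$trial_index)
  expect_false(1L %in% cl$accuracy_log$trial_index)
  expect_false(2L %in% cl$accuracy_log$trial_index)
  # the incorrect 800 ms trial stays in the accuracy log as an error only
  expect_false(4L %in% cl$rt_log$trial_index)
  expect_true(4L %in% cl$accuracy_log$trial_index)
  # the timeout is scored as an error, not an RT
  expect_false(5L %in% cl$rt_log$trial_index)
  expect_true(5L %in% cl$accuracy_log$trial_index)
  expect_false(any(cl$accuracy_log$correct[cl$accuracy_log$timeout]))
  expect_equal(cl$exclusions$n[cl$exclusions$category == "retained_rt"], 1)
  expect_error(clean_trials(log[, setdiff(names(log), "rt_ms")]), "rt_ms")
})

test_that("transforms use natural log and arcsine-root with exact inverses", {
  expect_equal(transform_acc(1), pi / 2)
  expect_equal(transform_acc(0.5), pi / 4)
  expect_error(transform_acc(1.2), "proportions")
  for (x in c(250, 640, 2000)) {
    expect_equal(back_transform_rt(transform_rt(x)), x)
  }
  expect_equal(back_transform_acc(transform_acc(0.37)), 0.37)
  # back-transformed mean log RT is the geometric mean
  rts <- c(300, 450, 700, 1200)
  expect_equal(back_transform_rt(mean(transform_rt(rts))),
               prod(rts)^(1 / 4), tolerance = 1e-9)
})

test_that("target/distractor regression recovers a known slope and nulls", {
  # generative model: log RT = const + b z(target) + sigma e, b = -0.5,
  # sigma = 1, so the standardized slope is b / sqrt(b^2 + sigma^2)
  cleaned <- make_regression_log(40, beta_target = -0.5, noise_sd = 1)
  fit <- regress_target_distractor(cleaned, "motion", "rt")
  betas <- tidy(fit)
  b_t <- betas$beta[betas$term == "target_coherence"]
  b_d <- betas$beta[betas$term == "distractor_congruence"]
  expect_gte(glance(fit)$n, 4000)
  expect_equal(b_t, -0.5 / sqrt(0.5^2 + 1), tolerance = 0.03 / 0.447)
  expect_lt(abs(b_d), 0.05)
  expect_lt(betas$p.value[betas$term == "target_coherence"], 1e-10)
  g <- glance(fit)
  expect_lte(g$adj.r.squared, g$r.squared)
})

test_that("regression coefficients equal the normal-equations oracle", {
  for (case in 1:20) {
    cleaned <- make_regression_log(4, beta_target = runif(1, -1, 1),
                                   noise_sd = runif(1, 0.5, 2),
                                   seed = 1000 + case)
    fit <- regress_target_distractor(cleaned, "motion", "rt")
    # brute-force oracle: standardized cells, explicit normal equations
    log <- cleaned$rt_log
    cells <- log |>
      dplyr::group_by(participant_id,
                      target = 100 * motion_coherence,
                      dist = signed_distractor_congruence(log)) |>
      dplyr::summarise(y = mean(log(rt_ms)), .groups = "drop")
    z <- function(x) (x - mean(x)) / stats::sd(x)
    X <- cbind(1, z(cells$target), z(cells$dist))
    beta_hat <- solve(t(X) %*% X, t(X) %*% z(cells$y))
    expect_equal(tidy(fit)$beta, unname(beta_hat[2:3, 1]), tolerance = 1e-10)
  }
})

test_that("pure-noise outcomes give a near-zero adjusted R-squared", {
  cleaned <- make_regression_log(100, beta_target = 0, noise_sd = 1,
                                 seed = 77)
  fit <- regress_target_distractor(cleaned, "motion", "rt")
  expect_gte(glance(fit)$n, 1e4)
  expect_lt(abs(glance(fit)$adj.r.squared), 0.01)
})

test_that("cost estimators return exact contrasts on constructed logs", {
  log <- make_constant_cost_log(rt_single = 500, rt_repeat = 600,
                                rt_switch = 700)
  costs <- compute_costs(log)
  expect_equal(costs$switch_cost_ms, rep(100, nrow(costs)))
  expect_equal(costs$rt_mixing_cost_ms, rep(100, nrow(costs)))
  expect_equal(costs$error_cost_pct, rep(0, nrow(costs)))
  # a pure 100-ms shift of repeat over single gives exactly 100 ms mixing cost
  log2 <- make_constant_cost_log(rt_single = 500, rt_repeat = 600,
                                 rt_switch = 600)
  costs2 <- compute_costs(log2)
  expect_equal(costs2$switch_cost_ms, rep(0, nrow(costs2)))
  expect_equal(costs2$rt_mixing_cost_ms, rep(100, nrow(costs2)))
})

test_that("the chance-level test handles boundary cases", {
  at_chance <- chance_level_test(rep(0.5, 10))
  expect_true(at_chance$degenerate)
  spread <- chance_level_test(c(0.45, 0.5, 0.55, 0.5))
  expect_equal(spread$t, 0)
  expect_equal(spread$p.value, 0.5)
  expect_equal(spread$cohens_d, 0)
  expect_true(chance_level_test(c(0.6, 0.6, 0.6, 0.6))$degenerate)
  expect_error(chance_level_test(0.7), "two participants")
  above <- chance_level_test(c(0.7, 0.75, 0.8, 0.72))
  expect_lt(above$p.value, 0.01)
  expect_gt(above$cohens_d, 1)
})

test_that("asymmetry analysis recovers constructed direction-specific costs", {
  # build a log where to-motion switches after incongruent trials carry +30 ms
  base <- make_constant_cost_log(rt_single = 500, rt_repeat = 600,
                                 rt_switch = 640, n_per_cell = 6,
                                 n_participants = 4)
  color <- base |> dplyr::mutate(task = "color", correct_response = "left",
                                 response = "left")
  log <- dplyr::bind_rows(base, color) |>
    dplyr::group_by(participant_id) |>
    dplyr::mutate(trial_index = dplyr::row_number() + 1L) |>
    dplyr::ungroup()
  sel <- log$sequence_type == "switch" & log$task == "motion" &
    !log$congruency_n_minus_1
  log$rt_ms[sel] <- log$rt_ms[sel] + 30
  asym <- asymmetry_analysis(log)
  m <- asym$cost_table |>
    dplyr::group_by(direction_to, prev_congruency) |>
    dplyr::summarise(sc = mean(switch_cost_ms), .groups = "drop")
  expect_equal(m$sc[m$direction_to == "to_motion" &
                      m$prev_congruency == "incongruent_n1"], 70)
  expect_equal(m$sc[m$direction_to == "to_motion" &
                      m$prev_congruency == "congruent_n1"], 40)
  expect_equal(m$sc[m$direction_to == "to_color"], rep(40, 2))
})
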