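test_that("motion-psychometric design holds the printed grid and balance", {
  plan <- build_exp1a_design(seed = 3)
  expect_equal(nrow(plan), 120)
  expect_equal(sum(plan$direction == "leftward"), 60)
  expect_equal(sort(unique(plan$motion_coherence)), seq(0.05, 0.95, 0.1))
  expect_true(all(table(plan$motion_coherence) == 12))
  expect_true(all(plan$color_coherence == 1))
  expect_true(all(table(plan$block_index) == 60))
  expect_true(all(is.na(plan$congruent)))
  v <- validate_plan(plan)
  expect_equal(attr(v, "n_violations"), 0)
})

test_that("color-psychometric design fixes motion at zero with a balanced grid", {
  plan <- build_exp1b_design(seed = 3)
  expect_equal(nrow(plan), 60)
  expect_true(all(plan$motion_coherence == 0))
  expect_equal(sum(plan$majority_color == "khaki"), 30)
  expect_equal(sort(unique(plan$color_coherence)), seq(0.55, 0.95, 0.1))
  expect_equal(attr(validate_plan(plan), "n_violations"), 0)
})

test_that("orthogonal design crosses 10 x 10 coherence conditions in quadrants of 25", {
  plan <- build_exp2_design(seed = 11, first_task = "color")
  expect_equal(nrow(plan), 800)
  expect_true(all(table(plan$task) == 400))
  expect_true(all(table(plan$block_index) == 50))
  # the first 8 blocks belong to the first task
  expect_true(all(plan$task[plan$block_index <= 8] == "color"))
  quad <- plan |>
    dplyr::distinct(motion_coherence, direction, color_coherence,
                    majority_color) |>
    dplyr::count(majority_color, direction)
  expect_equal(nrow(quad), 4)
  expect_true(all(quad$n == 25))
  expect_equal(sum(plan$congruent), 400)
  sc_color <- signed_distractor_congruence(plan[plan$task == "color", ])
  sc_motion <- signed_distractor_congruence(plan[plan$task == "motion", ])
  expect_equal(dplyr::n_distinct(sc_color), 20)
  expect_equal(dplyr::n_distinct(sc_motion), 10)
  expect_true(all(abs(sc_color) <= 95 & abs(sc_color) >= 5))
})

test_that("signed distractor congruence carries coherence magnitude and mapped sign", {
  # color task, correct response left (khaki majority), 95% leftward motion
  t1 <- make_trial(task = "color", motion_coherence = 0.95,
                   direction = "leftward", majority_color = "khaki",
                   congruent = TRUE)
  expect_equal(signed_distractor_congruence(t1), +95)
  t2 <- make_trial(task = "color", motion_coherence = 0.95,
                   direction = "rightward", majority_color = "khaki",
                   congruent = FALSE)
  expect_equal(signed_distractor_congruence(t2), -95)
  # motion task, rightward target, 95% white majority (maps right by default)
  t3 <- make_trial(task = "motion", direction = "rightward",
                   color_coherence = 0.95, majority_color = "white",
                   congruent = TRUE)
  expect_equal(signed_distractor_congruence(t3), +95)
  # antisymmetry: flipping the distractor feature or the mapping flips the sign
  t4 <- make_trial(task = "motion", direction = "rightward",
                   color_coherence = 0.95, majority_color = "khaki",
                   congruent = FALSE)
  expect_equal(signed_distractor_congruence(t4), -95)
  expect_equal(
    signed_distractor_congruence(t3, response_mapping(TRUE)), -95)
  # univalent trials have no defined congruence
  expect_error(signed_distractor_congruence(make_trial(congruent = NA)),
               "univalent")
})

test_that("task-switching design satisfies the sandwich structure and balances", {
  plan <- build_exp3_design(seed = 21, first_task = "color")
  expect_equal(nrow(plan), 768)
  st <- table(plan$sequence_type)
  expect_equal(unname(st[c("single", "repeat", "switch")]), c(256L, 256L, 256L),
               ignore_attr = TRUE)
  expect_true(all(table(plan$task[plan$sequence_type == "single"]) == 128))
  expect_true(all(plan$motion_coherence == 0.75))
  expect_true(all(plan$color_coherence == 0.75))
  # per mixed block: 32 switch + 32 repeat, tasks balanced, congruency 1:1
  mixed <- plan[plan$block_index %in% 3:10, ]
  per_block <- mixed |> dplyr::count(block_index, sequence_type)
  expect_true(all(per_block$n == 32))
  per_task <- mixed |> dplyr::count(block_index, task)
  expect_true(all(per_task$n == 32))
  bal <- plan |>
    dplyr::group_by(block_index) |>
    dplyr::summarise(cong = sum(congruent),
                     left = sum(direction == "leftward"),
                     khaki = sum(majority_color == "khaki"),
                     n_csi = dplyr::n_distinct(csi_ms))
  expect_true(all(bal$cong == 32))
  expect_true(all(bal$left == 32))
  expect_true(all(bal$khaki == 32))
  expect_true(all(bal$n_csi == 1))
  # each task x CSI cell holds 64 single-task trials
  singles <- plan[plan$sequence_type == "single", ] |>
    dplyr::count(task, csi_ms)
  expect_true(all(singles$n == 64))
  # sandwich mirror: blocks 11/12 hold the tasks of blocks 2/1 at the other CSI
  block_info <- plan |>
    dplyr::filter(sequence_type == "single") |>
    dplyr::distinct(block_index, task, csi_ms)
  expect_equal(block_info$task[block_info$block_index == 11],
               block_info$task[block_info$block_index == 2])
  expect_false(block_info$csi_ms[block_info$block_index == 11] ==
                 block_info$csi_ms[block_info$block_index == 2])
  expect_equal(attr(validate_plan(plan), "n_violations"), 0)
})

test_that("previous-trial congruency is the lag of the congruent flag within blocks", {
  plan <- build_exp3_design(seed = 8)
  by_block <- plan |>
    dplyr::group_by(block_index) |>
    dplyr::mutate(expected = dplyr::lag(congruent)) |>
    dplyr::ungroup()
  expect_identical(by_block$congruency_n_minus_1, by_block$expected)
  expect_true(all(is.na(plan$congruency_n_minus_1[plan$block_first])))
})

test_that("trial timeline keeps the response-stimulus interval constant across CSIs", {
  short <- trial_timeline(timing = timing_config(200))
  long <- trial_timeline(timing = timing_config(800))
  expect_equal(short$duration_ms[short$event == "blank"], 800)
  expect_equal(long$duration_ms[long$event == "blank"], 200)
  expect_equal(short$onset_ms[short$event == "stimulus"], 2000)
  expect_equal(long$onset_ms[long$event == "stimulus"], 2000)
  expect_equal(timing_config(200)$rsi_ms, 2000)
  expect_equal(timing_config(800)$rsi_ms, 2000)
  # uncued designs: fixation then stimulus, no cue event
  uncued <- trial_timeline(timing = timing_config(NA))
  expect_equal(uncued$event, c("fixation", "stimulus"))
  expect_equal(uncued$onset_ms[2], 1000)
  expect_error(timing_config(500), "csi_ms")
})

test_that("plans are deterministic given seed and flags", {
  expect_identical(tibble::as_tibble(build_exp3_design(5)),
                   tibble::as_tibble(build_exp3_design(5)))
  expect_identical(tibble::as_tibble(build_exp2_design(5, "motion")),
                   tibble::as_tibble(build_exp2_design(5, "motion")))
  expect_false(identical(tibble::as_tibble(build_exp3_design(5)),
                         tibble::as_tibble(build_exp3_design(6))))
})

test_that("the validator flags constructed constraint violations", {
  plan <- build_exp1b_design(seed = 2)
  bad <- plan
  bad$correct_response[1:5] <- "left"   # 5 consecutive same-response trials
  v <- validate_plan(bad)
  expect_gt(attr(v, "n_violations"), 0)
  expect_false(v$pass[v$check == "max response run <= 4"])
})

test_that("counterbalancing enumerates a balanced assignment", {
  cb <- counterbalance_participants(16)
  combos <- cb |> dplyr::count(first_task, color_mapping_flipped, csi_first)
  expect_equal(nrow(combos), 8)
  expect_true(all(combos$n == 2))
})
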