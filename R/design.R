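# Experimental-design generators: response mappings, timing, trial plans for
# the four designs (1a, 1b, 2, 3), signed distractor congruence, plan
# validation.

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Stimulus-response mapping
#'
#' The motion task is spatially compatible and fixed: leftward motion maps to
#' the left key, rightward motion to the right key. The color mapping is
#' arbitrary and counterbalanced across participants: by default khaki maps to
#' the left key and white to the right key; `color_mapping_flipped = TRUE`
#' swaps it.
#'
#' @param color_mapping_flipped Swap the color-to-key assignment.
#' @return A list of class `rsk_mapping` with elements `motion`, `color`
#'   (named character vectors onto `"left"`/`"right"`) and the flag.
#' @examples
#' response_mapping()$color
#' @export
response_mapping <- function(color_mapping_flipped = FALSE) {
  color <- if (color_mapping_flipped) {
    c(khaki = "right", white = "left")
  } else {
    c(khaki = "left", white = "right")
  }
  structure(
    list(motion = c(leftward = "left", rightward = "right"),
         color = color,
         color_mapping_flipped = color_mapping_flipped),
    class = "rsk_mapping"
  )
}

# Which uniform color maps to a given response side.
color_for_side <- function(side, mapping) {
  names(mapping$color)[match(side, mapping$color)]
}

# Which motion direction maps to a given response side.
direction_for_side <- function(side, mapping) {
  names(mapping$motion)[match(side, mapping$motion)]
}

#' Correct response for a trial
#'
#' @param task `"motion"` or `"color"` (vectorised).
#' @param direction Coherent motion direction.
#' @param majority_color Majority uniform color.
#' @param mapping A [response_mapping()].
#' @return `"left"`/`"right"` vector.
#' @export
correct_response_for <- function(task, direction, majority_color,
                                 mapping = response_mapping()) {
  ifelse(task == "motion",
         unname(mapping$motion[direction]),
         unname(mapping$color[majority_color]))
}

#' Trial timing configuration
#'
#' Cued trials run blank (from the previous response), fixation (1000 ms),
#' cue (the cue-stimulus interval, CSI: 200 or 800 ms), then the stimulus.
#' The blank duration is `1000 - csi_ms`, so the response-stimulus interval
#' (RSI) is a constant 2000 ms for both CSIs, controlling the decay of
#' task-set inertia. Uncued trials (`csi_ms = NA`) run fixation then stimulus.
#'
#' @param csi_ms Cue-stimulus interval: 200, 800, or `NA` for uncued designs.
#' @param fixation_ms Fixation-cross duration.
#' @param max_stim_ms Maximum stimulus lifetime.
#' @return A list of class `rsk_timing` with derived `blank_ms` and `rsi_ms`.
#' @examples
#' timing_config(200)$rsi_ms
#' @export
timing_config <- function(csi_ms = NA, fixation_ms = 1000, max_stim_ms = 2000) {
  if (!is.na(csi_ms) && !csi_ms %in% c(200, 800)) {
    abort("`csi_ms` must be 200, 800, or NA")
  }
  blank_ms <- if (is.na(csi_ms)) NA_real_ else 1000 - csi_ms
  rsi_ms <- if (is.na(csi_ms)) NA_real_ else blank_ms + fixation_ms + csi_ms
  structure(
    list(csi_ms = csi_ms, fixation_ms = fixation_ms, max_stim_ms = max_stim_ms,
         blank_ms = blank_ms, rsi_ms = rsi_ms),
    class = "rsk_timing"
  )
}

#' Event timeline of one trial
#'
#' @param trial A one-row trial tibble (only `csi_ms` is consulted) or a list
#'   with a `csi_ms` element; may be omitted if `timing` is given directly.
#' @param timing A [timing_config()]; defaults to the trial's CSI.
#' @return A tibble with columns `event`, `onset_ms`, `duration_ms`. Onsets
#'   are relative to the previous trial's response (cued designs) or to trial
#'   start (uncued designs).
#' @examples
#' trial_timeline(list(csi_ms = 200))
#' @export
trial_timeline <- function(trial = NULL, timing = NULL) {
  if (is.null(timing)) {
    csi <- if (is.null(trial)) NA else trial$csi_ms[[1]]
    timing <- timing_config(csi_ms = csi)
  }
  if (is.na(timing$csi_ms)) {
    return(tibble(
      event = c("fixation", "stimulus"),
      onset_ms = c(0, timing$fixation_ms),
      duration_ms = c(timing$fixation_ms, timing$max_stim_ms)
    ))
  }
  blank <- timing$blank_ms
  tibble(
    event = c("blank", "fixation", "cue", "stimulus"),
    onset_ms = c(0, blank, blank + timing$fixation_ms,
                 blank + timing$fixation_ms + timing$csi_ms),
    duration_ms = c(blank, timing$fixation_ms, timing$csi_ms,
                    timing$max_stim_ms)
  )
}

#' Signed distractor congruence of bivalent trials
#'
#' Parametrizes the task-irrelevant dimension on a signed percentage scale:
#' the magnitude is the distractor dimension's coherence (in percent) and the
#' sign is positive iff the distractor maps, via the response mapping, to the
#' same response as the correct one. In the color task the distractor is
#' motion (10 coherence magnitudes x 2 signs = 20 levels on the standard
#' grid); in the motion task it is color (5 magnitudes x 2 signs = 10
#' levels).
#'
#' @param trials A trial tibble (plan or log rows). Must be bivalent.
#' @param mapping A [response_mapping()]; defaults to the plan's own mapping
#'   when `trials` is an `rsk_plan`.
#' @return Numeric vector of signed congruence in `[-95, 95]`.
#' @export
signed_distractor_congruence <- function(trials, mapping = NULL) {
  mapping <- mapping %||% attr(trials, "metadata")$mapping %||% response_mapping()
  univalent <- is.na(trials$congruent)
  if (any(univalent)) {
    abort("signed distractor congruence is undefined for univalent trials")
  }
  dist_coh <- ifelse(trials$task == "color",
                     trials$motion_coherence, trials$color_coherence)
  dist_side <- ifelse(trials$task == "color",
                      unname(mapping$motion[trials$direction]),
                      unname(mapping$color[trials$majority_color]))
  sign <- ifelse(dist_side == trials$correct_response, 1, -1)
  sign * dist_coh * 100
}

# ---- internal plan machinery -----------------------------------------------

new_plan <- function(trials, experiment, seed, mapping, extra = list()) {
  trials$block_first <- trials$trial_index == 1L
  meta <- c(list(experiment = experiment, seed = seed, mapping = mapping),
            extra)
  structure(as_tibble(trials), metadata = meta,
            class = c("rsk_plan", class(as_tibble(trials))))
}

#' @export
print.rsk_plan <- function(x, ...) {
  m <- attr(x, "metadata")
  cat(sprintf("<rsk_plan> experiment %s | %d trials in %d block(s) | seed %s\n",
              m$experiment, nrow(x), dplyr::n_distinct(x$block_index),
              format(m$seed)))
  NextMethod()
}

# Shuffle rows until every column in `run_cols` has max run <= max_run;
# deterministic under the current RNG state.
shuffle_with_constraints <- function(df, run_cols, max_run = 4L,
                                     max_attempts = 10000L) {
  for (attempt in seq_len(max_attempts)) {
    cand <- df[sample.int(nrow(df)), , drop = FALSE]
    ok <- all(vapply(run_cols,
                     function(col) max_run_length(cand[[col]]) <= max_run,
                     logical(1)))
    if (ok) return(cand)
  }
  abort(sprintf(
    "could not satisfy sequencing constraints (run <= %d on %s) in %d attempts",
    max_run, paste(run_cols, collapse = ", "), max_attempts))
}

# Deal rows randomly into consecutive blocks of `block_size`, then shuffle
# each block under the run constraint. Blocks are numbered from
# `first_block`.
deal_into_blocks <- function(df, block_size, run_cols, first_block = 1L) {
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  n_blocks <- nrow(df) %/% block_size
  df$block_index <- first_block - 1L + rep(seq_len(n_blocks), each = block_size)
  split(df, df$block_index) |>
    purrr::map(shuffle_with_constraints, run_cols = run_cols) |>
    dplyr::bind_rows()
}

add_congruent <- function(trials, mapping, bivalent = TRUE) {
  if (!bivalent) {
    trials$congruent <- NA
    return(trials)
  }
  dist_side <- ifelse(trials$task == "color",
                      unname(mapping$motion[trials$direction]),
                      unname(mapping$color[trials$majority_color]))
  trials$congruent <- dist_side == trials$correct_response
  trials
}

add_prev_congruent <- function(trials) {
  trials |>
    group_by(.data$block_index) |>
    mutate(congruency_n_minus_1 = dplyr::lag(.data$congruent)) |>
    ungroup()
}

motion_levels <- function() seq(0.05, 0.95, by = 0.10)
color_levels <- function() seq(0.55, 0.95, by = 0.10)

# ---- Experiment 1a ---------------------------------------------------------

#' Build the motion-psychometric design (Experiment 1a)
#'
#' Univalent motion task: 10 motion-coherence levels (5% to 95% in 10% steps)
#' crossed with the two uniform colors at 100% color coherence, six replicates
#' each (120 trials in two blocks of 60), with leftward and rightward motion
#' balanced and at most four consecutive trials requiring the same response.
#'
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @param color_mapping_flipped Counterbalancing flag for the color mapping
#'   (irrelevant to 1a responses, carried for bookkeeping).
#' @return An `rsk_plan` tibble, one row per trial.
#' @export
build_exp1a_design <- function(seed = 1L, color_mapping_flipped = FALSE) {
  mapping <- response_mapping(color_mapping_flipped)
  cells <- tidyr::expand_grid(
    motion_coherence = motion_levels(),
    majority_color = c("khaki", "white"),
    direction = c("leftward", "rightward"),
    rep = 1:3
  )
  cells$color_coherence <- 1
  cells$task <- "motion"
  trials <- with_rng_seed(seed, {
    cells$correct_response <- correct_response_for(
      cells$task, cells$direction, cells$majority_color, mapping)
    deal_into_blocks(cells, 60L, "correct_response")
  })
  trials <- trials |>
    group_by(.data$block_index) |>
    mutate(trial_index = dplyr::row_number()) |>
    ungroup() |>
    mutate(experiment = "1a", csi_ms = NA_real_, sequence_type = "single")
  trials <- add_congruent(trials, mapping, bivalent = FALSE)
  trials$congruency_n_minus_1 <- NA
  cols <- c("experiment", "block_index", "trial_index", "task",
            "motion_coherence", "direction", "color_coherence",
            "majority_color", "csi_ms", "sequence_type", "congruent",
            "congruency_n_minus_1", "correct_response")
  new_plan(trials[, cols], "1a", seed, mapping)
}

# ---- Experiment 1b ---------------------------------------------------------

#' Build the color-psychometric design (Experiment 1b)
#'
#' Univalent color task at 0% motion coherence: five color-coherence levels
#' (55% to 95%) for each majority uniform color, six replicates each (60
#' trials in one block), with at most four consecutive same-response trials.
#' With 0% motion coherence every agent follows its own random linear path;
#' the nominal direction label is balanced but inert.
#'
#' @inheritParams build_exp1a_design
#' @return An `rsk_plan`.
#' @export
build_exp1b_design <- function(seed = 1L, color_mapping_flipped = FALSE) {
  mapping <- response_mapping(color_mapping_flipped)
  cells <- tidyr::expand_grid(
    color_coherence = color_levels(),
    majority_color = c("khaki", "white"),
    direction = c("leftward", "rightward"),
    rep = 1:3
  )
  cells$motion_coherence <- 0
  cells$task <- "color"
  trials <- with_rng_seed(seed, {
    cells$correct_response <- correct_response_for(
      cells$task, cells$direction, cells$majority_color, mapping)
    deal_into_blocks(cells, 60L, "correct_response")
  })
  trials <- trials |>
    mutate(trial_index = dplyr::row_number(),
           experiment = "1b", csi_ms = NA_real_, sequence_type = "single")
  trials <- add_congruent(trials, mapping, bivalent = FALSE)
  trials$congruency_n_minus_1 <- NA
  cols <- c("experiment", "block_index", "trial_index", "task",
            "motion_coherence", "direction", "color_coherence",
            "majority_color", "csi_ms", "sequence_type", "congruent",
            "congruency_n_minus_1", "correct_response")
  new_plan(trials[, cols], "1b", seed, mapping)
}

# ---- Experiment 2 ----------------------------------------------------------

# The 100 unique bivalent stimuli: 10 motion levels x (5 color levels x 2
# majority colors). The coherent direction is assigned by the parity of
# (motion index + color index) within each majority color, which yields
# exactly 25 stimuli in each majority x direction quadrant and, under either
# color mapping, 50 congruent and 50 incongruent stimuli.
exp2_stimulus_grid <- function() {
  g <- tidyr::expand_grid(
    m_idx = 1:10,
    majority_color = c("khaki", "white"),
    c_idx = 1:5
  )
  g$motion_coherence <- motion_levels()[g$m_idx]
  g$color_coherence <- color_levels()[g$c_idx]
  g$direction <- ifelse((g$m_idx + g$c_idx) %% 2 == 0, "leftward", "rightward")
  g[, c("motion_coherence", "direction", "color_coherence", "majority_color")]
}

#' Build the orthogonal target/distractor design (Experiment 2)
#'
#' 100 unique bivalent stimuli (10 motion-coherence levels x 10
#' color-coherence conditions), each replicated four times per task: 400
#' trials per task in eight blocks of 50, as two single-task series ordered
#' by `first_task`. Congruent and incongruent stimuli are equally probable;
#' at most four consecutive trials share a response.
#'
#' @inheritParams build_exp1a_design
#' @param first_task Which task's series comes first.
#' @return An `rsk_plan`.
#' @export
build_exp2_design <- function(seed = 1L, first_task = c("motion", "color"),
                              color_mapping_flipped = FALSE) {
  first_task <- match.arg(first_task)
  mapping <- response_mapping(color_mapping_flipped)
  grid <- exp2_stimulus_grid()
  tasks <- c(first_task, setdiff(c("motion", "color"), first_task))
  trials <- with_rng_seed(seed, {
    purrr::imap(tasks, function(tk, pos) {
      t <- tidyr::expand_grid(grid, rep = 1:4)
      t$task <- tk
      t$correct_response <- correct_response_for(
        t$task, t$direction, t$majority_color, mapping)
      deal_into_blocks(t, 50L, "correct_response",
                       first_block = (pos - 1L) * 8L + 1L)
    }) |>
      dplyr::bind_rows()
  })
  trials <- trials |>
    group_by(.data$block_index) |>
    mutate(trial_index = dplyr::row_number()) |>
    ungroup() |>
    mutate(experiment = "2", csi_ms = NA_real_, sequence_type = "single")
  trials <- add_congruent(trials, mapping, bivalent = TRUE)
  trials <- add_prev_congruent(trials)
  cols <- c("experiment", "block_index", "trial_index", "task",
            "motion_coherence", "direction", "color_coherence",
            "majority_color", "csi_ms", "sequence_type", "congruent",
            "congruency_n_minus_1", "correct_response")
  new_plan(trials[, cols], "2", seed, mapping,
           extra = list(first_task = first_task))
}

# ---- Experiment 3 ----------------------------------------------------------

# One single-task block of 64 trials: response side x congruency balanced
# 16/16/16/16, all stimuli at 75/75 coherence.
exp3_single_block <- function(task, mapping) {
  cells <- tidyr::expand_grid(
    correct_response = c("left", "right"),
    congruent = c(TRUE, FALSE),
    rep = 1:16
  )
  cells$task <- task
  cells$block_index <- 1L
  out <- shuffle_with_constraints(cells, "correct_response")
  out$sequence_type <- "single"
  out
}

# Sample a 64-long switch/repeat type sequence with 32 of each, max run 4,
# whose induced task sequence (from prev_task) has 16 trials per task x type.
exp3_type_sequence <- function(prev_task, max_attempts = 10000L) {
  other <- function(t) ifelse(t == "motion", "color", "motion")
  for (attempt in seq_len(max_attempts)) {
    types <- sample(rep(c("switch", "repeat"), each = 32))
    if (max_run_length(types) > 4L) next
    tasks <- character(64)
    prev <- prev_task
    for (i in 1:64) {
      tasks[i] <- if (types[i] == "switch") other(prev) else prev
      prev <- tasks[i]
    }
    tab <- table(factor(tasks, c("motion", "color")),
                 factor(types, c("repeat", "switch")))
    if (all(tab == 16L)) {
      return(tibble(sequence_type = types, task = tasks))
    }
  }
  abort("could not generate a balanced mixed-block task sequence")
}

# One mixed block of 64 trials given the previous block's final task.
exp3_mixed_block <- function(prev_task, mapping, max_attempts = 1000L) {
  seqs <- exp3_type_sequence(prev_task)
  # assign response x congruency 4x within each task x type group
  for (attempt in seq_len(max_attempts)) {
    cells <- tidyr::expand_grid(correct_response = c("left", "right"),
                                congruent = c(TRUE, FALSE), rep = 1:4)
    out <- seqs
    out$correct_response <- NA_character_
    out$congruent <- NA
    for (tk in c("motion", "color")) {
      for (ty in c("repeat", "switch")) {
        sel <- which(out$task == tk & out$sequence_type == ty)
        perm <- cells[sample.int(16L), ]
        out$correct_response[sel] <- perm$correct_response
        out$congruent[sel] <- perm$congruent
      }
    }
    if (max_run_length(out$correct_response) <= 4L) {
      out$block_index <- 1L
      return(out)
    }
  }
  abort("could not satisfy the response run constraint in a mixed block")
}

# Derive stimulus features (direction, majority color) at 75/75 coherence
# from task, correct response and congruency.
exp3_fill_stimulus <- function(trials, mapping) {
  other_side <- ifelse(trials$correct_response == "left", "right", "left")
  dist_target_side <- ifelse(trials$congruent, trials$correct_response, other_side)
  trials$direction <- ifelse(
    trials$task == "motion",
    direction_for_side(trials$correct_response, mapping),
    direction_for_side(dist_target_side, mapping))
  trials$majority_color <- ifelse(
    trials$task == "color",
    color_for_side(trials$correct_response, mapping),
    color_for_side(dist_target_side, mapping))
  trials$motion_coherence <- 0.75
  trials$color_coherence <- 0.75
  trials
}

#' Build the cued task-switching design (Experiment 3)
#'
#' Sandwich design: two single-task blocks, eight mixed-task blocks, then two
#' single-task blocks mirroring the first two (same tasks, other CSI), 64
#' trials per block, every stimulus at 75% motion and 75% color coherence.
#' Mixed blocks hold 32 switch and 32 repeat trials, equally distributed
#' across tasks, with at most four consecutive trials of the same sequence
#' type or response; majority color, direction and congruency are balanced
#' within every block. The first trial of each mixed block is typed relative
#' to the previous block's final task, so the plan totals 256 single-task
#' (128 per task), 256 repeat and 256 switch trials. The CSI (200 or 800 ms)
#' is constant within a block and varies between blocks.
#'
#' @inheritParams build_exp2_design
#' @param csi_order Length-2 vector giving CSI "A" and "B" in ms; single-task
#'   blocks run A,B,...,A,B and mixed blocks follow `csi_pattern`, so each
#'   task x CSI cell holds 64 single-task trials.
#' @param csi_pattern Assignment of CSIs A/B to the eight mixed blocks:
#'   `"ABBA"` (A,B,B,A,A,B,B,A, the default) or `"AABB"`, or an explicit
#'   length-8 vector of CSI values in ms.
#' @return An `rsk_plan`.
#' @export
build_exp3_design <- function(seed = 1L, first_task = c("motion", "color"),
                              csi_order = c(200, 800), csi_pattern = "ABBA",
                              color_mapping_flipped = FALSE) {
  first_task <- match.arg(first_task)
  stopifnot(length(csi_order) == 2, all(csi_order %in% c(200, 800)),
            csi_order[1] != csi_order[2])
  mixed_csi <- if (is.character(csi_pattern)) {
    idx <- switch(csi_pattern,
                  ABBA = c(1, 2, 2, 1, 1, 2, 2, 1),
                  AABB = c(1, 1, 2, 2, 1, 1, 2, 2),
                  abort("`csi_pattern` must be \"ABBA\", \"AABB\" or 8 CSI values"))
    csi_order[idx]
  } else {
    stopifnot(length(csi_pattern) == 8, all(csi_pattern %in% c(200, 800)))
    csi_pattern
  }
  mapping <- response_mapping(color_mapping_flipped)
  second_task <- setdiff(c("motion", "color"), first_task)
  block_tasks <- c(first_task, second_task, rep(NA, 8), second_task, first_task)
  block_csi <- c(csi_order[1], csi_order[2], mixed_csi,
                 csi_order[1], csi_order[2])

  blocks <- with_rng_seed(seed, {
    out <- vector("list", 12)
    prev_task <- NULL
    for (b in 1:12) {
      if (!is.na(block_tasks[b])) {
        bl <- exp3_single_block(block_tasks[b], mapping)
      } else {
        bl <- exp3_mixed_block(prev_task, mapping)
      }
      bl$block_index <- b
      bl$csi_ms <- block_csi[b]
      prev_task <- tail(bl$task, 1)
      out[[b]] <- bl
    }
    dplyr::bind_rows(out)
  })

  trials <- exp3_fill_stimulus(blocks, mapping) |>
    group_by(.data$block_index) |>
    mutate(trial_index = dplyr::row_number()) |>
    ungroup() |>
    mutate(experiment = "3")
  trials <- add_prev_congruent(trials)
  cols <- c("experiment", "block_index", "trial_index", "task",
            "motion_coherence", "direction", "color_coherence",
            "majority_color", "csi_ms", "sequence_type", "congruent",
            "congruency_n_minus_1", "correct_response")
  new_plan(trials[, cols], "3", seed, mapping,
           extra = list(first_task = first_task, csi_order = csi_order,
                        mixed_csi = mixed_csi))
}

# ---- counterbalancing ------------------------------------------------------

#' Enumerate balanced participant-level counterbalancing
#'
#' Cycles task order, color-mapping flip and CSI order over participants.
#'
#' @param n Number of participants.
#' @return A tibble with `participant_id`, `first_task`,
#'   `color_mapping_flipped`, `csi_first` (the CSI of the first block, ms).
#' @export
counterbalance_participants <- function(n) {
  combos <- tidyr::expand_grid(
    first_task = c("motion", "color"),
    color_mapping_flipped = c(FALSE, TRUE),
    csi_first = c(200, 800)
  )
  idx <- rep_len(seq_len(nrow(combos)), n)
  out <- combos[idx, ]
  out$participant_id <- seq_len(n)
  out[, c("participant_id", "first_task", "color_mapping_flipped", "csi_first")]
}

# ---- validation ------------------------------------------------------------

check_row <- function(check, value, expected, pass = value == expected) {
  tibble(check = check, value = as.numeric(value),
         expected = as.numeric(expected), pass = pass)
}

#' Validate an experiment plan against its design constraints
#'
#' Report-only constraint checker: counts per condition cell, maximum run
#' lengths (response key, sequence type), switch/repeat balance and coherence
#' grids, flagging every violated constraint of the plan's experiment.
#'
#' @param plan An `rsk_plan`.
#' @return A tibble with columns `check`, `value`, `expected`, `pass`;
#'   attribute `n_violations` counts failed checks.
#' @export
validate_plan <- function(plan) {
  m <- attr(plan, "metadata")
  exp <- m$experiment %||% plan$experiment[1]
  checks <- list()
  run_resp <- plan |>
    group_by(.data$block_index) |>
    summarise(r = max_run_length(.data$correct_response), .groups = "drop")
  checks[[length(checks) + 1]] <-
    check_row("max response run <= 4", max(run_resp$r), 4,
              pass = max(run_resp$r) <= 4)

  if (exp == "1a") {
    checks[[length(checks) + 1]] <- check_row("n trials", nrow(plan), 120)
    checks[[length(checks) + 1]] <-
      check_row("leftward trials", sum(plan$direction == "leftward"), 60)
    lev <- table(plan$motion_coherence)
    checks[[length(checks) + 1]] <-
      check_row("each motion level x12", min(lev), 12,
                pass = all(lev == 12) && length(lev) == 10)
    checks[[length(checks) + 1]] <-
      check_row("full color coherence", min(plan$color_coherence), 1)
  } else if (exp == "1b") {
    checks[[length(checks) + 1]] <- check_row("n trials", nrow(plan), 60)
    checks[[length(checks) + 1]] <-
      check_row("motion coherence 0", max(plan$motion_coherence), 0)
    checks[[length(checks) + 1]] <-
      check_row("khaki-majority trials", sum(plan$majority_color == "khaki"), 30)
  } else if (exp == "2") {
    per_task <- table(plan$task)
    checks[[length(checks) + 1]] <-
      check_row("trials per task", min(per_task), 400,
                pass = all(per_task == 400))
    bl <- table(plan$block_index)
    checks[[length(checks) + 1]] <-
      check_row("blocks of 50", min(bl), 50,
                pass = all(bl == 50) && length(bl) == 16)
    quad <- plan |>
      distinct(.data$motion_coherence, .data$direction,
               .data$color_coherence, .data$majority_color) |>
      count(.data$majority_color, .data$direction)
    checks[[length(checks) + 1]] <-
      check_row("25 unique stimuli per quadrant", min(quad$n), 25,
                pass = all(quad$n == 25) && nrow(quad) == 4)
    checks[[length(checks) + 1]] <-
      check_row("congruent trials", sum(plan$congruent), nrow(plan) / 2)
    sc_color <- dplyr::n_distinct(
      signed_distractor_congruence(plan[plan$task == "color", ], m$mapping))
    sc_motion <- dplyr::n_distinct(
      signed_distractor_congruence(plan[plan$task == "motion", ], m$mapping))
    checks[[length(checks) + 1]] <-
      check_row("signed congruence levels (color task)", sc_color, 20)
    checks[[length(checks) + 1]] <-
      check_row("signed congruence levels (motion task)", sc_motion, 10)
  } else if (exp == "3") {
    checks[[length(checks) + 1]] <- check_row("n trials", nrow(plan), 768)
    st <- table(factor(plan$sequence_type, c("single", "repeat", "switch")))
    for (ty in names(st)) {
      checks[[length(checks) + 1]] <-
        check_row(paste0("total ", ty, " trials"), st[[ty]], 256)
    }
    per_task_single <- table(plan$task[plan$sequence_type == "single"])
    checks[[length(checks) + 1]] <-
      check_row("single trials per task", min(per_task_single), 128,
                pass = all(per_task_single == 128))
    mixed <- plan[!plan$sequence_type %in% "single", ]
    mb <- mixed |> count(.data$block_index, .data$sequence_type)
    checks[[length(checks) + 1]] <-
      check_row("32 switch + 32 repeat per mixed block", min(mb$n), 32,
                pass = all(mb$n == 32))
    tt <- mixed |> count(.data$block_index, .data$task)
    checks[[length(checks) + 1]] <-
      check_row("tasks balanced per mixed block", min(tt$n), 32,
                pass = all(tt$n == 32))
    run_type <- mixed |>
      group_by(.data$block_index) |>
      summarise(r = max_run_length(.data$sequence_type), .groups = "drop")
    checks[[length(checks) + 1]] <-
      check_row("max sequence-type run <= 4", max(run_type$r), 4,
                pass = max(run_type$r) <= 4)
    checks[[length(checks) + 1]] <-
      check_row("75% motion coherence", unique(plan$motion_coherence), 0.75,
                pass = all(plan$motion_coherence == 0.75))
    checks[[length(checks) + 1]] <-
      check_row("75% color coherence", unique(plan$color_coherence), 0.75,
                pass = all(plan$color_coherence == 0.75))
    bal <- plan |>
      group_by(.data$block_index) |>
      summarise(left_dir = sum(.data$direction == "leftward"),
                khaki = sum(.data$majority_color == "khaki"),
                cong = sum(.data$congruent), .groups = "drop")
    checks[[length(checks) + 1]] <-
      check_row("direction equiprobable per block", min(bal$left_dir), 32,
                pass = all(bal$left_dir == 32))
    checks[[length(checks) + 1]] <-
      check_row("majority color equiprobable per block", min(bal$khaki), 32,
                pass = all(bal$khaki == 32))
    checks[[length(checks) + 1]] <-
      check_row("congruency 1:1 per block", min(bal$cong), 32,
                pass = all(bal$cong == 32))
  }
  out <- dplyr::bind_rows(checks)
  structure(out, n_violations = sum(!out$pass))
}
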