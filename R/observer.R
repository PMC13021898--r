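# Synthetic observer: a single-stage drift-diffusion process with additive
# reaction-time penalties and lapse-style accuracy penalties. The generative
# model is deliberately simple; its job is to reproduce the qualitative
# behavioural regularities of the paradigm (psychometric monotonicity,
# color-task-only distractor effects, switch/mixing costs, preparation
# benefits, inertia-driven switch-cost asymmetry) so the analysis pipeline can
# be exercised end-to-end and injected parameters can be recovered.

#' Observer parameters
#'
#' Drift gains are in evidence units per second per unit signed coherence;
#' the decision variable starts at 0 and terminates at `+boundary` (right
#' response) or `-boundary` (left response). RT penalties are additive in
#' milliseconds, so mean-difference cost estimators recover them exactly in
#' expectation; lapse-style parameters inject errors (a lapse replaces the
#' response by a fair coin but keeps the diffusion RT, leaving mean RT and
#' the RT-penalty recovery untouched).
#'
#' @param k_target_motion,k_target_color Drift gain per unit signed target
#'   coherence in each task (1/s).
#' @param k_distractor_in_color_task,k_distractor_in_motion_task Drift gain
#'   per unit signed distractor coherence. The motion task's default of 0
#'   encodes task dominance: task-irrelevant color does not activate
#'   responses, while task-irrelevant motion does.
#' @param boundary Decision threshold (evidence units).
#' @param noise_sd Diffusion coefficient (evidence / sqrt(s)).
#' @param t0_ms Non-decision time (ms).
#' @param mixed_block_penalty_ms Added to every mixed-block trial (sustained
#'   task-set maintenance; the source of the mixing cost).
#' @param switch_penalty_ms Added to switch trials (task-set reconfiguration;
#'   the source of the switch cost).
#' @param inertia_penalty_ms Added when switching TO the dominant motion task
#'   after an incongruent trial (persisting inhibition of the dominant task;
#'   the source of the switch-cost asymmetry).
#' @param csi_benefit_ms Subtracted from every mixed-block trial at the long
#'   CSI (preparation benefit, applied equally to repeat and switch trials).
#' @param lapse_rate Baseline probability of a uniform random response.
#' @param switch_lapse_rate Extra lapse probability on switch trials (the
#'   source of the error cost, constant across CSIs).
#' @param mixing_lapse_rate_short,mixing_lapse_rate_long Extra lapse
#'   probability on mixed-block trials at the short / long CSI (the source of
#'   the ER-mixing cost and its preparatory reduction).
#'
#' @return A list of class `rsk_observer_params`.
#' @examples
#' observer_params()
#' @export
observer_params <- function(k_target_motion = 10,
                            k_target_color = 7,
                            k_distractor_in_color_task = 1.5,
                            k_distractor_in_motion_task = 0,
                            boundary = 1,
                            noise_sd = 1,
                            t0_ms = 300,
                            mixed_block_penalty_ms = 90,
                            switch_penalty_ms = 40,
                            inertia_penalty_ms = 35,
                            csi_benefit_ms = 60,
                            lapse_rate = 0.02,
                            switch_lapse_rate = 0.06,
                            mixing_lapse_rate_short = 0.05,
                            mixing_lapse_rate_long = 0.005) {
  p <- list(
    k_target_motion = k_target_motion, k_target_color = k_target_color,
    k_distractor_in_color_task = k_distractor_in_color_task,
    k_distractor_in_motion_task = k_distractor_in_motion_task,
    boundary = boundary, noise_sd = noise_sd, t0_ms = t0_ms,
    mixed_block_penalty_ms = mixed_block_penalty_ms,
    switch_penalty_ms = switch_penalty_ms,
    inertia_penalty_ms = inertia_penalty_ms,
    csi_benefit_ms = csi_benefit_ms,
    lapse_rate = lapse_rate,
    switch_lapse_rate = switch_lapse_rate,
    mixing_lapse_rate_short = mixing_lapse_rate_short,
    mixing_lapse_rate_long = mixing_lapse_rate_long
  )
  assert_that(p$boundary > 0, "`boundary` must be positive")
  assert_that(p$noise_sd >= 0, "`noise_sd` must be non-negative")
  assert_that(p$t0_ms >= 0, "`t0_ms` must be non-negative")
  assert_that(all(c(p$mixed_block_penalty_ms, p$switch_penalty_ms,
                    p$inertia_penalty_ms, p$csi_benefit_ms) >= 0),
              "penalties and benefits must be non-negative")
  assert_that(p$lapse_rate >= 0 && p$lapse_rate <= 0.1,
              "`lapse_rate` must lie in [0, 0.1]")
  assert_that(all(c(p$switch_lapse_rate, p$mixing_lapse_rate_short,
                    p$mixing_lapse_rate_long) >= 0),
              "lapse rates must be non-negative")
  structure(p, class = "rsk_observer_params")
}

#' Default observer parameters
#'
#' The documented defaults of [observer_params()]: drift gains encode task
#' dominance (`k_distractor_in_motion_task = 0`, positive distractor gain in
#' the color task only), positive switch/mixing/inertia penalties, a CSI
#' benefit applied equally to repeat and switch trials, and lapse parameters
#' generating error costs and an ER-mixing cost that shrinks with
#' preparation. Regenerating the synthetic study and running the analysis
#' pipeline under these defaults reproduces the paradigm's qualitative cost
#' pattern.
#'
#' @return An `rsk_observer_params` object.
#' @export
default_observer_params <- function() observer_params()

#' Drift rate of the diffusion process for each trial
#'
#' `v = k_task * s_target + k_distractor * s_distractor`, where `s_target` is
#' the signed target coherence (positive when the correct response is right)
#' and `s_distractor` the signed distractor coherence (positive when the
#' distractor maps to the right key). An absent dimension (zero coherence)
#' contributes nothing.
#'
#' @param trials A trial tibble (plan rows).
#' @param params An [observer_params()].
#' @param mapping A [response_mapping()]; defaults to the plan's own.
#' @return Numeric drift rates (evidence/s), positive toward the right
#'   boundary.
#' @export
drift_rate <- function(trials, params = observer_params(), mapping = NULL) {
  mapping <- mapping %||% attr(trials, "metadata")$mapping %||% response_mapping()
  target_coh <- ifelse(trials$task == "motion",
                       trials$motion_coherence, trials$color_coherence)
  s_target <- target_coh * ifelse(trials$correct_response == "right", 1, -1)
  dist_coh <- ifelse(trials$task == "motion",
                     trials$color_coherence, trials$motion_coherence)
  dist_side <- ifelse(trials$task == "motion",
                      unname(mapping$color[trials$majority_color]),
                      unname(mapping$motion[trials$direction]))
  s_dist <- dist_coh * ifelse(dist_side == "right", 1, -1)
  k_t <- ifelse(trials$task == "motion",
                params$k_target_motion, params$k_target_color)
  k_d <- ifelse(trials$task == "motion",
                params$k_distractor_in_motion_task,
                params$k_distractor_in_color_task)
  k_t * s_target + k_d * s_dist
}

# Additive RT penalty (ms) per trial, from the plan's sequence bookkeeping.
# Inertia applies when switching TO the motion task right after an
# incongruent trial; block-first trials have no previous-trial context.
observer_penalty_ms <- function(trials, params) {
  mixed <- trials$sequence_type %in% c("repeat", "switch")
  is_switch <- trials$sequence_type == "switch"
  prev_incongruent <- !is.na(trials$congruency_n_minus_1) &
    !trials$congruency_n_minus_1
  inertia <- is_switch & trials$task == "motion" & prev_incongruent
  long_csi <- !is.na(trials$csi_ms) & trials$csi_ms == 800
  params$mixed_block_penalty_ms * mixed +
    params$switch_penalty_ms * is_switch +
    params$inertia_penalty_ms * inertia -
    params$csi_benefit_ms * (mixed & long_csi)
}

# Lapse probability per trial.
observer_lapse_prob <- function(trials, params) {
  mixed <- trials$sequence_type %in% c("repeat", "switch")
  long_csi <- !is.na(trials$csi_ms) & trials$csi_ms == 800
  p <- params$lapse_rate +
    params$switch_lapse_rate * (trials$sequence_type == "switch") +
    ifelse(mixed & !long_csi, params$mixing_lapse_rate_short, 0) +
    ifelse(mixed & long_csi, params$mixing_lapse_rate_long, 0)
  pmin(p, 1)
}

# Vectorised first-passage times of Euler-discretised (1 ms) diffusions
# through +/-boundary. Returns list(step = integer first-crossing step or NA,
# sign = +1/-1). `max_steps` may vary per trial (decision window).
diffusion_first_passage <- function(v, max_steps, boundary, noise_sd,
                                    dt = 1e-3, chunk = 256L) {
  n <- length(v)
  step_no <- rep(NA_integer_, n)
  sgn <- rep(NA_real_, n)
  x <- numeric(n)
  done_steps <- 0L
  active <- seq_len(n)
  overall_max <- max(max_steps)
  while (length(active) > 0 && done_steps < overall_max) {
    k <- min(chunk, overall_max - done_steps)
    inc <- matrix(rnorm(k * length(active), mean = 0, sd = noise_sd * sqrt(dt)),
                  nrow = k)
    inc <- sweep(inc, 2, v[active] * dt, `+`)
    paths <- apply(inc, 2, cumsum)
    if (k == 1L) paths <- matrix(paths, nrow = 1)
    paths <- sweep(paths, 2, x[active], `+`)
    crossed <- abs(paths) >= boundary
    any_crossed <- colSums(crossed) > 0
    first <- rep(NA_integer_, length(active))
    if (any(any_crossed)) {
      first[any_crossed] <- max.col(t(crossed[, any_crossed, drop = FALSE]),
                                    ties.method = "first")
    }
    # a crossing only counts if it falls inside the trial's own window
    global_first <- done_steps + first
    valid <- any_crossed & !is.na(first) & global_first <= max_steps[active]
    if (any(valid)) {
      ids <- active[valid]
      step_no[ids] <- global_first[valid]
      sgn[ids] <- sign(paths[cbind(first[valid], which(valid))])
    }
    # trials whose window ends inside this chunk and did not cross time out
    x[active] <- paths[k, ]
    done_steps <- done_steps + k
    still <- is.na(step_no[active]) & max_steps[active] > done_steps
    active <- active[still]
  }
  list(step = step_no, sign = sgn)
}

#' Simulate one trial
#'
#' First passage of a 1-ms Euler drift-diffusion through the response
#' boundaries gives the decision time and response sign; the reaction time is
#' decision time + non-decision time + applicable additive penalties
#' (mixed-block, switch, inertia, minus the CSI benefit), floored at the
#' non-decision time. If the process does not cross within
#' `max_stim_ms - net penalty`, the trial times out (no response, scored as
#' an error). With probability equal to the trial's lapse rate the response
#' is replaced by a fair coin.
#'
#' @param trial A one-row trial tibble (plan row).
#' @param params An [observer_params()].
#' @param seed Integer seed for this trial.
#' @param mapping Optional [response_mapping()].
#' @param max_stim_ms Maximum stimulus lifetime (ms).
#' @return The trial row with `rt_ms`, `response`, `correct`, `timeout`
#'   filled.
#' @export
simulate_trial <- function(trial, params = observer_params(), seed = 1L,
                           mapping = NULL, max_stim_ms = 2000) {
  with_rng_seed(seed, simulate_trials_impl(trial, params, mapping, max_stim_ms))
}

simulate_trials_impl <- function(trials, params, mapping = NULL,
                                 max_stim_ms = 2000) {
  v <- drift_rate(trials, params, mapping)
  penalty <- observer_penalty_ms(trials, params)
  window <- pmax(1L, as.integer(round(max_stim_ms - pmax(penalty, 0))))
  fp <- diffusion_first_passage(v, window, params$boundary, params$noise_sd)
  timeout <- is.na(fp$step)
  response <- ifelse(fp$sign > 0, "right", "left")
  # lapses: replace the response with a fair coin, keep the diffusion RT
  lapse_p <- observer_lapse_prob(trials, params)
  lapse <- runif(nrow(trials)) < lapse_p & !timeout
  coin <- sample(c("left", "right"), nrow(trials), replace = TRUE)
  response[lapse] <- coin[lapse]
  response[timeout] <- NA_character_
  rt <- pmax(fp$step + params$t0_ms + penalty, params$t0_ms)
  rt[timeout] <- NA_real_
  out <- trials
  out$response <- response
  out$rt_ms <- rt
  out$correct <- !timeout & response == trials$correct_response
  out$timeout <- timeout
  out
}

#' Simulate a full participant over an experiment plan
#'
#' Iterates the plan in order (vectorised internally), filling `rt_ms`,
#' `response`, `correct` and `timeout` for every trial. Previous-trial
#' context (task, congruency) is taken from the plan's own sequence
#' bookkeeping, which resets at block boundaries. Deterministic given the
#' seed.
#'
#' @param plan An `rsk_plan`.
#' @param params An [observer_params()].
#' @param seed Integer seed.
#' @param participant_id Value for the `participant_id` column.
#' @return The completed trial log (tibble, same metadata as the plan).
#' @examples
#' plan <- build_exp1b_design(seed = 1)
#' log <- simulate_participant(plan, observer_params(), seed = 2)
#' mean(log$correct)
#' @export
simulate_participant <- function(plan, params = observer_params(), seed = 1L,
                                 participant_id = 1L) {
  meta <- attr(plan, "metadata")
  out <- with_rng_seed(seed, {
    simulate_trials_impl(as_tibble(plan), params,
                         mapping = meta$mapping)
  })
  out$participant_id <- participant_id
  out <- out[, c("participant_id", setdiff(names(out), "participant_id"))]
  structure(out, metadata = meta, class = class(plan))
}
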