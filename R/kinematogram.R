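#' Arena configuration for the RSK stimulus
#'
#' Geometry and timing of the simulation plane. The stimulus is simulated in a
#' square arena expressed in degrees of visual angle; agents ("soldiers") move
#' on fixed linear paths and are re-drawn on the opposite side when they cross
#' a boundary, so crowd density is conserved throughout a trial.
#'
#' @param side_deg Side length of the square arena, degrees of visual angle.
#' @param fps Frame rate of the simulation, frames per second.
#' @param speed_deg_s Translational speed of every agent, degrees per second.
#' @param n_agents Number of agents in the crowd.
#' @param duration_ms Maximum stimulus lifetime in milliseconds (the stimulus
#'   is extinguished at response time in the experiment; the simulator always
#'   produces the full lifetime).
#'
#' @return A list of class `rsk_arena`.
#' @examples
#' arena_config()
#' @export
arena_config <- function(side_deg = 18, fps = 75, speed_deg_s = 5,
                         n_agents = 100, duration_ms = 2000) {
  assert_that(side_deg > 0, "`side_deg` must be positive")
  assert_that(fps > 0, "`fps` must be positive")
  assert_that(speed_deg_s >= 0, "`speed_deg_s` must be non-negative")
  assert_that(n_agents >= 2, "`n_agents` must be at least 2")
  assert_that(duration_ms > 0, "`duration_ms` must be positive")
  structure(
    list(side_deg = side_deg, fps = fps, speed_deg_s = speed_deg_s,
         n_agents = as.integer(n_agents), duration_ms = duration_ms,
         step_deg = speed_deg_s / fps),
    class = "rsk_arena"
  )
}

#' Stimulus specification for one RSK trial
#'
#' One RSK stimulus is fully described by a motion coherence (fraction of
#' agents translating in the common horizontal direction), that direction, a
#' color coherence (fraction of agents bearing the majority uniform color),
#' the majority color, and an RNG seed. The seed fully determines the
#' stimulus.
#'
#' @param motion_coherence Fraction in `[0, 1]` of coherently moving agents.
#' @param direction `"leftward"` or `"rightward"`: the coherent direction.
#' @param color_coherence Fraction in `[0.5, 1]` of majority-color agents.
#' @param majority_color `"khaki"` or `"white"`.
#' @param seed Integer seed; identical seeds give byte-identical stimuli.
#'
#' @return A list of class `rsk_stimulus_spec`.
#' @examples
#' stimulus_spec(0.75, "leftward", 0.75, "white", seed = 1)
#' @export
stimulus_spec <- function(motion_coherence, direction = c("leftward", "rightward"),
                          color_coherence = 1, majority_color = c("khaki", "white"),
                          seed = 1L) {
  direction <- match.arg(direction)
  majority_color <- match.arg(majority_color)
  if (!is.numeric(motion_coherence) || motion_coherence < 0 || motion_coherence > 1) {
    abort("`motion_coherence` must lie in [0, 1]")
  }
  if (!is.numeric(color_coherence) || color_coherence < 0.5 || color_coherence > 1) {
    abort("`color_coherence` must lie in [0.5, 1]")
  }
  structure(
    list(motion_coherence = motion_coherence, direction = direction,
         color_coherence = color_coherence, majority_color = majority_color,
         seed = as.integer(seed)),
    class = "rsk_stimulus_spec"
  )
}

#' Initialise the agent crowd for one stimulus
#'
#' Exactly `round(motion_coherence * n_agents)` agents are coherent, heading 0
#' (rightward) or pi (leftward); the remainder receive headings drawn
#' uniformly on `[0, 2*pi)` that stay fixed for the whole trial (linear
#' paths). Exactly `round(color_coherence * n_agents)` agents carry the
#' majority color; color assignment is an independent random permutation
#' relative to motion-group membership. Initial positions are i.i.d. uniform
#' in the arena.
#'
#' @param spec An [stimulus_spec()].
#' @param config An [arena_config()].
#'
#' @return A tibble with one row per agent: `agent_id`, `x`, `y` (degrees),
#'   `heading` (radians), `color`, `is_coherent`.
#' @examples
#' agents <- init_agents(stimulus_spec(0.75, "leftward", 0.75, "white"), arena_config())
#' sum(agents$is_coherent)
#' @export
init_agents <- function(spec, config = arena_config()) {
  stopifnot(inherits(spec, "rsk_stimulus_spec"), inherits(config, "rsk_arena"))
  n <- config$n_agents
  n_coh <- as.integer(round_half_up(spec$motion_coherence * n))
  n_maj <- as.integer(round_half_up(spec$color_coherence * n))

  withr_seed <- spec$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(withr_seed)

  coherent_heading <- if (spec$direction == "rightward") 0 else pi
  heading <- c(rep(coherent_heading, n_coh), runif(n - n_coh, 0, 2 * pi))
  is_coherent <- c(rep(TRUE, n_coh), rep(FALSE, n - n_coh))

  minority <- if (spec$majority_color == "khaki") "white" else "khaki"
  color <- sample(c(rep(spec$majority_color, n_maj), rep(minority, n - n_maj)))

  tibble(
    agent_id = seq_len(n),
    x = runif(n, 0, config$side_deg),
    y = runif(n, 0, config$side_deg),
    heading = heading,
    color = color,
    is_coherent = is_coherent
  )
}

#' Advance the crowd by one frame
#'
#' Each agent translates by `speed_deg_s / fps` along its fixed heading;
#' coordinates wrap toroidally (agents leaving one side re-enter on the
#' opposite side with identity, color and heading preserved), conserving
#' crowd density.
#'
#' @param agents Agent tibble from [init_agents()] (or a previous step).
#' @param config An [arena_config()].
#'
#' @return The agent tibble after one frame.
#' @export
step_agents <- function(agents, config = arena_config()) {
  step <- config$step_deg
  agents$x <- wrap_coord(agents$x + step * cos(agents$heading), config$side_deg)
  agents$y <- wrap_coord(agents$y + step * sin(agents$heading), config$side_deg)
  agents
}

#' Simulate the full frame sequence of one RSK stimulus
#'
#' Produces `round(duration_ms / 1000 * fps)` frames (150 at the defaults:
#' 2000 ms at 75 Hz). Every frame contains exactly `n_agents` agents; the
#' result is bit-reproducible given the spec's seed.
#'
#' @inheritParams init_agents
#'
#' @return A tibble of class `rsk_frames` in long format with columns `frame`,
#'   `agent_id`, `x`, `y`, `heading`, `color`, `is_coherent`, carrying the
#'   spec and config as attributes `spec` and `config`.
#' @examples
#' frames <- simulate_stimulus(stimulus_spec(1, "rightward"), arena_config())
#' dplyr::n_distinct(frames$frame)
#' @export
simulate_stimulus <- function(spec, config = arena_config()) {
  n_frames <- as.integer(round_half_up(config$duration_ms / 1000 * config$fps))
  agents <- init_agents(spec, config)
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    out[[f]] <- dplyr::bind_cols(tibble(frame = f), agents)
    if (f < n_frames) agents <- step_agents(agents, config)
  }
  frames <- dplyr::bind_rows(out)
  structure(frames, spec = spec, config = config,
            class = c("rsk_frames", class(frames)))
}

#' Estimate motion coherence from simulated trajectories
#'
#' Self-check oracle: computes wrap-corrected frame-to-frame displacements and
#' returns the fraction of agents whose path is exactly horizontal (to within
#' floating-point tolerance) in the modal horizontal direction. Under
#' continuous uniform noise headings, a noise agent is exactly horizontal with
#' probability zero, so the estimate equals the nominal coherence.
#'
#' @param frames An `rsk_frames` tibble from [simulate_stimulus()].
#' @param tol Tolerance in degrees on the vertical displacement component.
#'
#' @return A single number: the estimated motion-coherence fraction.
#' @export
measure_motion_coherence <- function(frames, tol = 1e-9) {
  if (dplyr::n_distinct(frames$frame) < 2) {
    abort("at least two frames are required to measure motion coherence")
  }
  config <- attr(frames, "config")
  side <- config$side_deg
  f12 <- frames[frames$frame %in% c(1L, 2L), , drop = FALSE]
  w <- tidyr::pivot_wider(
    as_tibble(f12)[, c("frame", "agent_id", "x", "y")],
    names_from = "frame", values_from = c("x", "y")
  )
  dx <- wrap_delta(w$x_2 - w$x_1, side)
  dy <- wrap_delta(w$y_2 - w$y_1, side)
  horizontal <- abs(dy) < tol & abs(dx) > 0
  if (!any(horizontal)) return(0)
  modal_sign <- sign(sum(sign(dx[horizontal])))
  if (modal_sign == 0) modal_sign <- 1
  mean(horizontal & sign(dx) == modal_sign)
}

#' Measure translational speed of the coherent agents
#'
#' Mean wrap-corrected per-frame displacement of coherently moving agents
#' multiplied by the frame rate, in degrees per second.
#'
#' @inheritParams measure_motion_coherence
#' @return Speed in deg/s.
#' @export
measure_agent_speed <- function(frames) {
  config <- attr(frames, "config")
  side <- config$side_deg
  coh_ids <- unique(frames$agent_id[frames$is_coherent])
  if (length(coh_ids) == 0) abort("no coherent agents in these frames")
  sub <- as_tibble(frames)[frames$agent_id %in% coh_ids,
                           c("frame", "agent_id", "x", "y")]
  sub <- dplyr::arrange(sub, .data$agent_id, .data$frame)
  by_agent <- dplyr::group_by(sub, .data$agent_id)
  disp <- dplyr::summarise(
    by_agent,
    d = mean(sqrt(wrap_delta(diff(.data$x), side)^2 +
                  wrap_delta(diff(.data$y), side)^2)),
    .groups = "drop"
  )
  mean(disp$d) * config$fps
}

#' Export a frame sequence as a plain trajectory table
#'
#' @param frames An `rsk_frames` object.
#' @param path File to write (CSV).
#' @return The path, invisibly.
#' @export
write_trajectories <- function(frames, path) {
  out <- as_tibble(frames)
  names(out) <- c("frame", "agent_id", "x_deg", "y_deg", "heading_rad",
                  "color", "is_coherent")
  readr::write_csv(out, path)
  invisible(path)
}

#' @export
print.rsk_frames <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf(
    "<rsk_frames> %d frames x %d agents | motion %.0f%% %s, color %.0f%% %s\n",
    dplyr::n_distinct(x$frame), dplyr::n_distinct(x$agent_id),
    100 * spec$motion_coherence, spec$direction,
    100 * spec$color_coherence, spec$majority_color))
  NextMethod()
}

#' Plot one frame of an RSK stimulus
#'
#' @param object An `rsk_frames` object.
#' @param frame Which frame to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rsk_frames <- function(object, frame = 1, ...) {
  config <- attr(object, "config")
  d <- as_tibble(object)[object$frame == frame, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  color = .data$color,
                                  shape = .data$is_coherent)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_manual(values = c(khaki = "#8a7f45", white = "grey70")) +
    ggplot2::coord_fixed(xlim = c(0, config$side_deg),
                         ylim = c(0, config$side_deg)) +
    ggplot2::labs(x = "x (deg)", y = "y (deg)",
                  shape = "coherent", color = "uniform") +
    ggplot2::theme_minimal()
}
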