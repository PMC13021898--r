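# Statistical pipeline: cleaning, transforms, target/distractor regressions,
# cost estimators, chance-level tests, switch-cost asymmetry.

#' Trial-cleaning configuration
#'
#' Defaults follow the paradigm's conventions: responses faster than 200 ms
#' and the first trial of each block are discarded from all analyses; for RT
#' analyses incorrect responses are further excluded; timeouts count as
#' errors.
#'
#' @param min_rt_ms Fast-guess threshold in ms.
#' @param drop_block_first Discard the first trial of every block.
#' @param errors_excluded_from_rt Exclude incorrect trials from the RT log.
#' @param timeouts_as_errors Score non-responses as errors in the accuracy
#'   log.
#' @return A list of class `rsk_cleaning`.
#' @export
cleaning_config <- function(min_rt_ms = 200, drop_block_first = TRUE,
                            errors_excluded_from_rt = TRUE,
                            timeouts_as_errors = TRUE) {
  assert_that(min_rt_ms >= 0, "`min_rt_ms` must be non-negative")
  structure(list(min_rt_ms = min_rt_ms, drop_block_first = drop_block_first,
                 errors_excluded_from_rt = errors_excluded_from_rt,
                 timeouts_as_errors = timeouts_as_errors),
            class = "rsk_cleaning")
}

required_log_columns <- function() {
  c("participant_id", "block_index", "trial_index", "task", "sequence_type",
    "rt_ms", "correct")
}

check_log_schema <- function(log, required = required_log_columns()) {
  missing <- setdiff(required, names(log))
  if (length(missing) > 0) {
    abort(paste0("trial log is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Clean a trial log for RT and accuracy analyses
#'
#' Returns an RT log (fast, block-first, error and timeout trials excluded),
#' an accuracy log (fast and block-first trials excluded; errors and timeouts
#' retained and scored 0), and an exclusion report. The individual filters
#' commute, so the retained sets do not depend on application order.
#'
#' @param log A trial log tibble (completed plan).
#' @param config A [cleaning_config()].
#' @return A list of class `rsk_cleaned` with elements `rt_log`,
#'   `accuracy_log`, `exclusions`.
#' @export
clean_trials <- function(log, config = cleaning_config()) {
  check_log_schema(log)
  log <- as_tibble(log)
  if (!"block_first" %in% names(log)) {
    log$block_first <- log$trial_index == 1L
  }
  if (!"timeout" %in% names(log)) {
    log$timeout <- is.na(log$rt_ms)
  }
  fast <- !is.na(log$rt_ms) & log$rt_ms < config$min_rt_ms
  block_first <- if (config$drop_block_first) log$block_first else rep(FALSE, nrow(log))
  error <- !log$timeout & !log$correct

  acc_keep <- !fast & !block_first
  accuracy_log <- log[acc_keep, , drop = FALSE]
  if (config$timeouts_as_errors) {
    accuracy_log$correct[accuracy_log$timeout] <- FALSE
  }
  rt_keep <- acc_keep & !log$timeout &
    (if (config$errors_excluded_from_rt) log$correct else TRUE)
  rt_log <- log[rt_keep, , drop = FALSE]

  exclusions <- tibble(
    category = c("total", "fast_guess", "block_first", "timeout",
                 "error_rt_only", "retained_rt", "retained_accuracy"),
    n = c(nrow(log), sum(fast), sum(block_first & !fast),
          sum(log$timeout & acc_keep),
          sum(error & acc_keep),
          nrow(rt_log), nrow(accuracy_log))
  )
  structure(list(rt_log = rt_log, accuracy_log = accuracy_log,
                 exclusions = exclusions, config = config),
            class = "rsk_cleaned")
}

#' @export
print.rsk_cleaned <- function(x, ...) {
  cat("<rsk_cleaned>\n")
  print(x$exclusions)
  invisible(x)
}

#' Normalising transforms and their inverses
#'
#' RTs are natural-log transformed; accuracy proportions are arcsine-root
#' transformed (`asin(sqrt(p))`). Descriptives are reported back-transformed,
#' so the back-transformed mean log RT is the geometric mean RT.
#'
#' @param rt_ms Reaction times in ms (positive).
#' @return Transformed values.
#' @export
transform_rt <- function(rt_ms) {
  if (any(rt_ms <= 0, na.rm = TRUE)) abort("RTs must be positive")
  log(rt_ms)
}

#' @rdname transform_rt
#' @param log_rt Log-scale RT values.
#' @export
back_transform_rt <- function(log_rt) exp(log_rt)

#' @rdname transform_rt
#' @param p Accuracy proportions in `[0, 1]`.
#' @export
transform_acc <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' @rdname transform_rt
#' @param a Arcsine-scale accuracy values.
#' @export
back_transform_acc <- function(a) sin(a)^2

#' Per-cell descriptive summaries
#'
#' Aggregates a cleaned log into participant/condition cells: trial counts,
#' mean log RT with its back-transform (the geometric-mean RT), accuracy
#' proportion and arcsine-transformed accuracy.
#'
#' @param cleaned An `rsk_cleaned` object from [clean_trials()].
#' @param ... Grouping columns (tidy-select), e.g. `participant_id, task`.
#' @return A tibble of cell summaries.
#' @export
cell_summary <- function(cleaned, ...) {
  rt <- cleaned$rt_log |>
    group_by(...) |>
    summarise(n_rt = dplyr::n(),
              mean_log_rt = mean(transform_rt(.data$rt_ms)),
              .groups = "drop") |>
    mutate(rt_ms = back_transform_rt(.data$mean_log_rt))
  acc <- cleaned$accuracy_log |>
    group_by(...) |>
    summarise(n_acc = dplyr::n(),
              accuracy = mean(.data$correct),
              .groups = "drop") |>
    mutate(arcsine_acc = transform_acc(.data$accuracy))
  dplyr::full_join(rt, acc, by = setdiff(names(acc),
                                         c("n_acc", "accuracy", "arcsine_acc")))
}

# ---- target/distractor regression ------------------------------------------

#' Regression of performance on target coherence and distractor congruence
#'
#' Multiple linear regression with target coherence and signed distractor
#' congruence as continuous predictors, fitted by OLS on standardized
#' outcome and predictors. Observations are participant x unique-stimulus
#' cell means (mean log RT, or arcsine-transformed accuracy), pooled across
#' participants. In the motion task the target predictor has 10 levels and
#' the distractor 10 signed levels; in the color task, 5 and 20.
#'
#' @param cleaned An `rsk_cleaned` object for a bivalent-stimulus log.
#' @param task `"motion"` or `"color"`.
#' @param outcome `"rt"` or `"accuracy"`.
#' @param mapping Optional [response_mapping()]; defaults to the log's own.
#' @return An object of class `rsk_regression` with `tidy()` (per-predictor
#'   standardized beta, t, p) and `glance()` (overall F, df pair, p,
#'   adjusted R-squared) methods.
#' @export
regress_target_distractor <- function(cleaned, task = c("motion", "color"),
                                      outcome = c("rt", "accuracy"),
                                      mapping = NULL) {
  task <- match.arg(task)
  outcome <- match.arg(outcome)
  log <- if (outcome == "rt") cleaned$rt_log else cleaned$accuracy_log
  mapping <- mapping %||% attr(log, "metadata")$mapping %||% response_mapping()
  log <- log[log$task == task, , drop = FALSE]
  if (nrow(log) == 0) abort("no trials for this task in the cleaned log")
  log$target_coherence <- 100 * ifelse(log$task == "motion",
                                       log$motion_coherence,
                                       log$color_coherence)
  log$distractor_congruence <- signed_distractor_congruence(log, mapping)

  cells <- if (outcome == "rt") {
    log |>
      group_by(.data$participant_id, .data$target_coherence,
               .data$distractor_congruence) |>
      summarise(y = mean(transform_rt(.data$rt_ms)), .groups = "drop")
  } else {
    log |>
      group_by(.data$participant_id, .data$target_coherence,
               .data$distractor_congruence) |>
      summarise(y = transform_acc(mean(.data$correct)), .groups = "drop")
  }
  z <- function(x) (x - mean(x)) / sd(x)
  d <- tibble(y = z(cells$y),
              target = z(cells$target_coherence),
              distractor = z(cells$distractor_congruence))
  qrX <- qr(cbind(1, d$target, d$distractor))
  if (qrX$rank < 3) abort("rank-deficient design: predictors are collinear")
  fit <- lm(y ~ target + distractor, data = d)
  sm <- summary(fit)
  coefs <- sm$coefficients[c("target", "distractor"), , drop = FALSE]
  terms <- tibble(
    term = c("target_coherence", "distractor_congruence"),
    beta = unname(coefs[, 1]),
    statistic = unname(coefs[, 3]),
    p.value = unname(coefs[, 4])
  )
  fstat <- sm$fstatistic
  structure(
    list(terms = terms,
         overall = tibble(
           statistic = unname(fstat[1]),
           df = unname(fstat[2]), df.residual = unname(fstat[3]),
           p.value = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
           r.squared = sm$r.squared, adj.r.squared = sm$adj.r.squared,
           n = nrow(d)),
         task = task, outcome = outcome, fit = fit),
    class = "rsk_regression")
}

#' @export
print.rsk_regression <- function(x, ...) {
  cat(sprintf("<rsk_regression> %s task, outcome: %s\n", x$task, x$outcome))
  print(x$terms)
  print(x$overall)
  invisible(x)
}

#' @rdname regress_target_distractor
#' @param x An `rsk_regression` object.
#' @param ... Unused.
#' @export
tidy.rsk_regression <- function(x, ...) x$terms

#' @rdname regress_target_distractor
#' @export
glance.rsk_regression <- function(x, ...) x$overall

# ---- cost estimators -------------------------------------------------------

#' Switch, error and mixing costs from a task-switching log
#'
#' Per participant x CSI x congruency cell, computes back-transformed mean
#' RTs and error percentages by task sequence, then the cost contrasts:
#' switch cost = switch - repeat (RT), error cost = switch - repeat (error
#' %), RT-mixing cost = repeat - single (RT), ER-mixing cost = repeat -
#' single (error %). Empty cells yield `NA` costs and are flagged.
#'
#' @param log A completed task-switching trial log (raw; cleaned internally).
#' @param cleaning A [cleaning_config()].
#' @param by_congruency Keep the congruency factor (default) or collapse it.
#' @return A tibble of class `rsk_cost_table`, one row per participant x CSI
#'   (x congruency), with attribute `summary` holding grand means and SDs.
#' @export
compute_costs <- function(log, cleaning = cleaning_config(),
                          by_congruency = TRUE) {
  cleaned <- clean_trials(log, cleaning)
  keys <- c("participant_id", "csi_ms",
            if (by_congruency) "congruent")
  rt_cells <- cleaned$rt_log |>
    group_by(across(dplyr::all_of(c(keys, "sequence_type")))) |>
    summarise(rt = back_transform_rt(mean(transform_rt(.data$rt_ms))),
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sequence_type", values_from = "rt",
                       names_prefix = "rt_")
  er_cells <- cleaned$accuracy_log |>
    group_by(across(dplyr::all_of(c(keys, "sequence_type")))) |>
    summarise(er = 100 * mean(!.data$correct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sequence_type", values_from = "er",
                       names_prefix = "er_")
  for (col in c("rt_single", "rt_repeat", "rt_switch")) {
    if (!col %in% names(rt_cells)) rt_cells[[col]] <- NA_real_
  }
  for (col in c("er_single", "er_repeat", "er_switch")) {
    if (!col %in% names(er_cells)) er_cells[[col]] <- NA_real_
  }
  out <- dplyr::full_join(rt_cells, er_cells, by = keys) |>
    mutate(
      switch_cost_ms = .data$rt_switch - .data$rt_repeat,
      rt_mixing_cost_ms = .data$rt_repeat - .data$rt_single,
      error_cost_pct = .data$er_switch - .data$er_repeat,
      er_mixing_cost_pct = .data$er_repeat - .data$er_single,
      empty_cell = is.na(.data$switch_cost_ms) | is.na(.data$rt_mixing_cost_ms)
    )
  if (any(out$empty_cell)) {
    warn("some participant x condition cells are empty; their costs are NA")
  }
  cost_cols <- c("switch_cost_ms", "error_cost_pct",
                 "rt_mixing_cost_ms", "er_mixing_cost_pct")
  summary <- out |>
    group_by(.data$csi_ms) |>
    summarise(across(dplyr::all_of(cost_cols),
                     list(mean = ~ mean(.x, na.rm = TRUE),
                          sd = ~ sd(.x, na.rm = TRUE))),
              .groups = "drop")
  structure(out, summary = summary,
            class = c("rsk_cost_table", class(out)))
}

#' @export
print.rsk_cost_table <- function(x, ...) {
  cat("<rsk_cost_table> grand means by CSI:\n")
  print(attr(x, "summary"))
  NextMethod()
}

#' Plot costs by CSI and congruency
#'
#' @param object An `rsk_cost_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rsk_cost_table <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(
      c("switch_cost_ms", "rt_mixing_cost_ms",
        "error_cost_pct", "er_mixing_cost_pct"),
      names_to = "cost", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(.data$csi_ms), y = .data$value)) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey70") +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "errorbar",
                          width = 0.2) +
    ggplot2::facet_wrap(~ .data$cost, scales = "free_y") +
    ggplot2::labs(x = "CSI (ms)", y = "cost") +
    ggplot2::theme_minimal()
}

# ---- chance-level test -----------------------------------------------------

#' One-tailed test of accuracy against chance
#'
#' One-sample t-test of per-participant accuracies against the chance level,
#' one-tailed (greater), with Cohen's d = (mean - chance) / sd. Optionally
#' performed on the arcsine scale.
#'
#' @param accuracies Numeric vector, one accuracy per participant.
#' @param chance Chance level (default 0.5).
#' @param scale `"raw"` (default) or `"arcsine"`.
#' @return A one-row tibble of class `rsk_chance_test`: mean accuracy, t,
#'   df, one-tailed p, Cohen's d, and a `degenerate` flag for zero-variance
#'   input.
#' @export
chance_level_test <- function(accuracies, chance = 0.5,
                              scale = c("raw", "arcsine")) {
  scale <- match.arg(scale)
  if (length(accuracies) < 2) abort("at least two participants are required")
  x <- if (scale == "arcsine") transform_acc(accuracies) else accuracies
  mu <- if (scale == "arcsine") transform_acc(chance) else chance
  s <- sd(x)
  if (s == 0) {
    out <- tibble(mean_accuracy = mean(accuracies), t = NA_real_,
                  df = length(x) - 1, p.value = NA_real_, cohens_d = NA_real_,
                  degenerate = TRUE)
  } else {
    tt <- stats::t.test(x, mu = mu, alternative = "greater")
    out <- tibble(mean_accuracy = mean(accuracies),
                  t = unname(tt$statistic), df = unname(tt$parameter),
                  p.value = tt$p.value,
                  cohens_d = (mean(x) - mu) / s,
                  degenerate = FALSE)
  }
  structure(out, class = c("rsk_chance_test", class(out)))
}

# ---- switch-cost asymmetry -------------------------------------------------

#' Switch-cost asymmetry by switch direction and previous congruency
#'
#' Computes switch costs per CSI x switch direction (to motion / to color) x
#' previous-trial congruency, with repeat trials of the same target task as
#' the baseline (or the pooled repeat baseline), and runs the 2 (CSI) x 2
#' (Switch Direction) x 2 (previous Congruency) repeated-measures ANOVA on
#' the RT switch cost and the error cost. Previous congruency is attached
#' from the plan's sequence bookkeeping before cleaning discards any trial;
#' trials with no previous-trial context (block-first) are excluded from the
#' factor.
#'
#' @param log A completed task-switching trial log.
#' @param cleaning A [cleaning_config()].
#' @param baseline `"direction_matched"` (default: to-motion switches against
#'   motion repeats) or `"pooled"` (all repeat trials of the same CSI x
#'   previous congruency cell).
#' @return A list of class `rsk_asymmetry`: `cost_table` (per participant x
#'   CSI x direction x previous congruency), `anova_rt`, `anova_error`.
#' @export
asymmetry_analysis <- function(log, cleaning = cleaning_config(),
                               baseline = c("direction_matched", "pooled")) {
  baseline <- match.arg(baseline)
  log <- as_tibble(log)
  if (!"congruency_n_minus_1" %in% names(log)) {
    log <- log |>
      group_by(.data$participant_id, .data$block_index) |>
      mutate(congruency_n_minus_1 = dplyr::lag(.data$congruent)) |>
      ungroup()
  }
  cleaned <- clean_trials(log, cleaning)
  prep <- function(d) {
    d |>
      filter(.data$sequence_type %in% c("repeat", "switch"),
             !is.na(.data$congruency_n_minus_1)) |>
      mutate(prev_congruency = ifelse(.data$congruency_n_minus_1,
                                      "congruent_n1", "incongruent_n1"),
             direction_to = paste0("to_", .data$task))
  }
  rt_cells <- prep(cleaned$rt_log) |>
    group_by(.data$participant_id, .data$csi_ms, .data$sequence_type,
             .data$direction_to, .data$prev_congruency) |>
    summarise(rt = back_transform_rt(mean(transform_rt(.data$rt_ms))),
              .groups = "drop")
  er_cells <- prep(cleaned$accuracy_log) |>
    group_by(.data$participant_id, .data$csi_ms, .data$sequence_type,
             .data$direction_to, .data$prev_congruency) |>
    summarise(er = 100 * mean(!.data$correct), .groups = "drop")

  cost_against_baseline <- function(cells, value_col) {
    sw <- cells |> filter(.data$sequence_type == "switch")
    rep_tr <- cells |> filter(.data$sequence_type == "repeat")
    if (baseline == "pooled") {
      base <- rep_tr |>
        group_by(.data$participant_id, .data$csi_ms, .data$prev_congruency) |>
        summarise(base = mean(.data[[value_col]]), .groups = "drop")
      sw |>
        left_join(base, by = c("participant_id", "csi_ms", "prev_congruency"))
    } else {
      base <- rep_tr |>
        mutate(direction_to = .data$direction_to) |>
        select("participant_id", "csi_ms", "direction_to",
               "prev_congruency", base = dplyr::all_of(value_col))
      sw |>
        left_join(base, by = c("participant_id", "csi_ms", "direction_to",
                               "prev_congruency"))
    }
  }
  rt_cost <- cost_against_baseline(rt_cells, "rt") |>
    mutate(switch_cost_ms = .data$rt - .data$base) |>
    select("participant_id", "csi_ms", "direction_to", "prev_congruency",
           "switch_cost_ms")
  er_cost <- cost_against_baseline(er_cells, "er") |>
    mutate(error_cost_pct = .data$er - .data$base) |>
    select("participant_id", "csi_ms", "direction_to", "prev_congruency",
           "error_cost_pct")
  cost_table <- dplyr::full_join(
    rt_cost, er_cost,
    by = c("participant_id", "csi_ms", "direction_to", "prev_congruency"))

  anova_rt <- rm_anova(rt_cost, "switch_cost_ms",
                       within = c("csi_ms", "direction_to", "prev_congruency"))
  anova_er <- rm_anova(er_cost, "error_cost_pct",
                       within = c("csi_ms", "direction_to", "prev_congruency"))
  structure(list(cost_table = cost_table, anova_rt = anova_rt,
                 anova_error = anova_er, baseline = baseline),
            class = "rsk_asymmetry")
}

#' @export
print.rsk_asymmetry <- function(x, ...) {
  cat(sprintf("<rsk_asymmetry> baseline: %s\n", x$baseline))
  means <- x$cost_table |>
    group_by(.data$direction_to, .data$prev_congruency) |>
    summarise(switch_cost_ms = mean(.data$switch_cost_ms, na.rm = TRUE),
              error_cost_pct = mean(.data$error_cost_pct, na.rm = TRUE),
              .groups = "drop")
  print(means)
  invisible(x)
}

# ---- cost significance pattern ---------------------------------------------

#' Qualitative cost pattern of a task-switching study
#'
#' Summarises a completed task-switching study into the canonical
#' significance pattern: are the switch cost, error cost and RT-mixing cost
#' reliably positive at each CSI (one-sample t, alpha = 0.05), and does
#' preparation (the CSI main effect of the 2x2 cost ANOVA) reduce the mixing
#' costs but not the switch/error costs?
#'
#' @param log A completed multi-participant task-switching log.
#' @param cleaning A [cleaning_config()].
#' @param alpha Significance level.
#' @return A tibble with one row per check: `check`, `cost`, `csi_ms`,
#'   `estimate`, `p.value`, `significant`, `expected_significant`, `pass`.
#' @export
cost_sign_pattern <- function(log, cleaning = cleaning_config(),
                              alpha = 0.05) {
  costs <- compute_costs(log, cleaning, by_congruency = TRUE)
  cost_cols <- c(switch_cost = "switch_cost_ms",
                 error_cost = "error_cost_pct",
                 rt_mixing_cost = "rt_mixing_cost_ms",
                 er_mixing_cost = "er_mixing_cost_pct")
  by_csi <- as_tibble(costs) |>
    group_by(.data$participant_id, .data$csi_ms) |>
    summarise(across(dplyr::all_of(unname(cost_cols)),
                     ~ mean(.x, na.rm = TRUE)), .groups = "drop")
  rows <- list()
  positive_checks <- tibble(
    cost = c("switch_cost", "error_cost", "rt_mixing_cost"),
    col = cost_cols[c("switch_cost", "error_cost", "rt_mixing_cost")]
  )
  for (i in seq_len(nrow(positive_checks))) {
    for (csi in sort(unique(by_csi$csi_ms))) {
      x <- by_csi[by_csi$csi_ms == csi, ][[positive_checks$col[i]]]
      tt <- stats::t.test(x)
      rows[[length(rows) + 1]] <- tibble(
        check = "cost positive", cost = positive_checks$cost[i], csi_ms = csi,
        estimate = mean(x), p.value = tt$p.value,
        significant = tt$p.value < alpha & mean(x) > 0,
        expected_significant = TRUE)
    }
  }
  prep_expect <- c(switch_cost = FALSE, error_cost = FALSE,
                   rt_mixing_cost = TRUE, er_mixing_cost = TRUE)
  for (nm in names(cost_cols)) {
    aov <- rm_anova(as_tibble(costs), cost_cols[[nm]],
                    within = c("csi_ms", "congruent"))
    row <- aov[aov$effect == "csi_ms", ]
    csi_means <- by_csi |>
      group_by(.data$csi_ms) |>
      summarise(m = mean(.data[[cost_cols[[nm]]]]), .groups = "drop")
    reduction <- csi_means$m[csi_means$csi_ms == min(csi_means$csi_ms)] -
      csi_means$m[csi_means$csi_ms == max(csi_means$csi_ms)]
    rows[[length(rows) + 1]] <- tibble(
      check = "preparatory reduction", cost = nm, csi_ms = NA_real_,
      estimate = reduction, p.value = row$p_gg,
      significant = row$p_gg < alpha,
      expected_significant = unname(prep_expect[nm]))
  }
  out <- dplyr::bind_rows(rows)
  out$pass <- out$significant == out$expected_significant
  out
}

# ---- psychometric plots ----------------------------------------------------

#' Psychometric summary and plot for single-task logs
#'
#' Accuracy and geometric-mean RT per target-coherence bin.
#'
#' @param cleaned An `rsk_cleaned` object.
#' @param task Which task to summarise.
#' @return `psychometric_summary()`: a tibble per coherence bin;
#'   `plot_psychometric()`: a ggplot.
#' @export
psychometric_summary <- function(cleaned, task = c("motion", "color")) {
  task <- match.arg(task)
  tc <- function(d) 100 * ifelse(d$task == "motion",
                                 d$motion_coherence, d$color_coherence)
  rt <- cleaned$rt_log |> filter(.data$task == !!task)
  rt$target_coherence <- tc(rt)
  acc <- cleaned$accuracy_log |> filter(.data$task == !!task)
  acc$target_coherence <- tc(acc)
  rt_s <- rt |>
    group_by(.data$target_coherence) |>
    summarise(rt_ms = back_transform_rt(mean(transform_rt(.data$rt_ms))),
              n_rt = dplyr::n(), .groups = "drop")
  acc_s <- acc |>
    group_by(.data$target_coherence) |>
    summarise(accuracy = mean(.data$correct), n_acc = dplyr::n(),
              .groups = "drop")
  dplyr::full_join(rt_s, acc_s, by = "target_coherence") |>
    arrange(.data$target_coherence)
}

#' @rdname psychometric_summary
#' @export
plot_psychometric <- function(cleaned, task = c("motion", "color")) {
  s <- psychometric_summary(cleaned, task)
  long <- tidyr::pivot_longer(s, c("rt_ms", "accuracy"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$target_coherence,
                                     y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$measure, scales = "free_y") +
    ggplot2::labs(x = "target coherence (%)", y = NULL) +
    ggplot2::theme_minimal()
}
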