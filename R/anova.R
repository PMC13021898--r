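# Repeated-measures ANOVA for balanced fully-within designs, with
# Greenhouse-Geisser correction and partial eta-squared.
#
# The decomposition works on the n x K matrix of per-subject cell means. For
# each effect (a subset of the within factors) an orthonormal contrast basis
# is built as the Kronecker product of per-factor bases (orthonormal
# complement of the intercept for factors in the effect, the unit mean vector
# 1/sqrt(k) for the others). Projecting subjects onto that basis gives effect
# scores whose mean carries the effect sum of squares and whose
# subject-by-effect scatter is the matching error term; the GG epsilon is
# tr(V)^2 / (d * tr(V^2)) for V the covariance of the scores.

orthonormal_contrasts <- function(k) {
  q <- qr.Q(qr(cbind(rep(1, k), stats::contr.helmert(k))))
  q[, -1, drop = FALSE]
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fits a fully within-subject ANOVA on a long table holding exactly one
#' value per subject per cell of the crossed within factors. For every main
#' effect and interaction it reports the F ratio against the matching
#' subject-by-effect error term, the Greenhouse-Geisser epsilon estimated
#' from the effect's covariance structure, sphericity-corrected degrees of
#' freedom and p value, and partial eta-squared
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Long tibble: one row per subject x cell.
#' @param dv Name of the dependent-variable column (string).
#' @param within Character vector of within-factor column names.
#' @param subject Name of the subject identifier column.
#' @return An object of class `rsk_anova`: a tibble with one row per effect
#'   (`effect`, `df1`, `df2`, `F`, `ggeps`, `df1_gg`, `df2_gg`, `p`, `p_gg`,
#'   `pes`), plus attributes `n_subjects` and `cells`.
#' @examples
#' d <- tidyr::expand_grid(s = 1:8, a = c("x", "y"))
#' d$y <- rnorm(nrow(d))
#' rm_anova(d, "y", within = "a", subject = "s")
#' @export
rm_anova <- function(data, dv, within, subject = "participant_id") {
  stopifnot(is.character(dv), length(dv) == 1, is.character(within))
  d <- as_tibble(data)[, c(subject, within, dv)]
  if (anyNA(d[[dv]])) abort("missing dependent-variable values: incomplete cells")
  levs <- lapply(within, function(f) sort(unique(as.character(d[[f]]))))
  names(levs) <- within
  k <- vapply(levs, length, 1L)
  counts <- d |> count(across(dplyr::all_of(c(subject, within))))
  if (any(counts$n != 1)) {
    abort("`rm_anova` needs exactly one value per subject per cell; aggregate first")
  }
  n_cells <- prod(k)
  subjects <- sort(unique(d[[subject]]))
  n <- length(subjects)
  if (nrow(d) != n * n_cells) {
    abort("unbalanced design: some subject x cell combinations are missing")
  }
  # arrange so the last factor varies fastest (Kronecker cell order)
  d <- dplyr::arrange(d, across(dplyr::all_of(c(subject, within))))
  Y <- matrix(d[[dv]], nrow = n, ncol = n_cells, byrow = TRUE)

  bases <- lapply(k, orthonormal_contrasts)
  unit <- lapply(k, function(kk) matrix(1 / sqrt(kk), nrow = kk))
  effects <- unlist(lapply(seq_along(within), function(m) {
    utils::combn(seq_along(within), m, simplify = FALSE)
  }), recursive = FALSE)

  rows <- purrr::map(effects, function(idx) {
    mats <- lapply(seq_along(within), function(j) {
      if (j %in% idx) bases[[j]] else unit[[j]]
    })
    C <- Reduce(kronecker, mats)
    S <- Y %*% C
    d_eff <- ncol(C)
    mns <- colMeans(S)
    ss_eff <- n * sum(mns^2)
    resid <- sweep(S, 2, mns)
    ss_err <- sum(resid^2)
    df_err <- (n - 1) * d_eff
    Fval <- (ss_eff / d_eff) / (ss_err / df_err)
    V <- crossprod(resid) / (n - 1)
    eps <- if (d_eff == 1) 1 else {
      sum(diag(V))^2 / (d_eff * sum(V * V))
    }
    tibble(
      effect = paste(within[idx], collapse = ":"),
      df1 = d_eff, df2 = df_err, F = Fval,
      ggeps = eps,
      df1_gg = eps * d_eff, df2_gg = eps * df_err,
      p = pf(Fval, d_eff, df_err, lower.tail = FALSE),
      p_gg = pf(Fval, eps * d_eff, eps * df_err, lower.tail = FALSE),
      pes = ss_eff / (ss_eff + ss_err),
      ss_effect = ss_eff, ss_error = ss_err
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, n_subjects = n, cells = levs,
            class = c("rsk_anova", class(out)))
}

#' @export
print.rsk_anova <- function(x, ...) {
  cat(sprintf("<rsk_anova> %d subjects, within factors: %s\n",
              attr(x, "n_subjects"),
              paste(names(attr(x, "cells")), collapse = ", ")))
  NextMethod()
}

#' @rdname rm_anova
#' @param x An `rsk_anova` object.
#' @param ... Unused.
#' @export
tidy.rsk_anova <- function(x, ...) {
  as_tibble(x)[, c("effect", "df1_gg", "df2_gg", "F", "p_gg", "pes", "ggeps")] |>
    rename(term = "effect", statistic = "F", p.value = "p_gg")
}

#' Bonferroni-corrected pairwise paired t-tests
#'
#' Post-hoc decomposition helper: all pairwise paired comparisons between the
#' levels of one within factor, with the family size equal to the number of
#' pairwise comparisons.
#'
#' @param data Long tibble, one value per subject per level.
#' @param dv Dependent-variable column name.
#' @param factor_col Column holding the factor.
#' @param subject Subject identifier column.
#' @return Tibble with one row per pair: means, t, df, raw and
#'   Bonferroni-adjusted p.
#' @export
pairwise_posthoc <- function(data, dv, factor_col, subject = "participant_id") {
  d <- as_tibble(data)
  levs <- sort(unique(as.character(d[[factor_col]])))
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  wide <- tidyr::pivot_wider(d[, c(subject, factor_col, dv)],
                             names_from = dplyr::all_of(factor_col),
                             values_from = dplyr::all_of(dv))
  rows <- purrr::map(pairs, function(pr) {
    diff <- wide[[pr[1]]] - wide[[pr[2]]]
    tt <- stats::t.test(diff)
    tibble(level_1 = pr[1], level_2 = pr[2],
           mean_1 = mean(wide[[pr[1]]]), mean_2 = mean(wide[[pr[2]]]),
           t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_bonferroni <- pmin(out$p * length(pairs), 1)
  out
}
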