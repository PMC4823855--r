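#' Summarize a creatinine-change distribution
#'
#' Median and interquartile range using linear interpolation between order
#' statistics ([stats::quantile()] type 7).
#'
#' @param x Numeric vector (may be empty).
#' @return List with `n`, `median`, `q1`, `q3` (all NA when empty).
#' @keywords internal
.iqr_summary <- function(x) {
  if (length(x) == 0) {
    return(list(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(n = length(x), median = q[2], q1 = q[1], q3 = q[3])
}

#' Creatinine change by code status
#'
#' Splits index cases into code-positive and code-negative groups under one
#' coding algorithm and summarizes the absolute (umol/L) and relative (%)
#' creatinine changes in each group with median and IQR.
#'
#' @param assessments Data frame from [assess_cohort()] (`abs_change`,
#'   `rel_change_pct`).
#' @param code_flag Logical code-positivity per index case (same order).
#' @return List with elements `positive` and `negative`, each containing
#'   `n`, `abs` and `rel` summaries (`median`, `q1`, `q3`). Empty groups are
#'   returned with NA summaries rather than an error.
#' @export
change_summary <- function(assessments, code_flag) {
  stopifnot(nrow(assessments) == length(code_flag))
  one <- function(rows) {
    list(n = nrow(rows),
         abs = .iqr_summary(rows$abs_change),
         rel = .iqr_summary(rows$rel_change_pct))
  }
  list(positive = one(assessments[code_flag, , drop = FALSE]),
       negative = one(assessments[!code_flag, , drop = FALSE]))
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two samples
#'
#' Returns the U statistic for the first sample, computed from midranks (so
#' `U_x + U_y = n_x * n_y` holds exactly, ties included), together with the
#' p-value from [stats::wilcox.test()]: exact by enumeration for small
#' tie-free samples (combined n <= 12), otherwise the normal approximation
#' with tie and continuity corrections.
#'
#' @param x,y Numeric samples (both nonempty).
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @return List with `U` and `p`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) > 0, length(y) > 0)
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  exact <- (length(x) + length(y)) <= 12 && !anyDuplicated(c(x, y))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)$p.value
  )
  list(U = U, p = p)
}

#' Code-positive vs code-negative creatinine-change contrast
#'
#' For each coding algorithm, summarizes absolute and relative creatinine
#' changes in the code-positive and code-negative groups and tests the
#' difference in distributions with the two-sided Mann-Whitney test.
#'
#' @param assessments Data frame from [assess_cohort()].
#' @param code_flags Data frame of logical columns named after
#'   [coding_algorithms()].
#' @param algorithms Algorithms to contrast.
#' @return Data frame, one row per algorithm: group sizes, median (IQR) of
#'   absolute and relative change per group, and Mann-Whitney p-values for
#'   the absolute and relative change distributions.
#' @export
change_contrast <- function(assessments, code_flags,
                            algorithms = coding_algorithms()) {
  rows <- lapply(algorithms, function(alg) {
    flag <- code_flags[[alg]]
    s <- change_summary(assessments, flag)
    p_abs <- p_rel <- NA_real_
    if (s$positive$n > 0 && s$negative$n > 0) {
      p_abs <- mann_whitney(assessments$abs_change[flag],
                            assessments$abs_change[!flag])$p
      p_rel <- mann_whitney(assessments$rel_change_pct[flag],
                            assessments$rel_change_pct[!flag])$p
    }
    data.frame(
      algorithm = alg,
      n_pos = s$positive$n, n_neg = s$negative$n,
      abs_median_pos = s$positive$abs$median,
      abs_q1_pos = s$positive$abs$q1, abs_q3_pos = s$positive$abs$q3,
      abs_median_neg = s$negative$abs$median,
      abs_q1_neg = s$negative$abs$q1, abs_q3_neg = s$negative$abs$q3,
      rel_median_pos = s$positive$rel$median,
      rel_q1_pos = s$positive$rel$q1, rel_q3_pos = s$positive$rel$q3,
      rel_median_neg = s$negative$rel$median,
      rel_q1_neg = s$negative$rel$q1, rel_q3_neg = s$negative$rel$q3,
      p_abs = p_abs, p_rel = p_rel,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
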