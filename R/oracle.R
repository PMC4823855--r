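#' Printed performance rows from the source validation study
#'
#' The eight unsuppressed rows of the published diagnostic-performance table
#' (three coding algorithms crossed with three AKIN reference standards; the
#' main-diagnosis / stage >= 1 row was suppressed for privacy and is not
#' included). Each row carries the cohort marginals (total, reference-positive
#' and code-positive counts) and the printed one-decimal percentages for
#' Sn/Sp/PPV/NPV with their Wilson 95% bounds, plus the printed LR+.
#'
#' @return Data frame with one row per published table row.
#' @export
printed_performance <- function() {
  path <- system.file("extdata", "printed_performance.csv",
                      package = "akicode", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reconstruct latent 2x2 counts from printed statistics
#'
#' Printed validation tables report rounded percentages, not the underlying
#' integer cell counts. Given the marginals (cohort size, reference-positive
#' and code-positive totals) and the four printed statistics, this searches
#' every feasible true-positive count, derives the other three cells from the
#' marginals, and keeps the candidates whose recomputed Sn/Sp/PPV/NPV all
#' render to the printed values under the report's printing convention
#' ([printed_percent()] by default). The inversion errors rather than guess:
#' zero survivors raise an inconsistency error, several survivors an
#' ambiguity error listing all candidates.
#'
#' @param n_total Cohort size.
#' @param n_ref_pos Reference-positive count (tp + fn).
#' @param n_code_pos Code-positive count (tp + fp).
#' @param sn,sp,ppv,npv Printed percentages (one decimal, 0-100 scale).
#' @param render Function mapping an exact percentage to its printed form;
#'   default [printed_percent()].
#' @return A [two_by_two()] table.
#' @export
reconstruct_counts <- function(n_total, n_ref_pos, n_code_pos,
                               sn, sp, ppv, npv, render = printed_percent) {
  stopifnot(n_ref_pos <= n_total, n_code_pos <= n_total)
  candidates <- list()
  for (tp in 0:min(n_ref_pos, n_code_pos)) {
    fp <- n_code_pos - tp
    fn <- n_ref_pos - tp
    tn <- n_total - tp - fp - fn
    if (tn < 0) next
    stats <- c(
      if (n_ref_pos > 0) render(100 * tp / n_ref_pos) else NA,
      if (tn + fp > 0) render(100 * tn / (tn + fp)) else NA,
      if (n_code_pos > 0) render(100 * tp / n_code_pos) else NA,
      if (tn + fn > 0) render(100 * tn / (tn + fn)) else NA
    )
    if (isTRUE(all(stats == c(sn, sp, ppv, npv)))) {
      candidates[[length(candidates) + 1L]] <- c(tp, fp, fn, tn)
    }
  }
  if (length(candidates) == 0) {
    stop("inconsistent printed row: no (tp, fp, fn, tn) with marginals (",
         n_total, ", ", n_ref_pos, ", ", n_code_pos,
         ") reproduces Sn/Sp/PPV/NPV = ",
         paste(c(sn, sp, ppv, npv), collapse = "/"))
  }
  if (length(candidates) > 1) {
    stop("ambiguous printed row: candidates ",
         paste(vapply(candidates, paste, "", collapse = ","),
               collapse = " | "))
  }
  k <- candidates[[1]]
  two_by_two(k[1], k[2], k[3], k[4])
}

#' Reconstruct the full published table of latent counts
#'
#' Applies [reconstruct_counts()] to every row of [printed_performance()].
#'
#' @return Data frame: `algorithm`, `reference`, `tp`, `fp`, `fn`, `tn`.
#' @export
reconstruct_table <- function() {
  rows <- printed_performance()
  out <- rows[, c("algorithm", "reference")]
  cells <- t(vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    t <- reconstruct_counts(r$n_total, r$n_ref_pos, r$n_code_pos,
                            r$sn, r$sp, r$ppv, r$npv)
    c(t$tp, t$fp, t$fn, t$tn)
  }, numeric(4)))
  out$tp <- cells[, 1]; out$fp <- cells[, 2]
  out$fn <- cells[, 3]; out$tn <- cells[, 4]
  out
}
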