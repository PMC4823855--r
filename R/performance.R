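#' Reference standards for the code validation
#'
#' Three creatinine-based reference standards are evaluated: any AKI
#' (AKIN stage 1 or greater), moderate-to-severe AKI (stage 2 or greater),
#' and severe AKI (stage 3).
#'
#' @return Character vector of reference standard names.
#' @export
reference_standards <- function() {
  c("stage_ge1", "stage_ge2", "stage_eq3")
}

#' Evaluate a reference standard predicate on AKIN stages
#'
#' @param stage Integer vector of AKIN stages 0-3.
#' @param reference One of [reference_standards()].
#' @return Logical vector: reference-positive.
#' @export
reference_positive <- function(stage, reference = reference_standards()) {
  reference <- match.arg(reference)
  switch(reference,
    stage_ge1 = stage >= 1,
    stage_ge2 = stage >= 2,
    stage_eq3 = stage == 3
  )
}

#' Construct a 2x2 diagnostic table
#'
#' @param tp,fp,fn,tn Nonnegative integer cell counts (true positive, false
#'   positive, false negative, true negative).
#' @return An object of class `two_by_two`.
#' @export
two_by_two <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("2x2 cells must be nonnegative integers")
  }
  structure(as.list(cells), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(code = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  if (isTRUE(attr(x, "suppressed"))) cat("[suppressed: small cells]\n")
  invisible(x)
}

#' Cross-tabulate a coding algorithm against a reference standard
#'
#' @param stage AKIN stage per index case.
#' @param code_flag Logical code-positivity per index case (same order).
#' @param reference One of [reference_standards()].
#' @return A [two_by_two()] table; cell totals equal the cohort size.
#' @export
build_two_by_two <- function(stage, code_flag, reference = reference_standards()) {
  if (length(stage) != length(code_flag)) {
    stop("stage and code_flag describe different case sets (",
         length(stage), " vs ", length(code_flag), " rows)")
  }
  ref <- reference_positive(stage, reference)
  two_by_two(
    tp = sum(ref & code_flag), fp = sum(!ref & code_flag),
    fn = sum(ref & !code_flag), tn = sum(!ref & !code_flag)
  )
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form score interval; well behaved at the boundaries (the lower
#' bound is exactly 0 when k = 0 and the upper bound exactly 1 when k = n).
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials.
#' @param conf Confidence level, default 0.95 (z = 1.959964).
#' @return Numeric `c(low, high)` on the proportion scale; `c(NA, NA)` when
#'   n = 0.
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  stopifnot(k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  pmin(pmax(c(centre - half, centre + half) / denom, 0), 1)
}

#' Diagnostic accuracy metrics with Wilson intervals
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive predictive value
#' tp/(tp+fp) and negative predictive value tn/(tn+fn), each with a Wilson
#' score interval. A metric with a zero denominator is returned as NA
#' (undefined), never as an error.
#'
#' @param t A [two_by_two()] table.
#' @param conf Confidence level for the intervals.
#' @return Data frame with columns `metric`, `k`, `n`, `estimate`, `lo`,
#'   `hi` (proportion scale).
#' @export
performance <- function(t, conf = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  num <- c(sn = t$tp, sp = t$tn, ppv = t$tp, npv = t$tn)
  den <- c(sn = t$tp + t$fn, sp = t$tn + t$fp,
           ppv = t$tp + t$fp, npv = t$tn + t$fn)
  rows <- lapply(names(num), function(m) {
    k <- num[[m]]; n <- den[[m]]
    if (n == 0) {
      data.frame(metric = m, k = k, n = n, estimate = NA_real_,
                 lo = NA_real_, hi = NA_real_, stringsAsFactors = FALSE)
    } else {
      ci <- wilson_interval(k, n, conf)
      data.frame(metric = m, k = k, n = n, estimate = k / n,
                 lo = ci[1], hi = ci[2], stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Positive likelihood ratio
#'
#' LR+ = sensitivity / (1 - specificity). Two modes:
#'
#' * `"exact"`: the ratio of the unrounded proportions;
#' * `"printed"`: both inputs are first rendered as printed percentages
#'   (see [printed_percent()]) and the ratio of those is then rounded
#'   half-up to one decimal — this replicates how the published report
#'   derived its LR+ column, and differs from exact mode for some tables
#'   (e.g. exact 10.07 vs printed 10.0).
#'
#' @param sn,sp Sensitivity and specificity as proportions in `[0, 1]`.
#' @param mode `"exact"` or `"printed"`.
#' @return The likelihood ratio; NA (undefined) when specificity is 1.
#' @export
positive_lr <- function(sn, sp, mode = c("exact", "printed")) {
  mode <- match.arg(mode)
  if (is.na(sn) || is.na(sp)) return(NA_real_)
  if (mode == "exact") {
    if (sp >= 1) return(NA_real_)
    return(sn / (1 - sp))
  }
  sn_p <- printed_percent(100 * sn)
  sp_p <- printed_percent(100 * sp)
  if (sp_p >= 100) return(NA_real_)
  round_half_up(sn_p / (100 - sp_p), 1)
}

#' Negative likelihood ratio
#'
#' LR- = (1 - sensitivity) / specificity; NA when specificity is 0.
#'
#' @param sn,sp Sensitivity and specificity as proportions.
#' @return The negative likelihood ratio.
#' @export
negative_lr <- function(sn, sp) {
  if (is.na(sn) || is.na(sp) || sp == 0) return(NA_real_)
  (1 - sn) / sp
}

#' Apply small-cell suppression to a 2x2 table
#'
#' Privacy rules for administrative health data forbid releasing small
#' nonzero counts. If any cell lies in `[1, threshold)` the whole table (and
#' every statistic derived from it) is marked suppressed; cells of exactly
#' zero do not trigger suppression. The default threshold of 6 implements
#' the common "counts of 1-5 are small cells" convention.
#'
#' @param t A [two_by_two()] table.
#' @param threshold Nonnegative integer; 0 disables suppression.
#' @return `t` with attribute `suppressed` set to TRUE or FALSE.
#' @export
apply_suppression <- function(t, threshold = 6) {
  stopifnot(inherits(t, "two_by_two"), threshold >= 0)
  cells <- unlist(t[c("tp", "fp", "fn", "tn")])
  attr(t, "suppressed") <- any(cells >= 1 & cells < threshold)
  t
}

#' Full diagnostic performance report
#'
#' Builds one row per (coding algorithm, reference standard) pair:
#' 2x2 counts, Sn/Sp/PPV/NPV with Wilson intervals, and LR+. Percentages
#' are reported on the 0-100 scale; with `rounding = "printed"` they are
#' rendered under the published table's double-rounding convention, with
#' `rounding = "none"` they are left unrounded. Suppressed rows carry
#' `suppressed = TRUE` and NA statistics (counts are also withheld).
#'
#' @param stage AKIN stage per index case.
#' @param code_flags Data frame of logical columns named after
#'   [coding_algorithms()], one row per index case.
#' @param algorithms,references Subsets of [coding_algorithms()] and
#'   [reference_standards()] to evaluate.
#' @param suppress_threshold Small-cell suppression threshold (see
#'   [apply_suppression()]); 0 disables.
#' @param lr_mode `"printed"` or `"exact"` (see [positive_lr()]).
#' @param rounding `"printed"` or `"none"`.
#' @param conf Confidence level for Wilson intervals.
#' @return Data frame, one row per pair, columns `algorithm`, `reference`,
#'   `tp`, `fp`, `fn`, `tn`, `sn`, `sn_lo`, `sn_hi`, ..., `npv_hi`,
#'   `lr_plus`, `suppressed`.
#' @export
performance_report <- function(stage, code_flags,
                               algorithms = coding_algorithms(),
                               references = reference_standards(),
                               suppress_threshold = 6,
                               lr_mode = c("printed", "exact"),
                               rounding = c("printed", "none"),
                               conf = 0.95) {
  lr_mode <- match.arg(lr_mode)
  rounding <- match.arg(rounding)
  fmt <- if (rounding == "printed") printed_percent else identity
  rows <- list()
  for (alg in algorithms) {
    for (ref in references) {
      t <- build_two_by_two(stage, code_flags[[alg]], ref)
      t <- apply_suppression(t, suppress_threshold)
      suppressed <- isTRUE(attr(t, "suppressed"))
      row <- data.frame(algorithm = alg, reference = ref,
                        tp = t$tp, fp = t$fp, fn = t$fn, tn = t$tn,
                        stringsAsFactors = FALSE)
      perf <- performance(t, conf)
      for (m in perf$metric) {
        p <- perf[perf$metric == m, ]
        row[[m]] <- fmt(100 * p$estimate)
        row[[paste0(m, "_lo")]] <- fmt(100 * p$lo)
        row[[paste0(m, "_hi")]] <- fmt(100 * p$hi)
      }
      sn <- perf$estimate[perf$metric == "sn"]
      sp <- perf$estimate[perf$metric == "sp"]
      row$lr_plus <- if (lr_mode == "printed") {
        positive_lr(sn, sp, "printed")
      } else {
        lr <- positive_lr(sn, sp, "exact")
        if (rounding == "printed" && !is.na(lr)) round_half_up(lr, 1) else lr
      }
      row$suppressed <- suppressed
      if (suppressed) {
        stat_cols <- setdiff(names(row),
                             c("algorithm", "reference", "suppressed"))
        row[stat_cols] <- NA_real_
      }
      rows[[paste(alg, ref)]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
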