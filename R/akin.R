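#' Assign a creatinine-only AKIN stage
#'
#' Implements the adapted Acute Kidney Injury Network staging used when only
#' serum creatinine (no urine output, no 48-h timing) is available. With
#' ratio r = peak/baseline and absolute rise d = peak - baseline (umol/L):
#'
#' * stage 3: r > 3, or peak > 354 umol/L with d >= 44 umol/L;
#' * stage 2: r > 2 (and not stage 3);
#' * stage 1: d >= 26.4 umol/L or r >= 1.5 (and not stage 2 or 3);
#' * stage 0: otherwise.
#'
#' Boundary conventions: r exactly 2 is stage 1, r exactly 3 is stage 2, a
#' peak of exactly 354 does not satisfy the stage-3 absolute clause, and
#' d exactly 44 does. The ratio criteria are scale-invariant; the absolute
#' thresholds (26.4, 44, 354 umol/L) are not.
#'
#' @param baseline Baseline serum creatinine, umol/L (positive).
#' @param peak Peak in-hospital serum creatinine, umol/L (positive).
#' @return Integer vector of stages 0-3.
#' @examples
#' akin_stage(100, 126.4)  # 1: absolute rise of 26.4 meets the threshold
#' akin_stage(100, 250)    # 2: 2.5-fold rise
#' akin_stage(320, 370)    # 3: peak > 354 with rise >= 44, despite ratio 1.16
#' @export
akin_stage <- function(baseline, peak) {
  if (any(!is.finite(baseline)) || any(!is.finite(peak)) ||
      any(baseline <= 0) || any(peak <= 0)) {
    stop("baseline and peak creatinine must be positive and finite")
  }
  r <- peak / baseline
  d <- peak - baseline
  stage <- integer(length(r))
  s3 <- r > 3 | (peak > 354 & d >= 44)
  s2 <- !s3 & r > 2
  s1 <- !s3 & !s2 & (d >= 26.4 | r >= 1.5)
  stage[s1] <- 1L
  stage[s2] <- 2L
  stage[s3] <- 3L
  stage
}

#' Select the baseline creatinine before an admission
#'
#' The baseline is the most recent creatinine drawn inside the pre-admission
#' window (default 2 weeks to 6 months before admission, i.e. draw dates in
#' `[admit - 183, admit - 14]`, both ends inclusive). Draws closer than two
#' weeks to admission are excluded because they may already reflect the start
#' of the injury episode. If several draws share the latest eligible date
#' their values are averaged.
#'
#' @param labs Data frame of lab rows for one patient with columns
#'   `draw_date` (Date) and `value`; rows for other analytes should be
#'   filtered out beforehand (see [assess_cohort()]).
#' @param admit_date Admission date (Date).
#' @param window Length-2 numeric: minimum and maximum offset in days before
#'   admission, default `c(14, 183)`.
#' @return A list with `value` and `date`, or `NULL` when no draw falls in
#'   the window (absence is a value here; eligibility filtering upstream is
#'   responsible for excluding such admissions).
#' @export
select_baseline <- function(labs, admit_date, window = c(14, 183)) {
  offset <- as.numeric(admit_date - as.Date(labs$draw_date))
  in_win <- offset >= window[1] & offset <= window[2]
  if (!any(in_win)) return(NULL)
  eligible <- labs[in_win, , drop = FALSE]
  latest <- max(as.Date(eligible$draw_date))
  on_day <- eligible[as.Date(eligible$draw_date) == latest, , drop = FALSE]
  list(value = mean(on_day$value), date = latest)
}

#' Select the peak creatinine during an admission
#'
#' Returns the maximum creatinine drawn between admission and discharge
#' (inclusive); ties on value are broken by the earliest draw date.
#'
#' @param labs Data frame of lab rows for one patient (`draw_date`, `value`).
#' @param admit_date,discharge_date Admission interval (Date).
#' @return A list with `value` and `date`.
#' @export
peak_creatinine <- function(labs, admit_date, discharge_date) {
  d <- as.Date(labs$draw_date)
  in_stay <- d >= admit_date & d <= discharge_date
  if (!any(in_stay)) {
    stop("no in-admission creatinine between ", admit_date, " and ",
         discharge_date, "; admission should have been excluded upstream")
  }
  stay <- labs[in_stay, , drop = FALSE]
  vmax <- max(stay$value)
  at_max <- stay[stay$value == vmax, , drop = FALSE]
  list(value = vmax, date = min(as.Date(at_max$draw_date)))
}

#' Stage every index admission from the lab table
#'
#' For each index case, selects the baseline creatinine (most recent draw in
#' the pre-admission window), the peak creatinine during the stay, and
#' assigns the AKIN stage. Absolute change is peak - baseline; relative
#' change is 100 * (peak - baseline) / baseline.
#'
#' @param index_admissions Data frame with one row per index case:
#'   `patient_id`, `admission_id`, `admit_date`, `discharge_date`.
#' @param labs Lab table (`patient_id`, `draw_date`, `analyte`, `value`).
#' @param window Baseline window in days before admission, default
#'   `c(14, 183)`.
#' @param analyte Lab analyte name identifying serum creatinine rows.
#' @return Data frame: `patient_id`, `admission_id`, `baseline`,
#'   `baseline_date`, `peak`, `peak_date`, `abs_change`, `rel_change_pct`,
#'   `stage`.
#' @export
assess_cohort <- function(index_admissions, labs, window = c(14, 183),
                          analyte = "creatinine") {
  scr <- labs[labs$analyte == analyte, , drop = FALSE]
  scr$draw_date <- as.Date(scr$draw_date)
  by_patient <- split(scr[, c("draw_date", "value")], scr$patient_id)
  n <- nrow(index_admissions)
  admit <- as.Date(index_admissions$admit_date)
  disch <- as.Date(index_admissions$discharge_date)
  baseline <- peak <- numeric(n)
  baseline_date <- peak_date <- rep(as.Date(NA), n)
  for (i in seq_len(n)) {
    pid <- as.character(index_admissions$patient_id[i])
    plabs <- by_patient[[pid]]
    base <- if (is.null(plabs)) NULL else
      select_baseline(plabs, admit[i], window)
    if (is.null(base)) {
      stop("index admission ", index_admissions$admission_id[i],
           " has no baseline creatinine in the window")
    }
    pk <- peak_creatinine(plabs, admit[i], disch[i])
    baseline[i] <- base$value
    baseline_date[i] <- base$date
    peak[i] <- pk$value
    peak_date[i] <- pk$date
  }
  data.frame(
    patient_id = index_admissions$patient_id,
    admission_id = index_admissions$admission_id,
    baseline = baseline, baseline_date = baseline_date,
    peak = peak, peak_date = peak_date,
    abs_change = peak - baseline,
    rel_change_pct = 100 * (peak - baseline) / baseline,
    stage = akin_stage(baseline, peak),
    stringsAsFactors = FALSE
  )
}
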