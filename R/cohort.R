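#' Eligibility configuration
#'
#' Calendar and window settings for [filter_eligible()]. "6 months" is
#' interpreted as 183 days and "2 weeks" as 14 days throughout; the baseline
#' window is `[admit - 183, admit - 14]`, inclusive at both ends. The default
#' study window is the Ottawa one (admissions from 2003-04-01, labs available
#' through 2012-12-31); both bounds are configurable because availability
#' differed by region.
#'
#' @param post_transplant_min_days Minimum days from transplant to admission
#'   (excludes early post-operative AKI, delayed graft function and early
#'   rejection), default 183.
#' @param baseline_window Offsets (days before admission) bounding the
#'   baseline creatinine draw, default `c(14, 183)`.
#' @param study_start Earliest eligible admission date (ICD-10 coding era).
#' @param lab_end Laboratory data availability end date; admissions must be
#'   discharged before it.
#' @return A list of class `eligibility_config`.
#' @export
eligibility_config <- function(post_transplant_min_days = 183,
                               baseline_window = c(14, 183),
                               study_start = "2003-04-01",
                               lab_end = "2012-12-31") {
  stopifnot(baseline_window[1] < baseline_window[2], baseline_window[1] > 0,
            post_transplant_min_days > 0)
  structure(list(
    post_transplant_min_days = post_transplant_min_days,
    baseline_window = baseline_window,
    study_start = as.Date(study_start),
    lab_end = as.Date(lab_end)
  ), class = "eligibility_config")
}

#' Apply the five cohort eligibility rules
#'
#' An admission is eligible iff, in cascade order:
#'
#' a. the patient's first transplant is a kidney-only first graft;
#' b. admission is at least `post_transplant_min_days` after that transplant;
#' c. at least one serum creatinine was drawn during the stay (admission to
#'    discharge, inclusive);
#' d. the admission falls in the study window: admitted on or after
#'    `study_start` and discharged before `lab_end`;
#' e. at least one creatinine was drawn in the baseline window before
#'    admission.
#'
#' Each excluded admission is counted against the first rule it fails, so
#' the per-rule exclusion counts plus the eligible count always sum to the
#' number of input admissions (a flow-diagram conservation property).
#'
#' @param patients,transplants,admissions,labs The input tables (see
#'   [generate_population()] for schemas).
#' @param config An [eligibility_config()].
#' @param analyte Lab analyte name identifying serum creatinine rows.
#' @return List with `eligible` (data frame `patient_id`, `admission_id`),
#'   `exclusions` (named counts for rules a-e) and `n_input`.
#' @export
filter_eligible <- function(patients, transplants, admissions, labs,
                            config = eligibility_config(),
                            analyte = "creatinine") {
  stopifnot(inherits(config, "eligibility_config"))
  unknown <- setdiff(admissions$patient_id, patients$patient_id)
  if (length(unknown)) {
    stop("referential integrity: admissions reference unknown patient ids: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  scr <- labs[labs$analyte == analyte, , drop = FALSE]
  scr_by_patient <- split(as.numeric(as.Date(scr$draw_date)), scr$patient_id)

  # first transplant per patient, and whether it is kidney-only first graft
  tx <- transplants[order(transplants$patient_id,
                          as.Date(transplants$transplant_date)), ]
  first_tx <- tx[!duplicated(tx$patient_id), ]
  ok_a <- first_tx$organ == "kidney" & first_tx$graft_number == 1
  first_date <- as.numeric(as.Date(first_tx$transplant_date))

  n <- nrow(admissions)
  pmap <- match(admissions$patient_id, first_tx$patient_id)
  admit <- as.numeric(as.Date(admissions$admit_date))
  disch <- as.numeric(as.Date(admissions$discharge_date))
  draws_in <- function(i, lo, hi) {
    d <- scr_by_patient[[as.character(admissions$patient_id[i])]]
    !is.null(d) && any(d >= lo & d <= hi)
  }

  fail_a <- is.na(pmap) | !ok_a[pmap]
  fail_b <- !fail_a &
    admit < first_date[pmap] + config$post_transplant_min_days
  alive <- !fail_a & !fail_b
  fail_c <- logical(n)
  fail_c[alive] <- !vapply(which(alive),
                           function(i) draws_in(i, admit[i], disch[i]),
                           logical(1))
  alive <- alive & !fail_c
  fail_d <- alive & (admit < as.numeric(config$study_start) |
                       disch >= as.numeric(config$lab_end))
  alive <- alive & !fail_d
  fail_e <- logical(n)
  fail_e[alive] <- !vapply(
    which(alive),
    function(i) draws_in(i, admit[i] - config$baseline_window[2],
                         admit[i] - config$baseline_window[1]),
    logical(1))
  keep <- alive & !fail_e
  excl <- c(a = sum(fail_a), b = sum(fail_b), c = sum(fail_c),
            d = sum(fail_d), e = sum(fail_e))
  list(
    eligible = data.frame(patient_id = admissions$patient_id[keep],
                          admission_id = admissions$admission_id[keep],
                          stringsAsFactors = FALSE),
    exclusions = excl,
    n_input = n
  )
}

#' Select one index admission per patient at random
#'
#' When a patient has several eligible admissions, exactly one is chosen
#' uniformly at random to avoid within-patient clustering in the accuracy
#' analysis. Deterministic under a fixed seed.
#'
#' @param eligible Data frame (`patient_id`, `admission_id`) from
#'   [filter_eligible()].
#' @param seed Optional integer seed; NULL uses the current RNG state.
#' @return Data frame with one row per patient.
#' @export
select_index_admission <- function(eligible, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  picks <- vapply(split(eligible$admission_id, eligible$patient_id),
                  function(ids) ids[sample.int(length(ids), 1)],
                  character(1))
  out <- data.frame(patient_id = names(picks), admission_id = unname(picks),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$patient_id), , drop = FALSE]
}

#' Flag comorbidities from prior admission history
#'
#' Looks back a fixed window (default 3 years = 1095 days) from each
#' patient's index admission date and flags a comorbidity when any diagnosis
#' code in any prior admission matches one of the supplied prefixes
#' (canonicalized; "I251" matches prefix "I25"). The index admission itself
#' is excluded from the history. Code lists are user-supplied configuration.
#'
#' @param index Data frame (`patient_id`, `admission_id`, `admit_date`), one
#'   row per patient.
#' @param admissions,diagnoses Full admission and diagnosis tables.
#' @param code_lists Named list of character prefix vectors, one per
#'   comorbidity; an empty vector triggers a configuration warning.
#' @param lookback_days Window length in days, default 1095.
#' @return Data frame: `patient_id` plus one logical column per comorbidity.
#' @export
flag_comorbidities <- function(index, admissions, diagnoses, code_lists,
                               lookback_days = 1095) {
  empty <- names(code_lists)[vapply(code_lists, length, 0L) == 0]
  if (length(empty)) {
    warning("empty code list for comorbidity: ",
            paste(empty, collapse = ", "))
  }
  dx_by_adm <- split(canonicalize_code(diagnoses$code),
                     diagnoses$admission_id)
  out <- data.frame(patient_id = index$patient_id, stringsAsFactors = FALSE)
  for (cm in names(code_lists)) out[[cm]] <- FALSE
  for (i in seq_len(nrow(index))) {
    pid <- index$patient_id[i]
    idx_date <- as.Date(index$admit_date[i])
    hist <- admissions[admissions$patient_id == pid &
                         admissions$admission_id != index$admission_id[i], ,
                       drop = FALSE]
    hist_dates <- as.Date(hist$admit_date)
    hist <- hist[hist_dates >= idx_date - lookback_days &
                   hist_dates <= idx_date, , drop = FALSE]
    if (nrow(hist) == 0) next
    codes <- unlist(dx_by_adm[as.character(hist$admission_id)],
                    use.names = FALSE)
    if (is.null(codes)) next
    for (cm in names(code_lists)) {
      prefixes <- canonicalize_code(code_lists[[cm]])
      out[[cm]][i] <- any(vapply(prefixes,
                                 function(p) any(startsWith(codes, p)),
                                 logical(1)))
    }
  }
  out
}

#' CKD-EPI (2009) estimated glomerular filtration rate
#'
#' eGFR in mL/min/1.73 m^2 from serum creatinine (umol/L, converted at
#' 88.4 umol/L per mg/dL), age and sex. The race coefficient (1.159) is
#' omitted by default and available via `black = TRUE`.
#'
#' @param scr Serum creatinine, umol/L (positive).
#' @param age Age in years (>= 18).
#' @param sex `"F"` or `"M"` (recycled).
#' @param black Apply the optional race coefficient (default FALSE).
#' @return eGFR values, mL/min/1.73 m^2.
#' @examples
#' egfr_ckd_epi(61.9, 50, "F")  # ~101
#' egfr_ckd_epi(133, 60, "M")   # ~49.7
#' @export
egfr_ckd_epi <- function(scr, age, sex, black = FALSE) {
  if (any(scr <= 0)) stop("serum creatinine must be positive")
  if (any(age < 18)) stop("CKD-EPI is an adult equation (age >= 18)")
  stopifnot(all(sex %in% c("F", "M")))
  scr_mg <- scr / 88.4
  female <- sex == "F"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  egfr <- 141 *
    pmin(scr_mg / kappa, 1)^alpha *
    pmax(scr_mg / kappa, 1)^(-1.209) *
    0.993^age *
    ifelse(female, 1.018, 1)
  if (isTRUE(black)) egfr <- egfr * 1.159
  egfr
}

#' Descriptive summary of the index cohort
#'
#' Baseline-characteristics style summary: cohort size, sex, age at
#' admission, baseline creatinine, CKD-EPI eGFR with clinical bands, donor
#' type, AKIN stage distribution (with the any-AKI total and the share of
#' AKI cases at stage 1), and code-positivity per coding algorithm.
#' Percentages are rendered with [printed_percent()].
#'
#' @param index_cases Data frame with one row per index case: `patient_id`,
#'   `admit_date`, `baseline`, `stage`, and one logical column per
#'   [coding_algorithms()].
#' @param patients,transplants The corresponding input tables.
#' @return A list of summary components; standard deviations are NA
#'   (undefined) for single-patient cohorts.
#' @export
summarize_cohort <- function(index_cases, patients, transplants) {
  stopifnot(nrow(index_cases) > 0)
  n <- nrow(index_cases)
  pct <- function(k) printed_percent(100 * k / n)
  m <- merge(index_cases, patients, by = "patient_id")
  m <- merge(m, transplants[, c("patient_id", "transplant_date", "donor_type")],
             by = "patient_id")
  age <- as.numeric(as.Date(m$admit_date) - as.Date(m$birth_date)) / 365.25
  egfr <- egfr_ckd_epi(m$baseline, age, m$sex)
  egfr_bands <- cut(egfr, c(-Inf, 15, 30, 45, 60, Inf), right = FALSE,
                    labels = c("<15", "15-<30", "30-<45", "45-<60", ">=60"))
  stage_n <- vapply(0:3, function(s) sum(index_cases$stage == s), 0L)
  names(stage_n) <- paste0("stage", 0:3)
  n_aki <- sum(stage_n[2:4])
  code_n <- vapply(coding_algorithms(),
                   function(a) sum(index_cases[[a]]), 0L)
  years_since_tx <- as.numeric(as.Date(m$admit_date) -
                                 as.Date(m$transplant_date)) / 365.25
  iqr3 <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE)
  list(
    n = n,
    women = list(n = sum(m$sex == "F"), pct = pct(sum(m$sex == "F"))),
    age = list(mean = mean(age), sd = if (n > 1) stats::sd(age) else NA_real_),
    years_since_transplant = stats::setNames(iqr3(years_since_tx),
                                             c("median", "q1", "q3")),
    baseline_scr = stats::setNames(iqr3(index_cases$baseline),
                                   c("median", "q1", "q3")),
    egfr = stats::setNames(iqr3(egfr), c("median", "q1", "q3")),
    egfr_bands = table(egfr_bands),
    donor_type = table(m$donor_type),
    stage_n = stage_n,
    stage_pct = pct(stage_n),
    any_aki = list(n = n_aki, pct = pct(n_aki)),
    stage1_share_of_aki_pct =
      if (n_aki > 0) unname(printed_percent(100 * stage_n["stage1"] / n_aki))
      else NA_real_,
    code_positive = list(n = code_n, pct = pct(code_n))
  )
}
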