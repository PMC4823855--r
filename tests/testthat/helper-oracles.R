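# Independent oracles used to cross-check the package's implementations.

# Wilson interval by root finding: the bounds are the two solutions p of
# |phat - p| = z * sqrt(p (1 - p) / n), located numerically rather than via
# the closed form the package uses.
wilson_root <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- k / n
  f <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  # search strictly inside (0, 1): f also vanishes at the trivial endpoints
  lo <- if (k == 0) 0 else
    uniroot(f, c(0, phat - phat * 1e-9), tol = 1e-12)$root
  hi <- if (k == n) 1 else
    uniroot(f, c(phat + (1 - phat) * 1e-9, 1), tol = 1e-12)$root
  c(lo, hi)
}

# Literal transcription of the creatinine-only AKIN rule table, evaluated
# branch by branch in precedence order (scalar).
akin_stage_literal <- function(baseline, peak) {
  ratio <- peak / baseline
  rise <- peak - baseline
  if (ratio > 3) return(3L)
  if (peak > 354 && rise >= 44) return(3L)
  if (ratio > 2) return(2L)
  if (rise >= 26.4) return(1L)
  if (ratio >= 1.5) return(1L)
  0L
}

# Minimal hand-built dataset: one fully conforming patient/admission, used
# as a base for eligibility-rule perturbation tests.
conforming_dataset <- function() {
  list(
    patients = data.frame(
      patient_id = "P1", sex = "M", birth_date = as.Date("1950-06-01"),
      stringsAsFactors = FALSE),
    transplants = data.frame(
      patient_id = "P1", transplant_date = as.Date("2004-01-01"),
      organ = "kidney", graft_number = 1L, donor_type = "deceased",
      stringsAsFactors = FALSE),
    admissions = data.frame(
      admission_id = "A1", patient_id = "P1",
      admit_date = as.Date("2008-03-01"),
      discharge_date = as.Date("2008-03-06"), stringsAsFactors = FALSE),
    diagnoses = data.frame(
      admission_id = "A1", position = 1:2, code = c("J189", "N179"),
      dx_type = c("M", "OTHER"), stringsAsFactors = FALSE),
    labs = data.frame(
      patient_id = "P1",
      draw_date = as.Date(c("2008-01-20", "2008-03-02", "2008-03-04")),
      analyte = "creatinine", value = c(120, 150, 210), units = "umol/L",
      setting = c("outpatient", "inpatient", "inpatient"),
      admission_id = c(NA, "A1", "A1"), stringsAsFactors = FALSE)
  )
}

# A mutually consistent planted-counts specification on a 50-patient cohort
# (identical counts for all three algorithms; stage sizes 20/15/5/10).
small_plant_counts <- function() {
  one <- data.frame(
    reference = c("stage_ge1", "stage_ge2", "stage_eq3"),
    tp = c(14, 9, 6), fp = c(2, 7, 10), fn = c(16, 6, 4), tn = c(18, 28, 30),
    stringsAsFactors = FALSE)
  do.call(rbind, lapply(c("any_diagnosis", "admission_diagnosis",
                          "main_diagnosis"),
                        function(a) cbind(algorithm = a, one)))
}
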