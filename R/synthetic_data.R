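#' Default per-stage code-positivity profile
#'
#' Probability that an admission receives the target ICD-10 code under each
#' coding algorithm, conditional on the true AKIN stage. The defaults are the
#' exact per-stage code rates implied by the latent 2x2 counts of the source
#' validation table (reconstructed with [reconstruct_counts()]): e.g. under
#' the any-diagnosis algorithm 8/288 of stage-0, 34/160 of stage-1, 10/21 of
#' stage-2 and 22/55 of stage-3 admissions were code-positive.
#'
#' @return A 3 x 4 numeric matrix, rows named after [coding_algorithms()],
#'   columns `stage0`..`stage3`.
#' @export
default_code_profile <- function() {
  m <- rbind(
    any_diagnosis       = c(8 / 288, 34 / 160, 10 / 21, 22 / 55),
    admission_diagnosis = c(6 / 288, 22 / 160,  8 / 21, 18 / 55),
    main_diagnosis      = c(2 / 288, 10 / 160,  3 / 21, 10 / 55)
  )
  colnames(m) <- paste0("stage", 0:3)
  m
}

#' Simulation parameters for the synthetic cohort generator
#'
#' Bundles and validates everything [generate_population()] needs. Defaults
#' are calibrated to the source validation cohort: stage prevalences
#' (0.55, 0.305, 0.04, 0.105) over AKIN stages 0-3 (45% any AKI), baseline
#' creatinine lognormal with median 133 and IQR 103-174 umol/L, transplant to
#' admission gap lognormal with median 3.5 years (IQR 1.5-7.1), baseline draw
#' offset lognormal with median 34 days (IQR 22-68) truncated to the 14-183
#' day eligibility window, and the per-stage coding profile of
#' [default_code_profile()].
#'
#' @param n_patients Number of patients to simulate.
#' @param stage_prevalence Probabilities over stages 0-3; must sum to 1
#'   within 1e-12.
#' @param code_profile 3 x 4 matrix of P(code+ | stage) per algorithm; the
#'   admission- and main-diagnosis rows must not exceed the any-diagnosis row
#'   (the any-diagnosis field set is a superset by construction).
#' @param baseline_scr List `meanlog`, `sdlog` for the lognormal baseline
#'   creatinine (umol/L).
#' @param timing List of timing controls: `gap_meanlog`/`gap_sdlog`/`gap_min`
#'   (transplant-to-admission gap, days), `offset_meanlog`/`offset_sdlog`/
#'   `offset_range` (baseline draw, days before admission), `los_range`
#'   (length of stay, days), `peak_day_max` (latest day of the peak draw),
#'   `recent_draw_prob` (chance of an extra creatinine 7 days before
#'   admission, too recent to serve as baseline).
#' @param n_admissions Eligible admissions per patient (default 1; larger
#'   values exercise random index selection, with admissions spaced >= 400
#'   days so baseline windows never capture another stay's labs).
#' @param study_start,lab_end Calendar bounds for admissions (ISO dates).
#' @param peak_margin Distance (umol/L) kept between sampled peaks and stage
#'   boundaries to avoid float-edge flips.
#' @param seed RNG seed, or NULL to use the current RNG state.
#' @return A validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_patients = 524,
                              stage_prevalence = c(0.55, 0.305, 0.04, 0.105),
                              code_profile = default_code_profile(),
                              baseline_scr = list(
                                meanlog = log(133),
                                sdlog = log(174 / 103) / (2 * stats::qnorm(0.75))
                              ),
                              timing = list(),
                              n_admissions = 1,
                              study_start = "2003-04-01",
                              lab_end = "2012-12-31",
                              peak_margin = 1,
                              seed = NULL) {
  default_timing <- list(
    gap_meanlog = log(3.5 * 365.25),
    gap_sdlog = log(7.1 / 1.5) / (2 * stats::qnorm(0.75)),
    gap_min = 183,
    offset_meanlog = log(34),
    offset_sdlog = log(68 / 22) / (2 * stats::qnorm(0.75)),
    offset_range = c(14, 183),
    los_range = c(2, 14),
    peak_day_max = 2,
    recent_draw_prob = 0.25
  )
  timing <- utils::modifyList(default_timing, timing)

  if (n_patients < 1 || n_patients != floor(n_patients)) {
    stop("n_patients must be a positive integer")
  }
  if (length(stage_prevalence) != 4 || any(stage_prevalence < 0) ||
      any(stage_prevalence > 1)) {
    stop("stage_prevalence must be four probabilities over AKIN stages 0-3")
  }
  if (abs(sum(stage_prevalence) - 1) > 1e-12) {
    stop("stage_prevalence must sum to 1 (got ", sum(stage_prevalence), ")")
  }
  if (!is.matrix(code_profile) || !identical(dim(code_profile), c(3L, 4L)) ||
      !setequal(rownames(code_profile), coding_algorithms())) {
    stop("code_profile must be a 3 x 4 matrix with rows named after ",
         "coding_algorithms()")
  }
  code_profile <- code_profile[coding_algorithms(), , drop = FALSE]
  if (any(code_profile < 0) || any(code_profile > 1)) {
    stop("code_profile entries must be probabilities in [0, 1]")
  }
  for (alg in c("admission_diagnosis", "main_diagnosis")) {
    if (any(code_profile[alg, ] > code_profile["any_diagnosis", ] + 1e-12)) {
      stop("code_profile: ", alg, " rate exceeds the any_diagnosis rate for ",
           "some stage; the any-diagnosis set must be a superset")
    }
  }
  if (timing$gap_min < 183) {
    stop("timing violates the post-transplant exclusion window: gap_min ",
         timing$gap_min, " is below the 183-day minimum")
  }
  if (timing$offset_range[1] < 14 || timing$offset_range[2] > 183 ||
      timing$offset_range[1] >= timing$offset_range[2]) {
    stop("timing violates the baseline window: offset_range must lie inside ",
         "[14, 183] days before admission")
  }
  if (timing$los_range[1] < 1 || timing$los_range[1] > timing$los_range[2]) {
    stop("timing violates the length-of-stay range: need 1 <= min <= max")
  }
  if (timing$peak_day_max < 0) stop("peak_day_max must be nonnegative")
  structure(list(
    n_patients = as.integer(n_patients),
    stage_prevalence = stage_prevalence,
    code_profile = code_profile,
    baseline_scr = baseline_scr,
    timing = timing,
    n_admissions = as.integer(n_admissions),
    study_start = as.Date(study_start),
    lab_end = as.Date(lab_end),
    peak_margin = peak_margin,
    seed = seed
  ), class = "simulation_params")
}

#' Sample a peak creatinine that realizes a requested AKIN stage
#'
#' Inverts the staging rule: given a baseline, draws a peak uniformly from
#' the creatinine interval whose [akin_stage()] equals the requested stage,
#' keeping `margin` umol/L away from stage boundaries so floating-point
#' comparisons can never flip the recovered stage.
#'
#' Stage 2 is geometrically impossible for baselines of 177 umol/L or more:
#' any more-than-2-fold rise from such a baseline exceeds 354 umol/L with an
#' acute increase over 44 umol/L and is therefore captured by the stage-3
#' absolute clause. Such requests raise an error; the generator truncates
#' baseline draws for planted stage-2 cases accordingly.
#'
#' @param baseline Baseline creatinine, umol/L (positive); vectorized.
#' @param stage Requested stage 0-3 (recycled against `baseline`).
#' @param margin Boundary margin in umol/L (default 1; shrunk automatically
#'   when an interval is narrower than 4 margins).
#' @return Peak creatinine values, umol/L.
#' @export
sample_peak_for_stage <- function(baseline, stage, margin = 1) {
  stopifnot(all(baseline > 0), all(stage %in% 0:3))
  n <- max(length(baseline), length(stage))
  baseline <- rep_len(baseline, n)
  stage <- rep_len(stage, n)
  vapply(seq_len(n), function(i) {
    b <- baseline[i]
    s <- stage[i]
    if (s == 0) {
      hi <- min(b + 26.4, 1.5 * b)
      lo <- max(0.5 * b, 0.05 * hi)
      m <- min(margin, 0.25 * (hi - lo))
      stats::runif(1, lo, hi - m)
    } else if (s == 1) {
      lo <- min(b + 26.4, 1.5 * b)
      hi <- min(2 * b, max(354, b + 44))
      m <- min(margin, 0.25 * (hi - lo))
      stats::runif(1, lo + m, hi - m)
    } else if (s == 2) {
      if (b >= 177) {
        stop("stage 2 is unattainable for baseline ", round(b, 1),
             " umol/L (>= 177): any >2-fold rise exceeds 354 umol/L with an ",
             "increase >= 44 umol/L and meets the stage-3 absolute criterion")
      }
      lo <- 2 * b
      hi <- if (b >= 44) min(3 * b, 354) else 3 * b
      m <- min(margin, 0.25 * (hi - lo))
      stats::runif(1, lo + m, hi - m)
    } else {
      m <- min(margin, 0.25 * b)
      stats::runif(1, 3 * b + m, 4 * b)
    }
  }, numeric(1))
}

# Draw baseline creatinines; stage-2 cases are truncated below 170 umol/L so
# the requested stage is always attainable (see sample_peak_for_stage).
.sample_baseline <- function(stage, dist) {
  n <- length(stage)
  out <- stats::rlnorm(n, dist$meanlog, dist$sdlog)
  s2 <- which(stage == 2)
  if (length(s2)) {
    cap <- stats::plnorm(170, dist$meanlog, dist$sdlog)
    u <- stats::runif(length(s2), 0, cap)
    out[s2] <- stats::qlnorm(u, dist$meanlog, dist$sdlog)
  }
  pmax(out, 25)
}

# Hierarchical per-stage code flag draw: the any-diagnosis flag is drawn at
# its marginal rate, then the admission- and main-diagnosis flags are drawn
# conditional on any-positivity, preserving all three marginal profiles while
# guaranteeing the superset structure the classifier implies.
.sample_code_flags <- function(stage, profile) {
  p_any <- profile["any_diagnosis", stage + 1]
  p_adm <- profile["admission_diagnosis", stage + 1]
  p_main <- profile["main_diagnosis", stage + 1]
  any_pos <- stats::runif(length(stage)) < p_any
  cond <- function(p) ifelse(p_any > 0, pmin(p / p_any, 1), 0)
  adm_pos <- any_pos & stats::runif(length(stage)) < cond(p_adm)
  main_pos <- any_pos & stats::runif(length(stage)) < cond(p_main)
  data.frame(any_diagnosis = any_pos, admission_diagnosis = adm_pos,
             main_diagnosis = main_pos)
}

# Assemble the five relational tables from one row per admission:
# patient index, stage, and the three code flags.
.assemble_tables <- function(plan, params) {
  tm <- params$timing
  n_adm <- nrow(plan)
  patient_ids <- sprintf("P%05d", plan$patient)
  admission_ids <- sprintf("A%05d", seq_len(n_adm))

  los <- sample(tm$los_range[1]:tm$los_range[2], n_adm, replace = TRUE)
  latest_admit <- params$lab_end - max(los) - 1
  admit <- params$study_start +
    floor(stats::runif(n_adm) *
            (as.numeric(latest_admit - params$study_start) + 1))
  # Space multiple admissions of one patient >= 400 days apart so that one
  # stay's labs can never fall inside another stay's baseline window.
  for (p in unique(plan$patient[duplicated(plan$patient)])) {
    idx <- which(plan$patient == p)
    first <- min(admit[idx])
    admit[idx] <- first + 400 * (seq_along(idx) - 1)
    over <- admit[idx] > latest_admit
    if (any(over)) {
      admit[idx] <- latest_admit - 400 * rev(seq_along(idx) - 1)
    }
  }
  discharge <- admit + los

  gap <- pmax(round(stats::rlnorm(n_adm, tm$gap_meanlog, tm$gap_sdlog)),
              tm$gap_min)
  offset <- pmin(pmax(round(stats::rlnorm(n_adm, tm$offset_meanlog,
                                          tm$offset_sdlog)),
                      tm$offset_range[1]), tm$offset_range[2])

  baseline <- .sample_baseline(plan$stage, params$baseline_scr)
  peak <- sample_peak_for_stage(baseline, plan$stage, params$peak_margin)
  peak_day <- pmin(sample(0:tm$peak_day_max, n_adm, replace = TRUE), los)

  first_adm <- !duplicated(plan$patient)
  patients <- data.frame(
    patient_id = patient_ids[first_adm],
    sex = ifelse(stats::runif(sum(first_adm)) < 0.353, "F", "M"),
    birth_date = admit[first_adm] -
      round(pmin(pmax(stats::rnorm(sum(first_adm), 57.7, 12.1), 18.5), 90) *
              365.25),
    stringsAsFactors = FALSE
  )
  transplants <- data.frame(
    patient_id = patient_ids[first_adm],
    transplant_date = (admit - gap)[first_adm],
    organ = "kidney",
    graft_number = 1L,
    donor_type = sample(c("deceased", "living", "missing"),
                        sum(first_adm), replace = TRUE,
                        prob = c(0.662, 0.315, 0.023)),
    stringsAsFactors = FALSE
  )
  admissions <- data.frame(
    admission_id = admission_ids,
    patient_id = patient_ids,
    admit_date = admit,
    discharge_date = discharge,
    stringsAsFactors = FALSE
  )

  # Labs: one baseline draw in the window, the planted peak in-stay, one
  # extra in-stay value strictly below the peak, and (sometimes) a draw a
  # week before admission that is too recent to serve as baseline.
  lab_rows <- list(
    data.frame(patient_id = patient_ids, draw_date = admit - offset,
               value = round(baseline, 1), setting = "outpatient",
               admission_id = NA_character_, stringsAsFactors = FALSE),
    data.frame(patient_id = patient_ids, draw_date = admit + peak_day,
               value = round(peak, 1), setting = "inpatient",
               admission_id = admission_ids, stringsAsFactors = FALSE)
  )
  extra_day <- pmin(peak_day + 1, los)
  lab_rows[[3]] <- data.frame(
    patient_id = patient_ids, draw_date = admit + extra_day,
    value = round(peak * stats::runif(n_adm, 0.80, 0.95), 1),
    setting = "inpatient", admission_id = admission_ids,
    stringsAsFactors = FALSE
  )
  recent <- stats::runif(n_adm) < tm$recent_draw_prob
  if (any(recent)) {
    lab_rows[[4]] <- data.frame(
      patient_id = patient_ids[recent], draw_date = admit[recent] - 7,
      value = round(baseline[recent] * stats::runif(sum(recent), 1.0, 1.2), 1),
      setting = "outpatient", admission_id = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  labs <- do.call(rbind, lab_rows)
  labs <- data.frame(patient_id = labs$patient_id, draw_date = labs$draw_date,
                     analyte = "creatinine", value = labs$value,
                     units = "umol/L", setting = labs$setting,
                     admission_id = labs$admission_id,
                     stringsAsFactors = FALSE)
  labs <- labs[order(labs$patient_id, labs$draw_date), ]
  rownames(labs) <- NULL

  diagnoses <- .build_diagnoses(admission_ids, plan)

  list(patients = patients, transplants = transplants,
       admissions = admissions, diagnoses = diagnoses, labs = labs)
}

.build_diagnoses <- function(admission_ids, plan) {
  pool <- c("I10", "E119", "J189", "A419", "Z940", "I500", "K529", "M545")
  n <- length(admission_ids)
  main_pos <- plan$main_diagnosis
  adm_pos <- plan$admission_diagnosis
  any_only <- plan$any_diagnosis & !adm_pos & !main_pos
  n_fill <- sample(1:4, n, replace = TRUE)
  seg <- rbind(
    # exactly one most-responsible (type M) diagnosis per admission
    data.frame(admission_id = admission_ids,
               code = ifelse(main_pos, "N170",
                             sample(pool, n, replace = TRUE)),
               dx_type = "M", stringsAsFactors = FALSE),
    data.frame(admission_id = admission_ids[adm_pos],
               code = rep("N179", sum(adm_pos)),
               dx_type = rep("PREADMIT", sum(adm_pos)),
               stringsAsFactors = FALSE),
    data.frame(admission_id = admission_ids[any_only],
               code = rep("N179", sum(any_only)),
               dx_type = rep("OTHER", sum(any_only)),
               stringsAsFactors = FALSE),
    data.frame(admission_id = rep(admission_ids, n_fill),
               code = sample(pool, sum(n_fill), replace = TRUE),
               dx_type = "OTHER", stringsAsFactors = FALSE)
  )
  idx <- match(seg$admission_id, admission_ids)
  o <- order(idx, seq_len(nrow(seg)))  # stable: keeps the M row first
  seg <- seg[o, , drop = FALSE]
  seg <- data.frame(admission_id = seg$admission_id,
                    position = sequence(tabulate(idx, nbins = n)),
                    code = seg$code, dx_type = seg$dx_type,
                    stringsAsFactors = FALSE)
  rownames(seg) <- NULL
  seg
}

#' Generate a synthetic transplant cohort (distributional mode)
#'
#' Simulates the five relational tables the validation pipeline consumes:
#' patients, transplants, admissions, diagnoses and serum-creatinine labs.
#' Every generated patient has a first kidney-only transplant, eligible
#' admissions (post-transplant gap, study window, in-stay creatinine and a
#' baseline draw inside the 14-183 day window all guaranteed by
#' construction), an AKIN stage drawn from `stage_prevalence`, a peak
#' creatinine planted so that the staging module recovers the drawn stage
#' exactly, and diagnosis codes drawn from the per-stage coding profile.
#'
#' @param params A [simulation_params()] object.
#' @return A list of data frames `patients`, `transplants`, `admissions`,
#'   `diagnoses`, `labs`, with the drawn per-admission truth in
#'   `attr(, "truth")` (`admission_id`, `stage`, one column per coding
#'   algorithm) and the parameters in `attr(, "params")`.
#' @export
generate_population <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_patients
  plan <- data.frame(
    patient = rep(seq_len(n), each = params$n_admissions),
    stage = sample(0:3, n * params$n_admissions, replace = TRUE,
                   prob = params$stage_prevalence)
  )
  plan <- cbind(plan, .sample_code_flags(plan$stage, params$code_profile))
  ds <- .assemble_tables(plan, params)
  attr(ds, "truth") <- data.frame(
    admission_id = ds$admissions$admission_id,
    stage = plan$stage,
    plan[, coding_algorithms()],
    stringsAsFactors = FALSE
  )
  attr(ds, "params") <- params
  ds
}

#' Plant a dataset that reproduces exact 2x2 counts (exact mode)
#'
#' Builds a synthetic dataset whose full pipeline output (eligibility filter,
#' index selection, staging, coding, cross-tabulation) reproduces a specified
#' set of 2x2 counts exactly, for every (coding algorithm, reference
#' standard) pair. Used to turn printed summary tables back into runnable
#' fixtures.
#'
#' The specification must contain all three reference standards for each
#' algorithm and be mutually consistent: identical cohort size everywhere,
#' identical reference-positive margins across algorithms, identical
#' code-positive margins across references within an algorithm, and
#' per-stage code counts that fit within the stage sizes and within the
#' any-diagnosis counts (the any-diagnosis field set is a superset of the
#' other two). Violations raise an error naming the conflicting marginals.
#'
#' @param counts Data frame with columns `algorithm`, `reference`, `tp`,
#'   `fp`, `fn`, `tn` (one row per pair; see [reconstruct_table()]).
#' @param params A [simulation_params()] object controlling everything but
#'   stage and code assignment (its `n_patients` and `stage_prevalence` are
#'   ignored; `n_admissions` must be 1).
#' @return A dataset list as from [generate_population()].
#' @export
plant_exact_dataset <- function(counts, params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  if (params$n_admissions != 1) {
    stop("exact planting requires n_admissions = 1")
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  req <- c("algorithm", "reference", "tp", "fp", "fn", "tn")
  if (!all(req %in% names(counts))) {
    stop("counts must have columns ", paste(req, collapse = ", "))
  }
  cells <- counts[, c("tp", "fp", "fn", "tn")]
  if (any(cells < 0)) stop("counts must be nonnegative")
  totals <- rowSums(cells)
  if (length(unique(totals)) != 1) {
    stop("inconsistent counts: cohort totals differ across rows (",
         paste(unique(totals), collapse = ", "), ")")
  }
  n <- totals[1]
  get <- function(alg, ref, col) {
    v <- counts[counts$algorithm == alg & counts$reference == ref, col]
    if (length(v) != 1) {
      stop("counts must contain exactly one row for ", alg, " / ", ref)
    }
    v
  }
  algs <- unique(counts$algorithm)
  refpos <- sapply(reference_standards(), function(ref) {
    vals <- sapply(algs, function(a) get(a, ref, "tp") + get(a, ref, "fn"))
    if (length(unique(vals)) != 1) {
      stop("inconsistent counts: reference-positive margin for ", ref,
           " differs across algorithms (", paste(vals, collapse = ", "), ")")
    }
    unname(vals[1])
  })
  names(refpos) <- reference_standards()
  stage_n <- c(n - refpos["stage_ge1"],
               refpos["stage_ge1"] - refpos["stage_ge2"],
               refpos["stage_ge2"] - refpos["stage_eq3"],
               refpos["stage_eq3"])
  names(stage_n) <- paste0("stage", 0:3)
  if (any(stage_n < 0)) {
    stop("inconsistent counts: reference-positive margins are not nested (",
         paste(refpos, collapse = " >= "), " fails)")
  }
  stage_code <- sapply(algs, function(a) {
    codepos <- sapply(reference_standards(),
                      function(r) get(a, r, "tp") + get(a, r, "fp"))
    if (length(unique(codepos)) != 1) {
      stop("inconsistent counts: code-positive margin for ", a,
           " differs across references (", paste(codepos, collapse = ", "), ")")
    }
    c(get(a, "stage_ge1", "fp"),
      get(a, "stage_ge1", "tp") - get(a, "stage_ge2", "tp"),
      get(a, "stage_ge2", "tp") - get(a, "stage_eq3", "tp"),
      get(a, "stage_eq3", "tp"))
  })
  if (any(stage_code < 0)) stop("inconsistent counts: negative per-stage ",
                                "code counts implied")
  for (s in 1:4) {
    if (any(stage_code[s, ] > stage_n[s])) {
      stop("inconsistent counts: stage ", s - 1, " holds ", stage_n[s],
           " patients but ", max(stage_code[s, ]), " code-positives implied")
    }
    for (alg in setdiff(algs, "any_diagnosis")) {
      if (stage_code[s, alg] > stage_code[s, "any_diagnosis"]) {
        stop("inconsistent counts: ", alg, " code-positives exceed ",
             "any_diagnosis code-positives in stage ", s - 1)
      }
    }
  }
  # Prefix assignment inside each stage block nests the three flag sets.
  plan_rows <- list()
  for (s in 0:3) {
    ns <- stage_n[s + 1]
    if (ns == 0) next
    block <- data.frame(stage = rep(s, ns))
    for (alg in coding_algorithms()) {
      k <- if (alg %in% algs) stage_code[s + 1, alg] else 0
      block[[alg]] <- seq_len(ns) <= k
    }
    plan_rows[[as.character(s)]] <- block
  }
  plan <- do.call(rbind, plan_rows)
  plan <- plan[sample.int(nrow(plan)), , drop = FALSE]
  plan$patient <- seq_len(nrow(plan))
  rownames(plan) <- NULL
  ds <- .assemble_tables(plan, params)
  attr(ds, "truth") <- data.frame(
    admission_id = ds$admissions$admission_id,
    stage = plan$stage, plan[, coding_algorithms()],
    stringsAsFactors = FALSE
  )
  attr(ds, "params") <- params
  ds
}

#' Write a dataset to CSV files
#'
#' Writes `patients.csv`, `transplants.csv`, `admissions.csv`,
#' `diagnoses.csv` and `labs.csv` (ISO-8601 dates, UTF-8, header row) plus a
#' `params.json` sidecar recording the generator settings and seed.
#'
#' @param dataset A dataset list from [generate_population()] or
#'   [plant_exact_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tbl in c("patients", "transplants", "admissions", "diagnoses", "labs")) {
    utils::write.csv(dataset[[tbl]], file.path(dir, paste0(tbl, ".csv")),
                     row.names = FALSE)
  }
  params <- attr(dataset, "params")
  if (!is.null(params)) {
    p <- unclass(params)
    p$study_start <- as.character(p$study_start)
    p$lab_end <- as.character(p$lab_end)
    p$code_profile <- as.data.frame(p$code_profile)
    jsonlite::write_json(p, file.path(dir, "params.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a dataset from CSV files
#'
#' Inverse of [write_dataset()]; date columns are parsed as `Date`.
#'
#' @param dir Directory containing the five CSV tables.
#' @return A dataset list.
#' @export
read_dataset <- function(dir) {
  rd <- function(name) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) stop("missing input file: ", path)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  ds <- list(patients = rd("patients"), transplants = rd("transplants"),
             admissions = rd("admissions"), diagnoses = rd("diagnoses"),
             labs = rd("labs"))
  ds$patients$birth_date <- as.Date(ds$patients$birth_date)
  ds$transplants$transplant_date <- as.Date(ds$transplants$transplant_date)
  ds$admissions$admit_date <- as.Date(ds$admissions$admit_date)
  ds$admissions$discharge_date <- as.Date(ds$admissions$discharge_date)
  ds$labs$draw_date <- as.Date(ds$labs$draw_date)
  ds
}
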