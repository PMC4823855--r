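test_that("eligibility rules exclude admissions for the stated reasons", {
  base <- conforming_dataset()
  ok <- filter_eligible(base$patients, base$transplants, base$admissions,
                        base$labs)
  expect_equal(nrow(ok$eligible), 1)
  expect_true(all(ok$exclusions == 0))

  # (b) admitted only 100 days after transplant
  early <- base
  early$transplants$transplant_date <- early$admissions$admit_date - 100
  r <- filter_eligible(early$patients, early$transplants, early$admissions,
                       early$labs)
  expect_equal(unname(r$exclusions["b"]), 1)
  expect_equal(nrow(r$eligible), 0)

  # (e) only baseline draw is 10 days before admission: too recent
  recent <- base
  recent$labs$draw_date[1] <- recent$admissions$admit_date - 10
  r <- filter_eligible(recent$patients, recent$transplants, recent$admissions,
                       recent$labs)
  expect_equal(unname(r$exclusions["e"]), 1)

  # (a) first transplant not kidney-only
  liver <- base
  liver$transplants$organ <- "other"
  r <- filter_eligible(liver$patients, liver$transplants, liver$admissions,
                       liver$labs)
  expect_equal(unname(r$exclusions["a"]), 1)

  # (c) no creatinine during the stay
  nolab <- base
  nolab$labs <- nolab$labs[1, , drop = FALSE]
  r <- filter_eligible(nolab$patients, nolab$transplants, nolab$admissions,
                       nolab$labs)
  expect_equal(unname(r$exclusions["c"]), 1)

  # (d) discharged after the end of lab availability
  late <- base
  cfg <- eligibility_config(lab_end = "2008-03-04")
  r <- filter_eligible(late$patients, late$transplants, late$admissions,
                       late$labs, cfg)
  expect_equal(unname(r$exclusions["d"]), 1)

  # unknown patient id is a referential integrity error
  orphan <- base
  orphan$admissions$patient_id <- "P999"
  expect_error(filter_eligible(orphan$patients, orphan$transplants,
                               orphan$admissions, orphan$labs), "P999")
})

test_that("the filter cascade conserves admissions and is idempotent", {
  ds <- generate_population(simulation_params(n_patients = 150, seed = 21))
  # corrupt a few records so several rules fire
  ds$transplants$organ[1:5] <- "other"
  ds$transplants$transplant_date[6:10] <-
    as.Date(ds$transplants$transplant_date[6:10]) + 4000
  r <- filter_eligible(ds$patients, ds$transplants, ds$admissions, ds$labs)
  expect_equal(sum(r$exclusions) + nrow(r$eligible), r$n_input)
  expect_gt(sum(r$exclusions), 0)

  surviving <- ds$admissions[ds$admissions$admission_id %in%
                               r$eligible$admission_id, ]
  r2 <- filter_eligible(ds$patients, ds$transplants, surviving, ds$labs)
  expect_true(all(r2$exclusions == 0))
  expect_equal(sort(r2$eligible$admission_id), sort(r$eligible$admission_id))
})

test_that("index selection is uniform, one per patient, and seeded", {
  eligible <- data.frame(patient_id = rep("P1", 4),
                         admission_id = paste0("A", 1:4))
  expect_equal(nrow(select_index_admission(eligible, 5)), 1)
  expect_identical(select_index_admission(eligible, 5),
                   select_index_admission(eligible, 5))
  single <- data.frame(patient_id = "P9", admission_id = "A9")
  expect_equal(select_index_admission(single, 123)$admission_id, "A9")

  set.seed(22)
  picks <- replicate(40000, select_index_admission(eligible)$admission_id)
  freq <- table(picks) / 40000
  expect_true(all(abs(freq - 0.25) < 0.01))
})

test_that("comorbidity flags use prefix matching inside the lookback", {
  index <- data.frame(patient_id = "P1", admission_id = "A9",
                      admit_date = as.Date("2010-01-01"))
  adm <- data.frame(
    admission_id = c("A1", "A2", "A9"), patient_id = "P1",
    admit_date = as.Date("2010-01-01") - c(500, 1100, 0),
    discharge_date = as.Date("2010-01-01") - c(495, 1095, -5))
  dx <- data.frame(admission_id = c("A1", "A2", "A9"),
                   position = 1, code = c("I25.1", "E119", "N170"),
                   dx_type = "M")
  lists <- list(cad = "I25", diabetes = "E11", aki = "N17")
  fl <- flag_comorbidities(index, adm, dx, lists)
  expect_true(fl$cad)        # I251 matches prefix I25, 500 d back
  expect_false(fl$diabetes)  # 1100 d back: outside the 1095-d window
  expect_false(fl$aki)       # index admission itself is not history

  none <- flag_comorbidities(index, adm[0, ], dx[0, ], lists)
  expect_false(any(unlist(none[, -1])))
  expect_warning(flag_comorbidities(index, adm, dx, list(chf = character(0))),
                 "empty code list")
})

test_that("CKD-EPI matches published coefficients and is continuous", {
  expect_equal(egfr_ckd_epi(61.9, 50, "F"), 101, tolerance = 0.005)
  expect_equal(egfr_ckd_epi(133, 60, "M"), 49.7, tolerance = 0.005)
  # continuity at the sex-specific creatinine breakpoint (kappa)
  for (sex in c("F", "M")) {
    bp <- ifelse(sex == "F", 0.7, 0.9) * 88.4
    expect_lt(abs(egfr_ckd_epi(bp - 1e-6, 55, sex) -
                    egfr_ckd_epi(bp + 1e-6, 55, sex)), 1e-4)
  }
  expect_gt(egfr_ckd_epi(100, 50, "M", black = TRUE),
            egfr_ckd_epi(100, 50, "M"))
  expect_error(egfr_ckd_epi(-1, 50, "F"), "positive")
  expect_error(egfr_ckd_epi(100, 10, "F"), "adult")
})

test_that("cohort summary counts stages, codes and degenerate inputs", {
  n <- c(288, 160, 21, 55)
  idx <- data.frame(
    patient_id = sprintf("P%03d", 1:524),
    admission_id = sprintf("A%03d", 1:524),
    admit_date = as.Date("2010-06-01"),
    baseline = 133,
    stage = rep(0:3, times = n),
    any_diagnosis = c(rep(TRUE, 74), rep(FALSE, 450)),
    admission_diagnosis = FALSE, main_diagnosis = FALSE)
  pats <- data.frame(patient_id = idx$patient_id, sex = "M",
                     birth_date = as.Date("1950-01-01"))
  tx <- data.frame(patient_id = idx$patient_id,
                   transplant_date = as.Date("2005-01-01"),
                   donor_type = "deceased")
  s <- summarize_cohort(idx, pats, tx)
  expect_equal(s$n, 524)
  expect_equal(s$any_aki$n, 236)
  expect_equal(s$any_aki$pct, 45.0)
  expect_equal(unname(s$stage_pct), c(55.0, 30.5, 4.0, 10.5))
  expect_equal(s$stage1_share_of_aki_pct, 67.8)
  expect_equal(unname(s$code_positive$pct["any_diagnosis"]), 14.1)
  expect_equal(s$women$n, 0)
  expect_equal(s$women$pct, 0)

  one <- summarize_cohort(idx[1, ], pats, tx)
  expect_true(is.na(one$age$sd))
})
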