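test_that("2x2 construction matches hand counts and conserves the cohort", {
  stage <- c(0, 0, 1, 2, 3, 0, 1, 0, 3, 2)
  code <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE)
  t <- build_two_by_two(stage, code, "stage_ge1")
  expect_equal(unlist(t[c("tp", "fp", "fn", "tn")]),
               c(tp = 4, fp = 1, fn = 2, tn = 3))
  t2 <- build_two_by_two(stage, code, "stage_eq3")
  expect_equal(t2$tp, 2)
  expect_equal(t$tp + t$fp + t$fn + t$tn, 10)

  empty <- build_two_by_two(integer(0), logical(0), "stage_ge1")
  expect_equal(empty$tp + empty$fp + empty$fn + empty$tn, 0)
  expect_error(build_two_by_two(c(1, 2), TRUE, "stage_ge1"),
               "different case sets")
  expect_error(two_by_two(-1, 0, 0, 0), "nonnegative")
})

test_that("Wilson interval is exact at the boundaries and symmetric at 1/2", {
  expect_equal(wilson_interval(0, 10)[1], 0)
  expect_equal(wilson_interval(10, 10)[2], 1)
  ci <- wilson_interval(5, 10)
  expect_equal(ci[1] + ci[2], 1)  # symmetric about 0.5
  expect_equal(wilson_interval(0, 0), c(NA_real_, NA_real_))
})

test_that("Wilson interval matches the root-finding oracle", {
  set.seed(77)
  for (i in 1:300) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    expect_equal(wilson_interval(k, n), wilson_root(k, n), tolerance = 1e-9)
  }
})

test_that("Wilson interval contains k/n and narrows with n", {
  set.seed(78)
  for (i in 1:50) {
    n <- sample(1:200, 1); k <- sample(0:n, 1)
    ci <- wilson_interval(k, n)
    expect_true(ci[1] <= k / n && k / n <= ci[2])
  }
  widths <- vapply(c(10, 20, 40, 80, 160, 320),
                   function(n) diff(wilson_interval(0.3 * n, n)), numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("accuracy metrics are consistent with their 2x2 counts", {
  t <- two_by_two(66, 8, 170, 280)
  p <- performance(t)
  expect_equal(p$estimate[p$metric == "sn"], 66 / 236)
  expect_equal(p$estimate[p$metric == "sp"], 280 / 288)
  expect_equal(p$estimate[p$metric == "ppv"], 66 / 74)
  expect_equal(p$estimate[p$metric == "npv"], 280 / 450)
  # integer consistency: estimate * denominator recovers the cell exactly
  set.seed(5)
  for (i in 1:25) {
    cells <- sample(0:300, 4, replace = TRUE)
    tt <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    pp <- performance(tt)
    sn <- pp[pp$metric == "sn", ]
    if (sn$n > 0) expect_equal(round(sn$estimate * sn$n), tt$tp)
  }
  # zero denominators are undefined, not errors
  degen <- performance(two_by_two(0, 0, 0, 10))
  expect_true(is.na(degen$estimate[degen$metric == "sn"]))
  expect_true(is.na(degen$estimate[degen$metric == "ppv"]))
  expect_equal(degen$estimate[degen$metric == "sp"], 1)
})

test_that("likelihood ratio modes differ exactly as documented", {
  expect_equal(positive_lr(0.5, 0.5, "exact"), 1)
  expect_true(is.na(positive_lr(0.5, 1, "exact")))
  # printed mode works from the rendered percents; exact mode does not
  sn <- 66 / 236; sp <- 280 / 288
  expect_equal(positive_lr(sn, sp, "printed"), 10.0)
  expect_equal(round_half_up(positive_lr(sn, sp, "exact"), 1), 10.1)
  expect_equal(positive_lr(13 / 76, 436 / 448, "printed"), 6.3)
  expect_equal(round_half_up(positive_lr(13 / 76, 436 / 448, "exact"), 1), 6.4)
  expect_equal(negative_lr(0.28, 0.972), 0.72 / 0.972)
})

test_that("small-cell suppression triggers on 1..threshold-1 but not zero", {
  expect_true(attr(apply_suppression(two_by_two(3, 50, 100, 371), 6),
                   "suppressed"))
  expect_false(attr(apply_suppression(two_by_two(0, 50, 100, 374), 6),
                    "suppressed"))
  expect_false(attr(apply_suppression(two_by_two(1, 1, 1, 1), 0),
                    "suppressed"))
  # suppressed rows render no partial values
  stage <- c(rep(1, 3), rep(0, 47))
  flags <- data.frame(any_diagnosis = c(rep(TRUE, 3), rep(FALSE, 47)),
                      admission_diagnosis = FALSE, main_diagnosis = FALSE)
  rep <- performance_report(stage, flags, algorithms = "any_diagnosis",
                            references = "stage_ge1", suppress_threshold = 6)
  expect_true(rep$suppressed)
  expect_true(all(is.na(rep[, c("tp", "sn", "sp", "lr_plus")])))
})
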