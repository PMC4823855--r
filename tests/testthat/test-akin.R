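test_that("staging reproduces the rule table at its boundaries", {
  expect_identical(akin_stage(100, 100), 0L)
  expect_identical(akin_stage(100, 126.4), 1L)   # absolute rise boundary inclusive
  expect_identical(akin_stage(100, 145), 1L)     # rise 45 >= 26.4 although ratio 1.45
  expect_identical(akin_stage(100, 200), 1L)     # 2-fold exactly stays stage 1
  expect_identical(akin_stage(100, 250), 2L)
  expect_identical(akin_stage(100, 300), 2L)     # 3-fold exactly stays stage 2
  expect_identical(akin_stage(100, 301), 3L)
  expect_identical(akin_stage(320, 370), 3L)     # absolute clause, ratio only 1.16
  expect_identical(akin_stage(310, 354), 1L)     # peak exactly 354 fails ">354"
  expect_identical(akin_stage(310, 355), 3L)     # rise 45 >= 44 with peak > 354
  expect_error(akin_stage(0, 100), "positive")
  expect_error(akin_stage(100, -1), "positive")
})

test_that("staging agrees with a literal rule-table oracle", {
  set.seed(421)
  b <- exp(runif(10000, log(30), log(500)))
  p <- b * exp(runif(10000, log(0.5), log(5)))
  expect_identical(akin_stage(b, p),
                   vapply(seq_along(b),
                          function(i) akin_stage_literal(b[i], p[i]),
                          integer(1)))
})

test_that("stage is nondecreasing in peak for fixed baseline", {
  for (b in c(40, 100, 133, 176, 200, 354, 500)) {
    stages <- akin_stage(rep(b, 400), seq(0.5 * b, 5 * b, length.out = 400))
    expect_true(all(diff(stages) >= 0))
  }
})

test_that("absolute criteria break scale invariance, ratio criteria keep it", {
  # ratio-driven stages survive rescaling below the absolute thresholds
  expect_identical(akin_stage(50, 125), akin_stage(100, 250))
  # but not across them: the same 2.5-fold rise from a high baseline crosses
  # the >354 umol/L absolute clause and escalates to stage 3
  expect_identical(akin_stage(1000, 2500), 3L)
  # absolute-rise stage 1 vanishes when scaled down tenfold
  expect_identical(akin_stage(100, 130), 1L)
  expect_identical(akin_stage(10, 13), 0L)
  # the >354 umol/L clause vanishes when scaled down tenfold
  expect_identical(akin_stage(320, 370), 3L)
  expect_identical(akin_stage(32, 37), 0L)
})

test_that("baseline selection takes the latest draw in the window", {
  labs <- data.frame(
    draw_date = as.Date("2010-06-01") - c(100, 20, 10),
    value = c(110, 120, 180))
  b <- select_baseline(labs, as.Date("2010-06-01"))
  expect_equal(b$value, 120)  # the -10 d draw is too recent to be baseline
  expect_equal(b$date, as.Date("2010-06-01") - 20)

  # the two-week bound is inclusive
  one <- data.frame(draw_date = as.Date("2010-06-01") - 14, value = 99)
  expect_equal(select_baseline(one, as.Date("2010-06-01"))$value, 99)

  # same-day duplicates on the chosen date are averaged
  dup <- data.frame(draw_date = as.Date("2010-06-01") - c(30, 30, 60),
                    value = c(100, 110, 90))
  expect_equal(select_baseline(dup, as.Date("2010-06-01"))$value, 105)

  # nothing in the window is a value, not an error
  out <- data.frame(draw_date = as.Date("2010-06-01") - c(10, 200), value = 1:2)
  expect_null(select_baseline(out, as.Date("2010-06-01")))
})

test_that("peak selection takes the maximum, ties broken by earliest date", {
  admit <- as.Date("2010-06-01")
  labs <- data.frame(draw_date = admit + c(0, 2, 4), value = c(120, 180, 150))
  expect_equal(peak_creatinine(labs, admit, admit + 5)$value, 180)
  tie <- data.frame(draw_date = admit + c(2, 5), value = c(180, 180))
  expect_equal(peak_creatinine(tie, admit, admit + 5)$date, admit + 2)
  expect_error(peak_creatinine(labs, admit + 30, admit + 35), "no in-admission")
})

test_that("cohort assessment computes changes per the reporting formulas", {
  ds <- conforming_dataset()
  ds$labs$value <- c(100, 150, 204.2)
  idx <- ds$admissions
  a <- assess_cohort(idx, ds$labs)
  expect_equal(a$baseline, 100)
  expect_equal(a$peak, 204.2)
  expect_equal(a$abs_change, 104.2)
  expect_equal(a$rel_change_pct, 104.2)
  expect_identical(a$stage, 2L)

  # zero change is stage 0 with zero changes
  ds$labs$value <- c(133, 120, 133)
  a0 <- assess_cohort(idx, ds$labs)
  expect_identical(a0$stage, 0L)
  expect_equal(a0$abs_change, 0)

  # a missing baseline names the offending admission
  ds$labs <- ds$labs[-1, ]
  expect_error(assess_cohort(idx, ds$labs), "A1")
})
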