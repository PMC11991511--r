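test_that("step and sleep discretizers honour the clinical cut-offs", {
  expect_equal(as.character(discretize_steps(c(0, 3000, 4999))),
               rep("sedentary", 3))
  expect_equal(as.character(discretize_steps(c(5000, 7500, 10000))),
               rep("medium", 3))
  expect_equal(as.character(discretize_steps(c(10001, 25000))),
               rep("active", 2))
  expect_error(discretize_steps(-1), "nonnegative")

  expect_equal(as.character(discretize_sleep(c(0, 0.75, 0.799))),
               rep("insufficient", 3))
  expect_equal(as.character(discretize_sleep(c(0.8, 0.85, 0.899))),
               rep("normal", 3))
  expect_equal(as.character(discretize_sleep(c(0.9, 0.95, 1))),
               rep("beneficial", 3))
  expect_error(discretize_sleep(1.2), "outside")
})

test_that("discretizers are total and monotone in the ordinal order", {
  steps <- sort(sample.int(30000, 500) - 1L)
  cat_steps <- discretize_steps(steps)
  expect_false(anyNA(cat_steps))
  expect_true(all(diff(as.integer(cat_steps)) >= 0))
  eff <- sort(runif(500))
  cat_eff <- discretize_sleep(eff)
  expect_false(anyNA(cat_eff))
  expect_true(all(diff(as.integer(cat_eff)) >= 0))
})

test_that("PHQ-4 severity bands match the operational categories", {
  expect_equal(as.character(phq4_severity(c(0, 2, 3, 5, 6, 8, 9, 12))),
               c("normal", "normal", "mild", "mild", "moderate",
                 "moderate", "severe", "severe"))
  expect_error(phq4_severity(13), "0..12")
})

test_that("event CSV reading groups, sorts and validates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID_ANON,activity,value,timestamp",
               "P1,daily_steps,3000,2023-02-03",
               "P1,daily_steps,1000,2023-02-01",
               "P1,daily_steps,2000,2023-02-02"), f)
  log <- read_event_log(f)
  expect_s3_class(log, "event_log")
  expect_equal(nrow(log), 3L)
  expect_equal(length(unique(log$case_id)), 1L)
  expect_equal(log$value, c(1000, 2000, 3000))  # sorted ascending by date

  writeLines(c("ID_ANON,activity,value,timestamp",
               "P1,daily_steps,3000,2023-02-01",
               "P1,daily_steps,1000,2023-02-01"), f)
  expect_error(read_event_log(f), "duplicate daily record")

  writeLines(c("ID_ANON,activity,value,timestamp",
               "P1,daily_steps,3000,not-a-date"), f)
  expect_error(read_event_log(f), "date")

  writeLines(c("ID_ANON,activity,value,timestamp",
               "P1,daily_steps,oops,2023-02-01"), f)
  expect_error(read_event_log(f), "value in row 1")
})

test_that("write/read round-trip is the identity on canonical logs", {
  log <- toy_log()
  f <- withr::local_tempfile(fileext = ".csv")
  write_event_log(log, f)
  expect_equal(read_event_log(f), log)
})

test_that("outcome labels follow the any-positive-questionnaire rule", {
  p <- rbind(toy_patients(c(1, 2, 2), c(2, 2, 2, 3), "P1"),
             toy_patients(c(0, 0, 3), c(0, 0, 0, 0), "P2"))
  lab <- label_outcomes(p)
  expect_equal(lab$vulnerable, c(FALSE, TRUE))
  expect_equal(lab$anxiety, c(TRUE, FALSE))

  empty <- toy_patients(integer(0), c(1, 1, 1, 1))
  expect_error(label_outcomes(empty), "no questionnaire scores")
  expect_error(label_outcomes(toy_patients(c(1, 11), c(0))), "VES-13")
})

test_that("patients CSV round-trips semicolon-joined scores", {
  p <- rbind(toy_patients(c(1, 2, 3), c(0, 1, 2, 3), "P1"),
             toy_patients(c(0, 0, 0), c(12, 0, 0, 0), "P2"))
  p$age <- c(70.5, 81.2); p$sex <- c("F", "M")
  f <- withr::local_tempfile(fileext = ".csv")
  write_patients(p, f)
  q <- read_patients(f)
  expect_equal(q$ves_scores, p$ves_scores)
  expect_equal(q$phq_scores, p$phq_scores)
  expect_equal(q$age, p$age)
})

test_that("run collapsing merges states and applies the gap rule", {
  v <- collapse_runs(toy_log(), "P1")
  expect_equal(v$state, c("sedentary", "medium", "active"))
  expect_equal(v$duration, c(2L, 1L, 1L))
  expect_equal(v$segment, rep(1L, 3))

  gap_log <- event_log(data.frame(
    case_id = "P1", activity = "daily_steps",
    value = c(100, 200, 300),
    timestamp = as.Date("2023-02-01") + c(0, 1, 8)))
  v <- collapse_runs(gap_log, "P1")
  expect_equal(v$state, c("sedentary", "sedentary"))
  expect_equal(v$duration, c(2L, 1L))
  expect_equal(v$segment, c(1L, 2L))

  # a gap within tolerance does not break the run
  short_gap <- event_log(data.frame(
    case_id = "P1", activity = "daily_steps",
    value = c(100, 200, 300),
    timestamp = as.Date("2023-02-01") + c(0, 1, 4)))
  v <- collapse_runs(short_gap, "P1")
  expect_equal(nrow(v), 1L)
  expect_equal(v$duration, 3L)

  single <- event_log(data.frame(case_id = "P1", activity = "daily_steps",
                                 value = 100,
                                 timestamp = as.Date("2023-02-01")))
  expect_equal(collapse_runs(single, "P1")$duration, 1L)
  expect_error(collapse_runs(single, "P1", activity = "sleep_efficiency"),
               "no 'sleep_efficiency' events")
})

test_that("visit durations partition the observed days", {
  co <- generate_cohort(cohort_config(n_patients = 12, seed = 5))
  for (case in co$patients$case_id[1:5]) {
    v <- collapse_runs(co$log, case)
    n_days <- sum(co$log$case_id == case &
                    co$log$activity == "daily_steps")
    expect_equal(sum(v$duration), n_days)
  }
})
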