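test_that("contingency tables tabulate id sets exactly", {
  t <- make_contingency(exposed = c("1", "2"), event = c("2", "3"),
                        universe = as.character(1:4))
  expect_equal(unclass(t)[c("a", "b", "c", "d")],
               list(a = 1L, b = 1L, c = 1L, d = 1L))
  t2 <- make_contingency(character(0), character(0), as.character(1:4))
  expect_equal(t2$a + t2$c, 0L)
  t3 <- make_contingency(as.character(1:4), c("1", "2"),
                         as.character(1:4))
  expect_equal(t3$c + t3$d, 0L)
  expect_error(make_contingency("1", "1", character(0)), "empty universe")
  expect_error(make_contingency("9", "1", as.character(1:4)), "subsets")
  expect_error(contingency_table(-1, 0, 0, 0), "nonnegative")
})

test_that("relative risk follows the 2x2 formula with explicit errors", {
  expect_equal(relative_risk(contingency_table(10, 10, 10, 10)), 1)
  # direct arithmetic oracle: (6/19) / (13/102)
  expect_equal(relative_risk(contingency_table(6, 13, 13, 89)),
               (6 / 19) / (13 / 102), tolerance = 1e-12)
  expect_equal(round(relative_risk(contingency_table(6, 13, 13, 89)), 4),
               2.4777)
  expect_equal(relative_risk(contingency_table(0, 19, 13, 89)), 0)
  expect_error(relative_risk(contingency_table(5, 5, 0, 10)),
               "undefined")
  expect_error(relative_risk(contingency_table(0, 0, 5, 5)),
               "degenerate")
})

test_that("log-method confidence intervals match the closed form", {
  ci <- rr_confidence_interval(contingency_table(10, 90, 10, 90))
  expect_equal(unname(ci["low"] * ci["high"]), 1, tolerance = 1e-9)

  t <- contingency_table(20, 80, 10, 90)
  ci <- rr_confidence_interval(t)
  se <- sqrt(1 / 20 - 1 / 100 + 1 / 10 - 1 / 100)
  z <- qnorm(0.975)
  expect_equal(unname(ci), c(2 * exp(-z * se), 2 * exp(z * se)),
               tolerance = 1e-12)
  expect_equal(round(unname(ci), 3), c(0.987, 4.054))

  wide <- rr_confidence_interval(t, level = 0.999)
  expect_lt(wide["low"], ci["low"])
  expect_gt(wide["high"], ci["high"])

  expect_error(rr_confidence_interval(contingency_table(0, 5, 3, 7)),
               "zero event cell")
  corr <- rr_confidence_interval(contingency_table(0, 5, 3, 7),
                                 correction = TRUE)
  expect_true(all(is.finite(corr)))
})

test_that("estimates are classified by where the interval sits", {
  expect_equal(assess_estimate(2.58, 1.13, 5.85), "positive_association")
  expect_equal(assess_estimate(1.22, 1.07, 1.39), "positive_association")
  expect_equal(assess_estimate(0.39, 0.17, 0.88), "protective")
  expect_equal(assess_estimate(0.9, 0.5, 1.6), "inconclusive")
  est <- risk_estimate(contingency_table(20, 80, 10, 90))
  expect_equal(est$classification, "inconclusive")
  expect_true(est$ci_low <= est$rr && est$rr <= est$ci_high)
  expect_equal(format(est), "2.00 (0.99; 4.05)")
})

test_that("sign duality holds on random tables", {
  set.seed(31)
  n <- 1e4
  a <- sample(1:50, n, TRUE); b <- sample(1:50, n, TRUE)
  cc <- sample(1:50, n, TRUE); d <- sample(1:50, n, TRUE)
  rr_event <- (a / (a + b)) / (cc / (cc + d))
  rr_comp <- (b / (a + b)) / (d / (cc + d))
  expect_true(all(sign(round(rr_event - 1, 12)) *
                    sign(round(rr_comp - 1, 12)) <= 0))
  # spot-check the vectorised oracle against the package on a sample
  for (i in sample(n, 20)) {
    expect_equal(relative_risk(contingency_table(a[i], b[i], cc[i], d[i])),
                 rr_event[i])
    expect_equal(relative_risk(contingency_table(b[i], a[i], d[i], cc[i])),
                 rr_comp[i])
  }
})

test_that("scaling all cells leaves the RR fixed and shrinks the CI", {
  t1 <- contingency_table(8, 12, 6, 24)
  t2 <- contingency_table(80, 120, 60, 240)
  expect_equal(relative_risk(t1), relative_risk(t2))
  ci1 <- rr_confidence_interval(t1)
  ci2 <- rr_confidence_interval(t2)
  expect_lt(diff(log(rev(unname(ci2)))) * -1,
            diff(log(rev(unname(ci1)))) * -1)
  expect_lt(ci2["high"] - ci2["low"], ci1["high"] - ci1["low"])
})

test_that("behaviour-strata risk tables carry dual estimates", {
  cl <- structure(list(
    clusters = list(sprintf("P%02d", 1:20), sprintf("P%02d", 21:60)),
    outliers = character(0), threshold = 0.3, min_size = 5L),
    class = "qt_clustering")
  lab <- setNames(c(rep(TRUE, 10), rep(FALSE, 10),
                    rep(TRUE, 4), rep(FALSE, 36)), sprintf("P%02d", 1:60))
  rt <- build_risk_table(cl, lab, outcome = "vulnerable",
                         universe = sprintf("P%02d", 1:60))
  r1 <- rt$rows[[1]]
  expect_equal(r1$event$rr, (10 / 20) / (4 / 40))  # hand-computed: 5
  expect_equal(r1$event$classification, "positive_association")
  expect_equal(r1$complement$classification, "protective")
  f <- format_risk_table(rt)
  expect_true(f$significant[1])
  expect_false(f$significant[2])
  expect_match(f$vulnerable[1], "^5\\.00 \\(")
  md <- risk_table_markdown(rt)
  expect_match(md, "\\*\\*cluster_1\\*\\*")
})

test_that("degenerate strata are marked, never silently estimated", {
  cl <- structure(list(clusters = list(c("P1", "P2", "P3")),
                       outliers = c("P4", "P5"),
                       threshold = 0.2, min_size = 2L),
                  class = "qt_clustering")
  all_neg <- setNames(rep(FALSE, 5), sprintf("P%d", 1:5))
  rt <- build_risk_table(cl, all_neg, universe = sprintf("P%d", 1:5))
  expect_true(rt$rows[[1]]$event$degenerate)
  expect_equal(rt$rows[[1]]$complement$rr, 1)

  solo <- structure(list(clusters = list("P1"), outliers = character(0),
                         threshold = 0.1, min_size = 2L),
                    class = "qt_clustering")
  rt2 <- build_risk_table(solo, setNames(TRUE, "P1"), universe = "P1")
  expect_true(rt2$rows[[1]]$event$degenerate)
  expect_equal(format_risk_table(rt2)$vulnerable, "-")
})

test_that("categorical exposures mirror the stratified contract", {
  set.seed(41)
  n <- 2000
  patients <- data.frame(
    case_id = sprintf("P%04d", 1:n),
    group = sample(LETTERS[1:5], n, TRUE),
    stringsAsFactors = FALSE)
  lab <- setNames(runif(n) < 0.3, patients$case_id)  # independent of group
  rt <- categorical_exposure_risk(patients, "group", lab,
                                  outcome = "vulnerable")
  expect_length(rt$rows, 5)
  for (r in rt$rows) {
    expect_false(isTRUE(r$event$degenerate))
    expect_lt(abs(r$event$rr - 1), 0.35)  # null: RR near 1 at this n
    # complement derives from the swapped table
    swapped <- contingency_table(r$event$table$b, r$event$table$a,
                                 r$event$table$d, r$event$table$c)
    expect_equal(r$complement$rr, relative_risk(swapped))
  }
  single <- data.frame(case_id = c("P1", "P2"), group = "A",
                       stringsAsFactors = FALSE)
  rt2 <- categorical_exposure_risk(
    single, "group", setNames(c(TRUE, FALSE), c("P1", "P2")))
  expect_true(rt2$rows[[1]]$event$degenerate)
})

test_that("share tables compute percentages from counts", {
  tab <- cohort_share_table(c(medium_to_active = 42,
                              medium_to_sedentary = 25), total = 121)
  expect_equal(tab$pct, c(34.7, 20.7))
  expect_equal(attr(tab, "total"), 121L)
  cl <- structure(list(clusters = list(c("a", "b"), c("c", "d", "e")),
                       outliers = "f", threshold = 0.5, min_size = 2L),
                  class = "qt_clustering")
  st <- clustering_share_table(cl)
  expect_equal(st$n, c(2L, 3L, 1L))
  expect_equal(sum(st$n), attr(st, "total"))
})
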