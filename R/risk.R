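#' 2x2 contingency table from id sets
#'
#' Tabulates exposure against event over a universe of case ids:
#' `a` exposed with the event, `b` exposed without, `c` unexposed with,
#' `d` unexposed without.
#'
#' @param exposed case ids of the exposed stratum (subset of `universe`).
#' @param event case ids experiencing the event (subset of `universe`).
#' @param universe all case ids under study (non-empty).
#' @return object of class `contingency_table` with integer fields
#'   `a`, `b`, `c`, `d`.
#' @export
make_contingency <- function(exposed, event, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  exposed <- unique(as.character(exposed))
  event <- unique(as.character(event))
  if (length(setdiff(exposed, universe)) ||
      length(setdiff(event, universe))) {
    stop("exposed and event sets must be subsets of the universe",
         call. = FALSE)
  }
  in_exp <- universe %in% exposed
  in_ev <- universe %in% event
  contingency_table(sum(in_exp & in_ev), sum(in_exp & !in_ev),
                    sum(!in_exp & in_ev), sum(!in_exp & !in_ev))
}

#' @rdname make_contingency
#' @param a,b,c,d nonnegative integer cell counts.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  cells <- as.list(setNames(as.integer(cells), c("a", "b", "c", "d")))
  structure(cells, class = "contingency_table")
}

#' Relative risk of a 2x2 table
#'
#' `RR = (a / (a + b)) / (c / (c + d))`: the probability of the event in
#' the exposed group over the probability in the unexposed group. An
#' empty margin (`a + b = 0` or `c + d = 0`) is a degenerate stratum and
#' an error; `c = 0` leaves the RR undefined and is an explicit error —
#' never a silent infinity.
#'
#' @param t a [contingency_table()].
#' @return the relative risk (numeric scalar, >= 0).
#' @export
relative_risk <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$a + t$b == 0L || t$c + t$d == 0L) {
    stop("degenerate stratum: an exposure margin is empty", call. = FALSE)
  }
  if (t$c == 0L) {
    stop("relative risk undefined: no events among the unexposed",
         call. = FALSE)
  }
  (t$a / (t$a + t$b)) / (t$c / (t$c + t$d))
}

#' Log-method (Katz) confidence interval for a relative risk
#'
#' The standard error of `log(RR)` is
#' `sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))` and the bounds are
#' `RR * exp(-z * se)` and `RR * exp(+z * se)` with `z` the standard
#' normal quantile of the requested level. Zero event cells (`a = 0` or
#' `c = 0`) leave the interval undefined; with `correction = TRUE` the
#' Haldane-Anscombe correction adds 0.5 to every cell first (never
#' silently).
#'
#' @param t a [contingency_table()].
#' @param level confidence level in (0,1); default 0.95.
#' @param correction apply the +0.5 continuity correction to all cells;
#'   default `FALSE`.
#' @return named numeric vector `c(low, high)`.
#' @export
rr_confidence_interval <- function(t, level = 0.95, correction = FALSE) {
  stopifnot(inherits(t, "contingency_table"), level > 0, level < 1)
  a <- t$a; b <- t$b; cc <- t$c; d <- t$d
  if (correction) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  if (a == 0 || cc == 0) {
    stop("zero event cell: enable the continuity correction or treat ",
         "the stratum as degenerate", call. = FALSE)
  }
  rr <- (a / (a + b)) / (cc / (cc + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / cc - 1 / (cc + d))
  z <- qnorm(1 - (1 - level) / 2)
  c(low = rr * exp(-z * se), high = rr * exp(z * se))
}

#' Risk estimate with classification
#'
#' Combines the relative risk, its confidence interval and the
#' association class: `positive_association` when the whole interval
#' exceeds 1, `protective` when it lies below 1, otherwise
#' `inconclusive`.
#'
#' @inheritParams rr_confidence_interval
#' @return object of class `risk_estimate` with fields `rr`, `ci_low`,
#'   `ci_high`, `classification`, `level` and the table `t`.
#' @export
risk_estimate <- function(t, level = 0.95, correction = FALSE) {
  rr <- if (correction) {
    a <- t$a + 0.5; b <- t$b + 0.5; cc <- t$c + 0.5; d <- t$d + 0.5
    (a / (a + b)) / (cc / (cc + d))
  } else {
    relative_risk(t)
  }
  ci <- rr_confidence_interval(t, level, correction)
  structure(list(rr = rr, ci_low = unname(ci["low"]),
                 ci_high = unname(ci["high"]),
                 classification = assess_estimate(rr, ci["low"], ci["high"]),
                 level = level, table = t),
            class = "risk_estimate")
}

#' @rdname risk_estimate
#' @param rr,ci_low,ci_high a relative risk and its interval bounds.
#' @export
assess_estimate <- function(rr, ci_low, ci_high) {
  if (ci_low > 1) "positive_association"
  else if (ci_high < 1 && rr < 1) "protective"
  else "inconclusive"
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf("RR %.2f (%.2f; %.2f) [%s]\n", x$rr, x$ci_low, x$ci_high,
              x$classification))
  invisible(x)
}

#' @export
format.risk_estimate <- function(x, ...) {
  sprintf("%.2f (%.2f; %.2f)", x$rr, x$ci_low, x$ci_high)
}

risk_row <- function(stratum, exposed, positives, universe, level,
                     correction) {
  negatives <- setdiff(universe, positives)
  row <- list(stratum = stratum, n = length(exposed))
  for (side in c("event", "complement")) {
    ev <- if (side == "event") positives else negatives
    t <- make_contingency(exposed, ev, universe)
    est <- tryCatch(risk_estimate(t, level, correction),
                    error = function(e) e)
    if (inherits(est, "error")) {
      row[[side]] <- list(degenerate = TRUE,
                          reason = conditionMessage(est))
    } else {
      row[[side]] <- est
    }
  }
  row
}

#' Dual event/complement risk table over behaviour strata
#'
#' One row per cluster of the clustering (named `cluster_1`, ... in
#' cluster order) plus, when non-empty and requested, an `outliers`
#' stratum. For each stratum the *event* column is the relative risk of
#' reporting the outcome (exposed = stratum members, non-exposed = the
#' rest) and the *complement* column the relative risk of not reporting
#' it; the two derive from complementary tables (a and b, c and d
#' swapped). Rows whose estimates cannot be computed (an empty margin or
#' a zero event cell with the correction disabled) carry a degenerate
#' marker instead of an estimate.
#'
#' @param clustering a [qt_cluster()] result.
#' @param labels an `outcome_labels` data frame (see [label_outcomes()])
#'   or a named logical vector.
#' @param outcome which outcome to tabulate: `"vulnerable"` or
#'   `"anxiety"`.
#' @param universe case ids of the full study population; defaults to
#'   all clustered cases plus outliers.
#' @param include_outliers include the outlier stratum as a row;
#'   default `TRUE`.
#' @param level confidence level; default 0.95.
#' @param correction Haldane-Anscombe +0.5 correction for zero cells;
#'   default `FALSE`.
#' @return object of class `risk_table`: a list of rows, each with the
#'   stratum name, size and the two [risk_estimate()]s (or degenerate
#'   markers).
#' @export
build_risk_table <- function(clustering, labels, outcome = "vulnerable",
                             universe = NULL, include_outliers = TRUE,
                             level = 0.95, correction = FALSE) {
  lab <- as_label_vector(labels, outcome)
  if (is.null(universe)) {
    universe <- c(unlist(clustering$clusters), clustering$outliers)
  }
  universe <- unique(as.character(universe))
  missing <- setdiff(universe, names(lab))
  if (length(missing)) {
    stop("labels missing for case(s): ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  positives <- universe[lab[universe]]
  rows <- list()
  for (i in seq_along(clustering$clusters)) {
    rows[[length(rows) + 1L]] <-
      risk_row(paste0("cluster_", i), clustering$clusters[[i]],
               positives, universe, level, correction)
  }
  if (include_outliers && length(clustering$outliers)) {
    rows[[length(rows) + 1L]] <-
      risk_row("outliers", clustering$outliers, positives, universe,
               level, correction)
  }
  structure(list(rows = rows, outcome = outcome, level = level),
            class = "risk_table")
}

#' Risk table over the levels of a categorical patient attribute
#'
#' Same dual event/complement contract as [build_risk_table()], with one
#' row per level of a categorical attribute (e.g. `cancer_type`); levels
#' without members are skipped with a warning.
#'
#' @param patients patients data frame with a `case_id` column.
#' @param attribute name of the categorical column (e.g.
#'   `"cancer_type"`).
#' @param labels outcome labels (see [build_risk_table()]).
#' @param outcome outcome column name.
#' @param level confidence level.
#' @param correction continuity correction flag.
#' @return a `risk_table`.
#' @export
categorical_exposure_risk <- function(patients, attribute, labels,
                                      outcome = "vulnerable",
                                      level = 0.95, correction = FALSE) {
  stopifnot(attribute %in% names(patients))
  lab <- as_label_vector(labels, outcome)
  universe <- as.character(patients$case_id)
  positives <- universe[lab[universe]]
  values <- as.character(patients[[attribute]])
  rows <- list()
  for (lev in sort(unique(values))) {
    exposed <- universe[values == lev]
    if (!length(exposed)) {
      warning("attribute level '", lev, "' has no members; skipped",
              call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <-
      risk_row(lev, exposed, positives, universe, level, correction)
  }
  structure(list(rows = rows, outcome = outcome, level = level),
            class = "risk_table")
}

#' Render a risk table
#'
#' `format_risk_table()` returns a data frame with the conventional
#' `"X (Y; Z)"` cells (RR and confidence bounds rounded to 2 decimals)
#' for the event and its complement; statistically positive rows are
#' marked. `write_risk_table()` writes the CSV; `risk_table_markdown()`
#' renders Markdown with significant cells in bold.
#'
#' @param rt a `risk_table`.
#' @return a data frame with columns `stratum`, `n`, `complement`,
#'   `event` and `significant`.
#' @export
format_risk_table <- function(rt) {
  fmt <- function(e) {
    if (isTRUE(e$degenerate)) "-" else format(e)
  }
  out <- data.frame(
    stratum = vapply(rt$rows, `[[`, character(1), "stratum"),
    n = vapply(rt$rows, `[[`, numeric(1), "n"),
    complement = vapply(rt$rows, function(r) fmt(r$complement),
                        character(1)),
    event = vapply(rt$rows, function(r) fmt(r$event), character(1)),
    significant = vapply(rt$rows, function(r) {
      !isTRUE(r$event$degenerate) &&
        identical(r$event$classification, "positive_association")
    }, logical(1)),
    stringsAsFactors = FALSE
  )
  names(out)[names(out) == "event"] <- rt$outcome
  names(out)[names(out) == "complement"] <- paste0("no_", rt$outcome)
  out
}

#' @rdname format_risk_table
#' @param path file path.
#' @export
write_risk_table <- function(rt, path) {
  write.csv(format_risk_table(rt), path, row.names = FALSE)
  invisible(path)
}

#' @rdname format_risk_table
#' @export
risk_table_markdown <- function(rt) {
  f <- format_risk_table(rt)
  ev <- names(f)[4]
  no <- names(f)[3]
  body <- vapply(seq_len(nrow(f)), function(i) {
    b <- function(x) if (f$significant[i]) paste0("**", x, "**") else x
    sprintf("| %s | %d | %s | %s |", b(f$stratum[i]), as.integer(f$n[i]),
            f[[no]][i], b(f[[ev]][i]))
  }, character(1))
  paste(c(sprintf("| Stratum | n | %s | %s |", no, ev),
          "|---|---|---|---|", body), collapse = "\n")
}

#' @export
print.risk_table <- function(x, ...) {
  print(format_risk_table(x))
  invisible(x)
}
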