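#' Event logs of daily wearable observations
#'
#' An event log is a table of timestamped observations. Each row (an
#' *event*) carries the patient identifier (`case_id`), the recorded
#' activity (e.g. `daily_steps` or `sleep_efficiency`), the numeric value
#' and the calendar date. All events of one patient form a *trace* (a
#' case); the set of traces is the log, the input object of process
#' mining.
#'
#' `event_log()` validates and canonicalises a data frame: dates are
#' parsed to `Date`, events are sorted by case, activity and date, and
#' duplicate `(case_id, activity, timestamp)` observations are rejected —
#' the log is daily-granular, so at most one value per activity and day
#' is meaningful.
#'
#' @param data data frame with columns `case_id`, `activity`, `value`,
#'   `timestamp`.
#' @return A data frame of class `event_log`.
#' @seealso [read_event_log()], [collapse_runs()]
#' @export
event_log <- function(data) {
  need <- c("case_id", "activity", "value", "timestamp")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing event-log columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data)[need]
  data$case_id <- as.character(data$case_id)
  data$activity <- as.character(data$activity)
  val <- suppressWarnings(as.numeric(data$value))
  bad <- which(!is.finite(val))
  if (length(bad)) {
    stop("non-finite or unparseable value in row ", bad[1], call. = FALSE)
  }
  data$value <- val
  ts <- as.Date(as.character(data$timestamp), format = "%Y-%m-%d")
  bad <- which(is.na(ts))
  if (length(bad)) {
    stop("unparseable ISO-8601 date in row ", bad[1], ": '",
         data$timestamp[bad[1]], "'", call. = FALSE)
  }
  data$timestamp <- ts
  key <- paste(data$case_id, data$activity, format(data$timestamp))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate daily record for (", d, ")", call. = FALSE)
  }
  data <- data[order(data$case_id, data$activity, data$timestamp), ,
               drop = FALSE]
  rownames(data) <- NULL
  class(data) <- c("event_log", "data.frame")
  data
}

#' Read and write event-log CSV files
#'
#' The CSV dialect has a mandatory header `ID_ANON,activity,value,timestamp`
#' (comma-separated, UTF-8) with one event per row and ISO-8601 dates, the
#' layout in which process-mining logs of daily tracker summaries are
#' exchanged. Reading groups events into traces sorted by date; writing is
#' the exact inverse, so `read_event_log(write_event_log(log))` is the
#' identity on canonical logs.
#'
#' @param path file path.
#' @param log an [event_log()].
#' @return `read_event_log()` returns an `event_log`;
#'   `write_event_log()` returns `path` invisibly.
#' @export
read_event_log <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("ID_ANON", "activity", "value", "timestamp")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("event CSV lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  names(raw)[names(raw) == "ID_ANON"] <- "case_id"
  event_log(raw)
}

#' @rdname read_event_log
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  out <- data.frame(ID_ANON = log$case_id, activity = log$activity,
                    value = log$value,
                    timestamp = format(log$timestamp, "%Y-%m-%d"))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> %d events, %d cases, activities: %s\n",
              nrow(x), length(unique(x$case_id)),
              paste(sort(unique(x$activity)), collapse = ", ")))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more events\n")
  invisible(x)
}

#' Label self-reported outcomes from questionnaire scores
#'
#' A patient is labelled *vulnerable* when at least one VES-13 total is
#' positive (score >= 3) and at *anxiety/depression risk* when at least
#' one PHQ-4 total is positive (score >= 3); patients whose questionnaires
#' all stay below the cut-offs are labelled negative.
#'
#' @param patients data frame with columns `case_id`, `ves_scores`,
#'   `phq_scores`; the score columns are either list columns of integer
#'   vectors or semicolon-joined strings (the patients-CSV encoding).
#' @return data frame of class `outcome_labels` with columns `case_id`,
#'   `vulnerable`, `anxiety` (logicals).
#' @export
label_outcomes <- function(patients) {
  stopifnot(all(c("case_id", "ves_scores", "phq_scores") %in% names(patients)))
  ves <- parse_scores(patients$ves_scores, 0L, 10L, "VES-13")
  phq <- parse_scores(patients$phq_scores, 0L, 12L, "PHQ-4")
  empty <- which(lengths(ves) == 0L | lengths(phq) == 0L)
  if (length(empty)) {
    stop("no questionnaire scores for case ",
         patients$case_id[empty[1]], call. = FALSE)
  }
  out <- data.frame(
    case_id = as.character(patients$case_id),
    vulnerable = vapply(ves, function(s) any(s >= 3L), logical(1)),
    anxiety = vapply(phq, function(s) any(s >= 3L), logical(1)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("outcome_labels", "data.frame")
  out
}

parse_scores <- function(x, lo, hi, what) {
  if (!is.list(x)) {
    x <- lapply(strsplit(as.character(x), ";", fixed = TRUE), function(s) {
      s <- trimws(s[nzchar(trimws(s))])
      as.integer(s)
    })
  }
  x <- lapply(x, as.integer)
  for (s in x) {
    if (any(is.na(s)) || any(s < lo | s > hi)) {
      stop(what, " scores must be integers in ", lo, "..", hi, call. = FALSE)
    }
  }
  x
}

join_scores <- function(x) {
  vapply(x, function(s) paste(as.integer(s), collapse = ";"), character(1))
}

#' Read and write patient-attribute CSV files
#'
#' Columns: `case_id`, `age`, `sex`, `country`, `cancer_type`,
#' `activity_archetype`, `sleep_archetype`, `ves_scores`, `phq_scores`,
#' with questionnaire scores semicolon-joined. In memory the score columns
#' are list columns of integer vectors.
#'
#' @param patients patients data frame (as from [generate_cohort()]).
#' @param path file path.
#' @export
write_patients <- function(patients, path) {
  out <- patients
  out$ves_scores <- join_scores(out$ves_scores)
  out$phq_scores <- join_scores(out$phq_scores)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_patients
#' @export
read_patients <- function(path) {
  p <- read.csv(path, stringsAsFactors = FALSE)
  p$case_id <- as.character(p$case_id)
  p$ves_scores <- parse_scores(p$ves_scores, 0L, 10L, "VES-13")
  p$phq_scores <- parse_scores(p$phq_scores, 0L, 12L, "PHQ-4")
  p
}
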