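#' Collapse daily states into visits
#'
#' A *visit* is a maximal run of consecutive observed days spent in the
#' same discretized state; its duration counts the observed days of the
#' run. Short calendar gaps (missing days) of at most `max_gap` days
#' inside a same-state run do not break it; a longer gap ends the current
#' visit, starts a new *segment*, and no transition is recorded across the
#' break when the visits are later turned into a process model.
#'
#' @param log an [event_log()].
#' @param case a case id present in `log`.
#' @param activity activity label to collapse (e.g. `"daily_steps"`).
#' @param scheme the [disc_scheme()] used to discretize the values.
#' @param max_gap largest calendar gap (in days) bridged inside a visit;
#'   default 2.
#' @return data frame with columns `state`, `start` (date of the first
#'   observed day), `duration` (observed days) and `segment` (integer id
#'   of the unbroken stretch the visit belongs to).
#' @examples
#' log <- event_log(data.frame(
#'   case_id = "P1", activity = "daily_steps",
#'   value = c(1000, 2000, 7000, 12000),
#'   timestamp = as.Date("2023-02-01") + 0:3))
#' collapse_runs(log, "P1")
#' @export
collapse_runs <- function(log, case, activity = "daily_steps",
                          scheme = steps_scheme(), max_gap = 2) {
  stopifnot(inherits(log, "event_log"))
  ev <- log[log$case_id == case & log$activity == activity, , drop = FALSE]
  if (nrow(ev) == 0L) {
    stop("no '", activity, "' events for case ", case, call. = FALSE)
  }
  ev <- ev[order(ev$timestamp), , drop = FALSE]
  states <- as.character(discretize(ev$value, scheme))
  gaps <- c(0, diff(as.numeric(ev$timestamp)) - 1)  # skipped days before each event
  broken <- gaps > max_gap
  segment <- cumsum(broken) + 1L
  new_visit <- broken | c(TRUE, states[-1L] != states[-length(states)])
  vid <- cumsum(new_visit)
  data.frame(
    state = states[new_visit],
    start = ev$timestamp[new_visit],
    duration = as.integer(tabulate(vid)),
    segment = segment[new_visit],
    stringsAsFactors = FALSE
  )
}

#' Visit sequences for process discovery
#'
#' Collapses every trace of the log into visits and splits each trace at
#' broken gaps, yielding one ordered visit list per unbroken segment.
#' These sequences are the direct input of [discover_model()].
#'
#' @inheritParams collapse_runs
#' @return named list of visit data frames (`state`, `start`, `duration`),
#'   names `"<case>#<segment>"`.
#' @export
visit_sequences <- function(log, activity = "daily_steps",
                            scheme = steps_scheme(), max_gap = 2) {
  cases <- sort(unique(log$case_id[log$activity == activity]))
  if (!length(cases)) stop("no '", activity, "' events in log", call. = FALSE)
  out <- list()
  for (case in cases) {
    v <- collapse_runs(log, case, activity, scheme, max_gap)
    for (seg in unique(v$segment)) {
      out[[paste0(case, "#", seg)]] <-
        v[v$segment == seg, c("state", "start", "duration"), drop = FALSE]
    }
  }
  out
}

#' Daily discretized state sequences per case
#'
#' Returns, for each case, the chronological sequence of discretized
#' states of the given activity (one element per observed day, calendar
#' gaps simply absent). These sequences feed the alignment distance used
#' for trace clustering.
#'
#' @inheritParams collapse_runs
#' @return named list of character vectors, one per case, names the case
#'   ids (sorted).
#' @export
state_sequences <- function(log, activity = "daily_steps",
                            scheme = steps_scheme()) {
  stopifnot(inherits(log, "event_log"))
  ev <- log[log$activity == activity, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no '", activity, "' events in log", call. = FALSE)
  ev <- ev[order(ev$case_id, ev$timestamp), , drop = FALSE]
  states <- as.character(discretize(ev$value, scheme))
  split(states, ev$case_id)
}
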