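#' Discretization schemes for daily wearable measures
#'
#' A discretization scheme maps a finite numeric measurement to exactly one
#' of an ordered set of behaviour categories. Two schemes are built in,
#' following cut-offs in common clinical use for older adults:
#'
#' * `steps_scheme()`: daily step counts. Fewer than 5000 steps is a
#'   `sedentary` day, 5000 to 10000 steps (both ends included) is `medium`
#'   activity, and more than 10000 steps is an `active` day.
#' * `sleep_scheme()`: nightly sleep efficiency (fraction of time in bed
#'   spent asleep, in `[0, 1]`). Below 0.80 is `insufficient`, 0.80 up to
#'   but not including 0.90 is `normal`, and 0.90 or higher is
#'   `beneficial`.
#'
#' Boundaries are strictly increasing and the intervals are left-closed
#' (`[b_i, b_{i+1})`), so every finite value maps to exactly one category;
#' for step counts the upper boundary is placed just above 10000 so that
#' 10000 itself still counts as `medium`.
#'
#' @param name scheme name.
#' @param categories ordered character vector of category labels.
#' @param boundaries strictly increasing numeric cut points; one fewer than
#'   the number of categories.
#' @param range permitted closed input range, used for validation.
#' @return An object of class `disc_scheme`.
#' @examples
#' discretize(c(3000, 10000, 10001), steps_scheme())
#' discretize(c(0.75, 0.85, 0.9), sleep_scheme())
#' @export
disc_scheme <- function(name, categories, boundaries, range = c(-Inf, Inf)) {
  stopifnot(is.character(categories), length(categories) >= 2)
  if (length(boundaries) != length(categories) - 1L) {
    stop("need exactly one boundary fewer than categories", call. = FALSE)
  }
  if (any(diff(boundaries) <= 0)) {
    stop("boundaries must be strictly increasing", call. = FALSE)
  }
  structure(
    list(name = name, categories = categories,
         boundaries = as.numeric(boundaries), range = as.numeric(range)),
    class = "disc_scheme"
  )
}

#' @rdname disc_scheme
#' @export
steps_scheme <- function() {
  # 10000 steps is still "medium", so the upper cut sits just above it;
  # step counts are integers, so nothing falls in (10000, 10001).
  disc_scheme("daily_steps", c("sedentary", "medium", "active"),
              boundaries = c(5000, 10000 + 1e-9), range = c(0, Inf))
}

#' @rdname disc_scheme
#' @export
sleep_scheme <- function() {
  disc_scheme("sleep_efficiency", c("insufficient", "normal", "beneficial"),
              boundaries = c(0.8, 0.9), range = c(0, 1))
}

#' Discretize numeric measurements into ordered behaviour states
#'
#' @param x numeric vector of measurements; must be finite and within the
#'   scheme's permitted range.
#' @param scheme a [disc_scheme()].
#' @return factor with the scheme's categories as ordered levels.
#' @export
discretize <- function(x, scheme) {
  stopifnot(inherits(scheme, "disc_scheme"))
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("values must be finite", call. = FALSE)
  if (any(x < scheme$range[1] | x > scheme$range[2])) {
    stop(sprintf("values outside [%g, %g] for scheme '%s'",
                 scheme$range[1], scheme$range[2], scheme$name),
         call. = FALSE)
  }
  idx <- findInterval(x, scheme$boundaries) + 1L
  factor(scheme$categories[idx], levels = scheme$categories, ordered = TRUE)
}

#' @rdname discretize
#' @param steps nonnegative integer vector of daily step counts.
#' @export
discretize_steps <- function(steps) {
  if (any(steps < 0)) stop("step counts must be nonnegative", call. = FALSE)
  discretize(steps, steps_scheme())
}

#' @rdname discretize
#' @param efficiency numeric vector of sleep-efficiency fractions in `[0, 1]`.
#' @export
discretize_sleep <- function(efficiency) {
  discretize(efficiency, sleep_scheme())
}

#' PHQ-4 severity bands
#'
#' Maps total PHQ-4 scores (0-12) to the standard operational severity
#' categories: normal (0-2), mild (3-5), moderate (6-8), severe (9-12).
#'
#' @param score integer vector of PHQ-4 total scores.
#' @return factor with levels normal < mild < moderate < severe.
#' @export
phq4_severity <- function(score) {
  score <- as.integer(score)
  if (any(is.na(score)) || any(score < 0L | score > 12L)) {
    stop("PHQ-4 scores must be integers in 0..12", call. = FALSE)
  }
  bands <- c("normal", "mild", "moderate", "severe")
  idx <- findInterval(score, c(3, 6, 9)) + 1L
  factor(bands[idx], levels = bands, ordered = TRUE)
}
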