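#' Behaviour archetypes as first-order Markov chains
#'
#' An archetype is a distribution over daily behaviour states: an initial
#' probability vector and a row-stochastic 3x3 transition matrix over the
#' ordered states of its domain (`sedentary < medium < active` for steps,
#' `insufficient < normal < beneficial` for sleep efficiency). Synthetic
#' patients assigned to an archetype evolve day by day under its chain.
#'
#' @param name archetype name.
#' @param states ordered state labels (length 3).
#' @param initial_dist probability vector over the states.
#' @param transition 3x3 row-stochastic matrix; rows and columns in state
#'   order.
#' @return object of class `archetype`.
#' @export
archetype <- function(name, states, initial_dist, transition) {
  initial_dist <- as.numeric(initial_dist)
  transition <- as.matrix(transition)
  stopifnot(length(states) == 3L, length(initial_dist) == 3L,
            all(dim(transition) == c(3L, 3L)))
  if (any(initial_dist < 0) || abs(sum(initial_dist) - 1) > 1e-9) {
    stop("initial_dist must be a probability vector", call. = FALSE)
  }
  if (any(transition < 0) || any(transition > 1) ||
      any(abs(rowSums(transition) - 1) > 1e-9)) {
    stop("transition rows must each sum to 1 with entries in [0,1]",
         call. = FALSE)
  }
  dimnames(transition) <- list(states, states)
  structure(list(name = name, states = states,
                 initial_dist = setNames(initial_dist, states),
                 transition = transition),
            class = "archetype")
}

act_states <- c("sedentary", "medium", "active")
slp_states <- c("insufficient", "normal", "beneficial")

#' Default activity archetypes
#'
#' Five activity behaviours, each given a distinct day-to-day dynamic so
#' the groups are numerically separable under the alignment distance as
#' well as visually distinct as workflows:
#'
#' * `active`: a dominantly active pattern (stationary active share
#'   about 0.9).
#' * `medium_to_active`: medium days interleaved with frequent active
#'   days in a near-alternating rhythm (active share just under 0.5).
#' * `medium_to_sedentary`: a medium-dominant mixture with recurring
#'   sedentary days (sedentary share about 0.25).
#' * `sedentary`: low overall activity cycling between sedentary and
#'   medium days in a near-alternating rhythm.
#' * `long_sedentary`: persistent multi-day sedentary runs (self-stay
#'   0.92 on the sedentary state, stationary sedentary occupancy above
#'   0.8).
#'
#' @return named list of [archetype()] objects.
#' @export
activity_archetypes <- function() {
  list(
    medium_to_active = archetype(
      "medium_to_active", act_states,
      initial_dist = c(0.02, 0.58, 0.40),
      transition = rbind(c(0.06, 0.84, 0.10),
                         c(0.02, 0.10, 0.88),
                         c(0.02, 0.88, 0.10))),
    medium_to_sedentary = archetype(
      "medium_to_sedentary", act_states,
      initial_dist = c(0.25, 0.72, 0.03),
      transition = rbind(c(0.30, 0.68, 0.02),
                         c(0.25, 0.72, 0.03),
                         c(0.10, 0.80, 0.10))),
    active = archetype(
      "active", act_states,
      initial_dist = c(0.02, 0.08, 0.90),
      transition = rbind(c(0.08, 0.32, 0.60),
                         c(0.02, 0.12, 0.86),
                         c(0.01, 0.07, 0.92))),
    long_sedentary = archetype(
      "long_sedentary", act_states,
      initial_dist = c(0.95, 0.04, 0.01),
      transition = rbind(c(0.92, 0.07, 0.01),
                         c(0.85, 0.14, 0.01),
                         c(0.80, 0.15, 0.05))),
    sedentary = archetype(
      "sedentary", act_states,
      initial_dist = c(0.50, 0.47, 0.03),
      transition = rbind(c(0.10, 0.88, 0.02),
                         c(0.90, 0.08, 0.02),
                         c(0.45, 0.50, 0.05)))
  )
}

#' Default sleep archetypes
#'
#' Three sleep behaviours plus an outlier generator:
#'
#' * `insufficient`: consistently insufficient nights (stationary
#'   insufficient share about 0.9).
#' * `insufficient_with_dynamism`: night-to-night alternation between
#'   insufficient and normal sleep (off-diagonal mass >= 0.4 between
#'   those states), with slightly more time insufficient than normal.
#' * `balanced`: stable, adequate sleep cycling between normal and
#'   beneficial nights with only occasional insufficient ones.
#'
#' The `outlier` archetype is not a shared chain: each outlier patient
#' gets an idiosyncratic high-variance transition matrix drawn from a
#' low-concentration Dirichlet, so outliers are heterogeneous and
#' resist clustering.
#'
#' @return named list of [archetype()] objects; the `outlier` entry is a
#'   template whose chain is redrawn per patient.
#' @export
sleep_archetypes <- function() {
  list(
    insufficient = archetype(
      "insufficient", slp_states,
      initial_dist = c(0.95, 0.04, 0.01),
      transition = rbind(c(0.95, 0.04, 0.01),
                         c(0.85, 0.13, 0.02),
                         c(0.70, 0.25, 0.05))),
    insufficient_with_dynamism = archetype(
      "insufficient_with_dynamism", slp_states,
      initial_dist = c(0.52, 0.46, 0.02),
      transition = rbind(c(0.14, 0.84, 0.02),
                         c(0.90, 0.08, 0.02),
                         c(0.45, 0.50, 0.05))),
    balanced = archetype(
      "balanced", slp_states,
      initial_dist = c(0.04, 0.48, 0.48),
      transition = rbind(c(0.08, 0.52, 0.40),
                         c(0.03, 0.32, 0.65),
                         c(0.03, 0.65, 0.32))),
    outlier = archetype(
      "outlier", slp_states,
      initial_dist = c(1, 1, 1) / 3,
      transition = matrix(1 / 3, 3, 3))
  )
}

# Idiosyncratic high-temperature chain for one outlier patient: rows ~
# Dirichlet(alpha). Near-uniform rows keep every outlier's sequence
# high-entropy, so outliers sit far (> 0.27) from each other and from
# the structured archetypes under the alignment distance.
random_outlier_archetype <- function(alpha = 2) {
  draw_row <- function() {
    g <- stats::rgamma(3L, shape = alpha, rate = 1)
    if (sum(g) <= 0) g <- rep(1, 3L)
    g / sum(g)
  }
  tr <- rbind(draw_row(), draw_row(), draw_row())
  archetype("outlier", slp_states, initial_dist = draw_row(), transition = tr)
}

#' Simulate a daily state sequence from an archetype
#'
#' Draws the first state from the archetype's initial distribution and
#' each subsequent state from the transition row of the current state,
#' using the current RNG stream.
#'
#' @param arch an [archetype()].
#' @param n_days number of days (>= 1).
#' @return character vector of length `n_days` of state labels.
#' @export
sample_daily_states <- function(arch, n_days) {
  stopifnot(inherits(arch, "archetype"), n_days >= 1)
  n_days <- as.integer(n_days)
  s <- integer(n_days)
  s[1L] <- sample.int(3L, 1L, prob = arch$initial_dist)
  if (n_days > 1L) {
    for (i in 2:n_days) {
      s[i] <- sample.int(3L, 1L, prob = arch$transition[s[i - 1L], ])
    }
  }
  arch$states[s]
}

#' Map state sequences back to plausible numeric measurements
#'
#' Inverse of the discretizers: each state label is replaced by a value
#' drawn uniformly from strictly inside its numeric interval, so that
#' discretizing the result returns the input states exactly. Step counts
#' are integers (`sedentary` 0-4999, `medium` 5000-10000, `active`
#' 10001-20000); sleep efficiencies are fractions (`insufficient`
#' 0.50-0.799, `normal` 0.80-0.899, `beneficial` 0.90-0.99).
#'
#' @param states character vector of state labels.
#' @param kind `"steps"` or `"sleep"`.
#' @return numeric vector of the same length.
#' @export
states_to_values <- function(states, kind = c("steps", "sleep")) {
  kind <- match.arg(kind)
  states <- as.character(states)
  if (kind == "steps") {
    lo <- c(sedentary = 0, medium = 5000, active = 10001)
    hi <- c(sedentary = 4999, medium = 10000, active = 20000)
    unknown <- setdiff(states, names(lo))
    if (length(unknown)) stop("unknown state '", unknown[1], "'", call. = FALSE)
    lo <- lo[states]; hi <- hi[states]
    lo + floor(runif(length(states)) * (hi - lo + 1))
  } else {
    lo <- c(insufficient = 0.50, normal = 0.80, beneficial = 0.90)
    hi <- c(insufficient = 0.799, normal = 0.899, beneficial = 0.99)
    unknown <- setdiff(states, names(lo))
    if (length(unknown)) stop("unknown state '", unknown[1], "'", call. = FALSE)
    lo <- lo[states]; hi <- hi[states]
    round(lo + runif(length(states)) * (hi - lo), 4)
  }
}
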