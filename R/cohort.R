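#' Planted exposure-outcome risk parameters
#'
#' Controls the associations the synthetic generator plants so the
#' downstream analysis can recover them. `p_vuln_base` / `p_anx_base` are
#' the probabilities of ever reporting a positive VES-13 / PHQ-4 among
#' non-exposed patients; the `rr_*` parameters are the relative risks of
#' the exposed strata (long-sedentary activity for vulnerability,
#' insufficient-with-dynamism sleep for anxiety/depression, and the
#' prostate-metastatic cancer type for vulnerability). Joint effects
#' multiply on the probability scale and are hard-capped at 0.95 (with a
#' warning when the cap binds); a single exposure whose `p_base * RR`
#' reaches 1 is rejected outright.
#'
#' @param p_vuln_base probability in (0,1); default 0.11, the largest
#'   round value for which the strongest joint exposure
#'   (`p_vuln_base * rr_vuln_long_sedentary * rr_vuln_prostate_metastatic`)
#'   stays below the 0.95 cap, so every planted relative risk remains
#'   marginally identifiable.
#' @param rr_vuln_long_sedentary relative risk; default 2.58.
#' @param p_anx_base probability in (0,1); default 0.25.
#' @param rr_anx_dynamism relative risk; default 2.02.
#' @param rr_vuln_prostate_metastatic relative risk; default 3.28.
#' @return object of class `risk_params`.
#' @export
risk_params <- function(p_vuln_base = 0.11,
                        rr_vuln_long_sedentary = 2.58,
                        p_anx_base = 0.25,
                        rr_anx_dynamism = 2.02,
                        rr_vuln_prostate_metastatic = 3.28) {
  p <- list(p_vuln_base = p_vuln_base,
            rr_vuln_long_sedentary = rr_vuln_long_sedentary,
            p_anx_base = p_anx_base,
            rr_anx_dynamism = rr_anx_dynamism,
            rr_vuln_prostate_metastatic = rr_vuln_prostate_metastatic)
  for (nm in c("p_vuln_base", "p_anx_base")) {
    if (p[[nm]] <= 0 || p[[nm]] >= 1) {
      stop(nm, " must lie strictly in (0,1)", call. = FALSE)
    }
  }
  for (nm in c("rr_vuln_long_sedentary", "rr_anx_dynamism",
               "rr_vuln_prostate_metastatic")) {
    if (p[[nm]] <= 0) stop(nm, " must be positive", call. = FALSE)
  }
  if (p$p_vuln_base * p$rr_vuln_long_sedentary >= 1 ||
      p$p_vuln_base * p$rr_vuln_prostate_metastatic >= 1 ||
      p$p_anx_base * p$rr_anx_dynamism >= 1) {
    stop("an exposed outcome probability p_base * RR reaches 1; ",
         "reduce the baseline or the relative risk", call. = FALSE)
  }
  structure(p, class = "risk_params")
}

#' Synthetic cohort configuration
#'
#' Describes the cohort the generator emulates: 121 patients monitored
#' for about three months, a five-way activity archetype mixture in
#' proportions 42:25:24:19:11, a sleep mixture of three behaviour
#' archetypes plus idiosyncratic outliers in proportions 35:22:16:48,
#' three VES-13 and four PHQ-4 questionnaires per patient, and a cancer
#' mix dominated by curative breast and prostate disease with a melanoma
#' arm and small metastatic groups.
#'
#' @param n_patients number of patients; default 121.
#' @param n_days monitored days per patient; default 90.
#' @param activity_mixture named nonnegative weights over the five
#'   activity archetypes (normalised internally).
#' @param sleep_mixture named nonnegative weights over the three sleep
#'   archetypes plus `outlier`.
#' @param cancer_mix named nonnegative weights over the five cancer types.
#' @param n_ves,n_phq questionnaires per patient (>= 1); defaults 3 and 4.
#' @param risk_params a [risk_params()] object.
#' @param missing_day_prob probability that a day's observation of one
#'   activity stream is missing; default 0.05.
#' @param seed integer seed controlling all randomness of the cohort.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 121L,
                          n_days = 90L,
                          activity_mixture = c(medium_to_active = 42,
                                               medium_to_sedentary = 25,
                                               active = 24,
                                               long_sedentary = 19,
                                               sedentary = 11),
                          sleep_mixture = c(insufficient_with_dynamism = 35,
                                            insufficient = 22,
                                            balanced = 16,
                                            outlier = 48),
                          cancer_mix = c("breast-curative" = 54,
                                         "prostate-curative" = 36,
                                         "melanoma" = 21,
                                         "breast-metastatic" = 5,
                                         "prostate-metastatic" = 5),
                          n_ves = 3L, n_phq = 4L,
                          risk_params = dynrisk::risk_params(),
                          missing_day_prob = 0.05,
                          seed = 1L) {
  stopifnot(n_patients >= 1, n_days >= 2, n_ves >= 1, n_phq >= 1,
            missing_day_prob >= 0, missing_day_prob < 1)
  check_mix <- function(w, allowed, what) {
    if (is.null(names(w)) || !all(names(w) %in% allowed)) {
      stop(what, " must be named with names among: ",
           paste(allowed, collapse = ", "), call. = FALSE)
    }
    if (any(w < 0) || sum(w) <= 0) {
      stop(what, " weights must be nonnegative with a positive total",
           call. = FALSE)
    }
    w
  }
  activity_mixture <- check_mix(activity_mixture,
                                names(activity_archetypes()),
                                "activity_mixture")
  sleep_mixture <- check_mix(sleep_mixture, names(sleep_archetypes()),
                             "sleep_mixture")
  cancer_mix <- check_mix(cancer_mix,
                          c("melanoma", "prostate-curative",
                            "prostate-metastatic", "breast-curative",
                            "breast-metastatic"), "cancer_mix")
  stopifnot(inherits(risk_params, "risk_params"))
  structure(list(n_patients = as.integer(n_patients),
                 n_days = as.integer(n_days),
                 activity_mixture = activity_mixture,
                 sleep_mixture = sleep_mixture,
                 cancer_mix = cancer_mix,
                 n_ves = as.integer(n_ves), n_phq = as.integer(n_phq),
                 risk_params = risk_params,
                 missing_day_prob = missing_day_prob,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Sample questionnaire outcomes for one patient
#'
#' The probability of *ever* reporting a positive questionnaire is
#' `p_base` multiplied by the relative risk of each exposure the patient
#' carries (capped at 0.95). With `k` questionnaires, each is positive
#' independently with probability `q = 1 - (1 - p_any)^(1/k)`, so the
#' ever-positive probability is exactly `p_any`. Positive VES-13 totals
#' are drawn uniformly from 3-10 and negative ones from 0-2; positive
#' PHQ-4 totals from 3-12 and negative ones from 0-2.
#'
#' @param activity_archetype,sleep_archetype archetype names.
#' @param cancer_type one of the five cancer types.
#' @param params a [risk_params()].
#' @param n_ves,n_phq questionnaire counts.
#' @return list with integer vectors `ves_scores`, `phq_scores` and the
#'   logical `capped` (whether the 0.95 cap was hit).
#' @export
sample_outcomes <- function(activity_archetype, sleep_archetype, cancer_type,
                            params, n_ves = 3L, n_phq = 4L) {
  p_vuln <- params$p_vuln_base
  if (identical(activity_archetype, "long_sedentary")) {
    p_vuln <- p_vuln * params$rr_vuln_long_sedentary
  }
  if (identical(cancer_type, "prostate-metastatic")) {
    p_vuln <- p_vuln * params$rr_vuln_prostate_metastatic
  }
  capped <- p_vuln > 0.95
  p_vuln <- min(p_vuln, 0.95)
  p_anx <- params$p_anx_base
  if (identical(sleep_archetype, "insufficient_with_dynamism")) {
    p_anx <- p_anx * params$rr_anx_dynamism
  }
  capped <- capped || p_anx > 0.95
  p_anx <- min(p_anx, 0.95)

  draw <- function(p_any, k, pos_range, neg_range) {
    q <- 1 - (1 - p_any)^(1 / k)
    pos <- runif(k) < q
    lo <- ifelse(pos, pos_range[1], neg_range[1])
    hi <- ifelse(pos, pos_range[2], neg_range[2])
    as.integer(lo + floor(runif(k) * (hi - lo + 1)))
  }
  list(ves_scores = draw(p_vuln, n_ves, c(3L, 10L), c(0L, 2L)),
       phq_scores = draw(p_anx, n_phq, c(3L, 12L), c(0L, 2L)),
       capped = capped)
}

#' Generate a synthetic digital-phenotyping cohort
#'
#' Draws, for each patient, an activity and a sleep archetype from the
#' configured mixtures, simulates daily behaviour states under the
#' archetype Markov chains for `n_days`, maps states to numeric step
#' counts and sleep efficiencies, drops days independently with
#' probability `missing_day_prob` (per activity stream), and samples
#' questionnaire outcomes with the planted exposure-outcome associations
#' of [risk_params()]. Demographics follow the study population the
#' generator emulates: ages normal(71.63, 5.93) truncated to 65-95,
#' melanoma patients recruited in Sweden and breast/prostate patients in
#' Greece, Spain or Scotland, with per-country sex ratios.
#'
#' The whole cohort is a deterministic function of the configuration,
#' including its `seed`.
#'
#' @param config a [cohort_config()].
#' @return list with elements `log` (an [event_log()] of `daily_steps`
#'   and `sleep_efficiency` events), `patients` (data frame of patient
#'   attributes with list columns `ves_scores`, `phq_scores`) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  n_days <- config$n_days
  ids <- sprintf("P%0*d", max(3L, nchar(n)), seq_len(n))
  acts <- activity_archetypes()
  slps <- sleep_archetypes()

  act_names <- names(config$activity_mixture)
  slp_names <- names(config$sleep_mixture)
  act_assign <- act_names[sample.int(length(act_names), n, replace = TRUE,
                                     prob = config$activity_mixture)]
  slp_assign <- slp_names[sample.int(length(slp_names), n, replace = TRUE,
                                     prob = config$sleep_mixture)]
  cancer_names <- names(config$cancer_mix)
  cancer <- cancer_names[sample.int(length(cancer_names), n, replace = TRUE,
                                    prob = config$cancer_mix)]

  # Demographics of the emulated study population.
  age <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      a <- rnorm(1, 71.63, 5.93)
      if (a >= 65 && a <= 95) break
    }
    age[i] <- round(a, 1)
  }
  country <- ifelse(cancer == "melanoma", "Sweden",
                    sample(c("Greece", "Spain", "Scotland"), n,
                           replace = TRUE, prob = c(30, 50, 20)))
  p_women <- c(Greece = 20 / 30, Spain = 27 / 50, Sweden = 5 / 21,
               Scotland = 6 / 20)
  sex <- ifelse(runif(n) < p_women[country], "F", "M")

  dates <- as.Date("2023-02-01") + seq_len(n_days) - 1L
  logs_case <- vector("list", 2L * n)
  logs_act <- vector("list", 2L * n)
  logs_val <- vector("list", 2L * n)
  logs_date <- vector("list", 2L * n)
  ves <- vector("list", n)
  phq <- vector("list", n)
  n_capped <- 0L

  for (i in seq_len(n)) {
    a_states <- sample_daily_states(acts[[act_assign[i]]], n_days)
    s_arch <- if (slp_assign[i] == "outlier") {
      random_outlier_archetype()
    } else {
      slps[[slp_assign[i]]]
    }
    s_states <- sample_daily_states(s_arch, n_days)
    steps <- states_to_values(a_states, "steps")
    sleep <- states_to_values(s_states, "sleep")
    keep_a <- runif(n_days) >= config$missing_day_prob
    keep_s <- runif(n_days) >= config$missing_day_prob
    j <- 2L * i - 1L
    logs_case[[j]] <- rep(ids[i], sum(keep_a))
    logs_act[[j]] <- rep("daily_steps", sum(keep_a))
    logs_val[[j]] <- steps[keep_a]
    logs_date[[j]] <- dates[keep_a]
    logs_case[[j + 1L]] <- rep(ids[i], sum(keep_s))
    logs_act[[j + 1L]] <- rep("sleep_efficiency", sum(keep_s))
    logs_val[[j + 1L]] <- sleep[keep_s]
    logs_date[[j + 1L]] <- dates[keep_s]

    out <- sample_outcomes(act_assign[i], slp_assign[i], cancer[i],
                           config$risk_params, config$n_ves, config$n_phq)
    ves[[i]] <- out$ves_scores
    phq[[i]] <- out$phq_scores
    n_capped <- n_capped + as.integer(out$capped)
  }
  if (n_capped > 0L) {
    warning(n_capped, " patient(s) hit the 0.95 joint-probability cap",
            call. = FALSE)
  }

  log <- event_log(data.frame(
    case_id = unlist(logs_case),
    activity = unlist(logs_act),
    value = unlist(logs_val),
    timestamp = as.Date(unlist(lapply(logs_date, as.character))),
    stringsAsFactors = FALSE
  ))
  patients <- data.frame(case_id = ids, age = age, sex = sex,
                         country = country, cancer_type = cancer,
                         activity_archetype = act_assign,
                         sleep_archetype = slp_assign,
                         stringsAsFactors = FALSE)
  patients$ves_scores <- ves
  patients$phq_scores <- phq
  list(log = log, patients = patients, config = config)
}
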