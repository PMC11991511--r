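test_that("cohort generation is a deterministic function of the config", {
  cfg <- cohort_config(n_patients = 25, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$log, b$log)
  expect_identical(a$patients, b$patients)
  c <- generate_cohort(cohort_config(n_patients = 25, seed = 12))
  expect_false(identical(a$log, c$log))
})

test_that("archetype mixture shares converge to the configured weights", {
  # large cohort, minimal days: only the assignment frequencies matter
  co <- generate_cohort(cohort_config(n_patients = 121000, n_days = 2,
                                      missing_day_prob = 0, seed = 4))
  shares <- table(co$patients$activity_archetype) / 121000
  expected <- c(medium_to_active = 42, medium_to_sedentary = 25,
                active = 24, long_sedentary = 19, sedentary = 11) / 121
  expect_true(all(abs(shares[names(expected)] - expected) < 0.01))
  slp <- table(co$patients$sleep_archetype) / 121000
  exp_slp <- c(insufficient_with_dynamism = 35, insufficient = 22,
               balanced = 16, outlier = 48) / 121
  expect_true(all(abs(slp[names(exp_slp)] - exp_slp) < 0.01))
})

test_that("missing-day handling and trace lengths behave as configured", {
  co <- generate_cohort(cohort_config(n_patients = 8, n_days = 30,
                                      missing_day_prob = 0, seed = 2))
  steps <- co$log[co$log$activity == "daily_steps", ]
  expect_equal(unname(table(steps$case_id)),
               as.array(rep(30L, 8)), ignore_attr = TRUE)
  co2 <- generate_cohort(cohort_config(n_patients = 60, n_days = 30,
                                       missing_day_prob = 0.2, seed = 2))
  steps2 <- co2$log[co2$log$activity == "daily_steps", ]
  expect_lt(nrow(steps2), 60 * 30)
  expect_gt(nrow(steps2), 60 * 30 * 0.7)
})

test_that("daily state sampling follows the chain", {
  ident <- archetype("stay", c("sedentary", "medium", "active"),
                     initial_dist = c(1, 0, 0), transition = diag(3))
  expect_equal(sample_daily_states(ident, 20), rep("sedentary", 20))
  one <- sample_daily_states(activity_archetypes()$active, 1)
  expect_length(one, 1)
  expect_true(one %in% c("sedentary", "medium", "active"))
})

test_that("long-sedentary chain has stationary sedentary occupancy > 0.8", {
  set.seed(1)
  s <- sample_daily_states(activity_archetypes()$long_sedentary, 1e5)
  expect_gt(mean(s == "sedentary"), 0.8)
})

test_that("every archetype's occupancy matches its intended profile", {
  set.seed(2)
  occ <- function(arch, state) {
    mean(sample_daily_states(arch, 2e4) == state)
  }
  acts <- activity_archetypes()
  expect_gt(occ(acts$active, "active"), 0.8)
  expect_gt(occ(acts$medium_to_active, "active"), 0.35)
  expect_gt(occ(acts$medium_to_sedentary, "medium"), 0.6)
  expect_gt(occ(acts$sedentary, "sedentary"), 0.4)
  slps <- sleep_archetypes()
  expect_gt(occ(slps$insufficient, "insufficient"), 0.85)
  dyn <- sample_daily_states(slps$insufficient_with_dynamism, 2e4)
  expect_gt(mean(dyn == "insufficient"), mean(dyn == "normal"))
  expect_gt(mean(dyn[-1] != dyn[-length(dyn)]), 0.5)  # alternation
  expect_lt(occ(slps$balanced, "insufficient"), 0.15)
})

test_that("state-to-value mapping inverts the discretizers", {
  set.seed(3)
  acts <- c("sedentary", "medium", "active")
  slps <- c("insufficient", "normal", "beneficial")
  for (i in 1:200) {
    s <- sample(acts, sample(1:30, 1), replace = TRUE)
    v <- states_to_values(s, "steps")
    expect_identical(as.character(discretize_steps(v)), s)
    s2 <- sample(slps, sample(1:30, 1), replace = TRUE)
    v2 <- states_to_values(s2, "sleep")
    expect_identical(as.character(discretize_sleep(v2)), s2)
  }
  expect_lt(states_to_values("sedentary", "steps"), 5000)
  expect_gte(states_to_values("beneficial", "sleep"), 0.90)
  expect_error(states_to_values("brisk", "steps"), "unknown state")
})

test_that("outcome sampling plants the configured ever-positive rates", {
  params <- risk_params()
  set.seed(7)
  n <- 2e4
  pos <- logical(n)
  for (i in 1:n) {
    out <- sample_outcomes("long_sedentary", "balanced", "melanoma",
                           params, n_ves = 3, n_phq = 4)
    pos[i] <- any(out$ves_scores >= 3)
  }
  p_any <- params$p_vuln_base * params$rr_vuln_long_sedentary
  # per-questionnaire q = 1 - (1 - p_any)^(1/3) makes P(any positive) = p_any
  expect_lt(abs(mean(pos) - p_any), 3 * sqrt(p_any * (1 - p_any) / n))

  low <- risk_params(p_vuln_base = 1e-6, p_anx_base = 1e-6)
  for (i in 1:50) {
    out <- sample_outcomes("active", "balanced", "melanoma", low)
    expect_true(all(out$ves_scores <= 2) && all(out$phq_scores <= 2))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(risk_params(p_vuln_base = 0.5, rr_vuln_long_sedentary = 3),
               "reaches 1")
  expect_error(risk_params(p_vuln_base = 0), "strictly in")
  expect_error(cohort_config(activity_mixture = c(bogus = 1)),
               "names among")
  expect_error(cohort_config(sleep_mixture = c(balanced = -1,
                                               outlier = 2)),
               "nonnegative")
  expect_error(cohort_config(n_days = 1), "n_days")
})

test_that("demographics match the emulated population", {
  co <- generate_cohort(cohort_config(n_patients = 400, seed = 9))
  expect_true(all(co$patients$age >= 65 & co$patients$age <= 95))
  # normal(71.63, 5.93) truncated to [65, 95] has mean ~73.1
  expect_lt(abs(mean(co$patients$age) - 73.1), 1)
  expect_true(all(co$patients$country[
    co$patients$cancer_type == "melanoma"] == "Sweden"))
})
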