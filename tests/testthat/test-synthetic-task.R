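test_that("reward schedules are blockwise exact and deterministic", {
  expect_true(all(make_reward_schedule(schedule_config(1, 60, seed = 1L))))

  sch <- make_reward_schedule(schedule_config(0.5, 100, seed = 2L))
  blocks <- matrix(sch, nrow = 20L)
  expect_equal(colSums(blocks), rep(10, 5), ignore_attr = TRUE)

  sch2 <- make_reward_schedule(schedule_config(0.2, 100, seed = 3L))
  expect_equal(mean(sch2), 0.2)
  expect_equal(colSums(matrix(sch2, nrow = 20L)), rep(4, 5),
               ignore_attr = TRUE)

  expect_identical(make_reward_schedule(schedule_config(0.5, 100, seed = 9L)),
                   make_reward_schedule(schedule_config(0.5, 100, seed = 9L)))
})

test_that("policy constructors validate probability vectors", {
  expect_error(behavior_policy("independence",
                               action_probs = c(0.5, 0.5, 0.2, -0.2)),
               "probability vector")
  expect_error(behavior_policy("first_order",
                               conditional_probs = matrix(0.25, 4, 4)),
               "5 x 4")
  pol <- behavior_policy("independence",
                         action_probs = c(0.25, 0.25, 0.25, 0.25))
  expect_equal(sum(pol$initial_action_probs), 1, tolerance = 1e-12)
})

test_that("the task layer maps actions through the schedule", {
  all_correct <- behavior_policy("independence",
                                 action_probs = c(1, 0, 0, 0))
  m1 <- session_meta("s", "crf", p_reward = 1, max_trials = 10L)
  s1 <- simulate_session(all_correct, m1, schedule_config(1, 10L, seed = 1L),
                         seed = 2L)
  expect_identical(s1$outcomes, rep("R", 10L))

  m2 <- session_meta("s", "prf", p_reward = 0.5, max_trials = 20L)
  s2 <- simulate_session(all_correct, m2,
                         schedule_config(0.5, 20L, seed = 1L), seed = 2L)
  expect_equal(sum(s2$outcomes == "R"), 10L)
  expect_equal(sum(s2$outcomes == "NR"), 10L)

  # reward-fraction conservation among correct outcomes, any p(R)
  for (p in c(0.2, 0.8)) {
    mp <- session_meta("s", paste0("p", p), p_reward = p, max_trials = 100L)
    sp <- simulate_session(all_correct, mp,
                           schedule_config(p, 100L, seed = 4L), seed = 5L)
    expect_equal(mean(sp$outcomes == "R"), round(20 * p) / 20)
  }

  expect_error(
    simulate_session(all_correct, m2, schedule_config(0.8, 20L, seed = 1L)),
    "disagree")
})

test_that("sessions are reproducible and writable byte-identically", {
  pol <- default_independence_policy()
  meta <- session_meta("s", "det", p_reward = 0.5, max_trials = 100L)
  a <- simulate_session(pol, meta, schedule_config(0.5, 100L, seed = 21L),
                        seed = 22L)
  b <- simulate_session(pol, meta, schedule_config(0.5, 100L, seed = 21L),
                        seed = 22L)
  expect_identical(a$outcomes, b$outcomes)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(list(a), fa)
  write_trial_log(list(b), fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("a perseverative first-order policy is recovered by estimation", {
  cp <- matrix(0, 5, 4, dimnames = list(OUTCOMES, ACTIONS))
  for (i in 1:5) cp[i, ] <- c(0.5, 0.15, 0.15, 0.2)
  cp["premature", ] <- c(0.1, 0.05, 0.05, 0.8)
  pol <- behavior_policy("first_order", conditional_probs = cp)
  meta <- session_meta("s", "persev", p_reward = 0.5, max_trials = 10000L)
  ses <- simulate_session(pol, meta,
                          schedule_config(0.5, 10000L, seed = 31L),
                          seed = 32L)
  est <- estimate_first_order(count_transitions(ses))
  expect_lt(abs(est$probs["premature", "premature"] - 0.8), 0.03)
})

test_that("frustration_policy hits its premature excess exactly", {
  pol <- frustration_policy(premature_excess = 0.25, p_reward = 0.5)
  q <- attr(pol, "premature_after_premature")
  Tm <- outcome_transition_matrix(pol, 0.5)
  expect_equal(rowSums(Tm), rep(1, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
  pi <- stationary_distribution(Tm)
  expect_equal(q - pi[["premature"]], 0.25, tolerance = 1e-7)
  expect_equal(pol$conditional_probs["premature", "premature"], q,
               ignore_attr = TRUE)
  # asymmetry mirrors the frustration structure
  expect_lt(Tm["R", "premature"], Tm["NR", "premature"])
})

test_that("cohorts are deterministic with controlled heterogeneity", {
  base <- default_independence_policy()
  metas <- lapply(c(0.2, 0.5, 0.8, 1), function(p)
    session_meta("template", paste0("p", p * 100), p_reward = p,
                 max_trials = 100L))
  coh <- simulate_cohort(24L, base, between_subject_sd = 0, metas = metas,
                         master_seed = 77L)
  expect_length(coh, 96L)
  keys <- vapply(coh, function(s)
    paste(s$meta$subject_id, s$meta$session_id), character(1L))
  expect_equal(anyDuplicated(keys), 0L)
  coh2 <- simulate_cohort(24L, base, between_subject_sd = 0, metas = metas,
                          master_seed = 77L)
  expect_identical(lapply(coh, `[[`, "outcomes"),
                   lapply(coh2, `[[`, "outcomes"))

  # sd = 0 leaves the policy untouched
  expect_identical(perturb_policy(base, 0), base)

  # heterogeneity inflates across-subject spread of premature counts
  one_meta <- metas[2L]
  prem_counts <- function(sd, seed)
    vapply(simulate_cohort(30L, base, sd, one_meta, master_seed = seed),
           function(s) sum(s$outcomes == "premature"), numeric(1L))
  v0 <- stats::var(prem_counts(0, 101L))
  v3 <- stats::var(prem_counts(0.6, 101L))
  expect_gt(v3, v0)
})
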