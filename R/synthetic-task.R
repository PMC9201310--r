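#' Behavioural actions available to a simulated animal
#'
#' The four actions a policy can emit on a trial. The task layer maps
#' `correct` to outcome `R` or `NR` according to the reinforcement
#' schedule; the other actions map to the like-named outcomes.
#' @format character vector of length 4.
#' @export
ACTIONS <- c("correct", "incorrect", "omission", "premature")

.check_prob_vector <- function(p, what, len) {
  if (length(p) != len || any(p < 0) || any(p > 1) ||
      abs(sum(p) - 1) > 1e-12)
    stop(what, " must be a length-", len,
         " probability vector summing to 1", call. = FALSE)
  invisible(p)
}

#' Behavioural policy for session simulation
#'
#' The generative stand-in for the animal. An `independence` policy draws
#' every action from one fixed distribution over [ACTIONS], producing
#' history-free (zeroth-order) outcome sequences up to the reinforcement
#' schedule. A `first_order` policy conditions the action distribution on
#' the previous trial's *outcome* (5 states, so rewarded and non-rewarded
#' correct trials can shape behaviour differently — the structure needed to
#' produce, e.g., elevated premature responding after reward omission).
#'
#' @param kind `"independence"` or `"first_order"`.
#' @param action_probs (independence) named probability vector over
#'   [ACTIONS].
#' @param conditional_probs (first_order) 5 x 4 matrix, rows = previous
#'   outcome in canonical [OUTCOMES] order, columns = [ACTIONS]; each row a
#'   probability vector.
#' @param initial_action_probs distribution for the first trial of a
#'   session; defaults to `action_probs` (independence) or the column means
#'   of `conditional_probs` (first_order).
#' @return an object of class `behavior_policy`.
#' @export
behavior_policy <- function(kind = c("independence", "first_order"),
                            action_probs = NULL, conditional_probs = NULL,
                            initial_action_probs = NULL) {
  kind <- match.arg(kind)
  if (kind == "independence") {
    if (is.null(action_probs))
      stop("independence policy requires action_probs", call. = FALSE)
    action_probs <- .check_prob_vector(as.numeric(action_probs),
                                       "action_probs", 4L)
    names(action_probs) <- ACTIONS
    if (is.null(initial_action_probs)) initial_action_probs <- action_probs
  } else {
    if (is.null(conditional_probs))
      stop("first_order policy requires conditional_probs", call. = FALSE)
    conditional_probs <- as.matrix(conditional_probs)
    if (!all(dim(conditional_probs) == c(N_STATES, 4L)))
      stop("conditional_probs must be a 5 x 4 matrix", call. = FALSE)
    for (i in seq_len(N_STATES))
      .check_prob_vector(conditional_probs[i, ],
                         paste0("conditional_probs row ", i), 4L)
    dimnames(conditional_probs) <- list(previous = OUTCOMES, action = ACTIONS)
    if (is.null(initial_action_probs))
      initial_action_probs <- colMeans(conditional_probs)
  }
  initial_action_probs <- .check_prob_vector(as.numeric(initial_action_probs),
                                             "initial_action_probs", 4L)
  names(initial_action_probs) <- ACTIONS
  structure(
    list(kind = kind, action_probs = action_probs,
         conditional_probs = conditional_probs,
         initial_action_probs = initial_action_probs),
    class = "behavior_policy")
}

#' Reinforcement schedule configuration
#'
#' Parameters of the blockwise pseudo-randomised partial-reinforcement
#' schedule: within every block of `block_size` trials exactly
#' `round(block_size * p_reward)` correct responses are rewarded, in
#' seeded-random order.
#'
#' @param p_reward reinforcement probability p(R) in (0, 1].
#' @param n_trials number of trials to schedule.
#' @param block_size block length over which the reward count is exact
#'   (default 20).
#' @param seed integer seed for the within-block shuffles; `NULL` uses the
#'   current RNG stream.
#' @return an object of class `schedule_config`.
#' @export
schedule_config <- function(p_reward, n_trials, block_size = 20L,
                            seed = NULL) {
  if (p_reward <= 0 || p_reward > 1)
    stop("p_reward must be in (0, 1]", call. = FALSE)
  n_trials <- as.integer(n_trials)
  block_size <- as.integer(block_size)
  stopifnot(n_trials >= 1L, block_size >= 1L)
  structure(
    list(p_reward = p_reward, n_trials = n_trials,
         block_size = block_size, seed = seed),
    class = "schedule_config")
}

.with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Build a blockwise pseudo-randomised reward schedule
#'
#' Returns a logical vector (length the smallest multiple of `block_size`
#' at or above `n_trials`) whose consecutive `block_size`-slot blocks each
#' contain exactly `round(block_size * p_reward)` `TRUE` slots in shuffled
#' order. Deterministic given `config$seed`.
#'
#' @param config a [schedule_config()].
#' @return logical vector of rewarded slots.
#' @export
#' @examples
#' sum(make_reward_schedule(schedule_config(0.5, 100, seed = 1)))  # 50
make_reward_schedule <- function(config) {
  stopifnot(inherits(config, "schedule_config"))
  n_blocks <- ceiling(config$n_trials / config$block_size)
  k <- as.integer(round(config$block_size * config$p_reward))
  .with_optional_seed(config$seed, {
    unlist(lapply(seq_len(n_blocks), function(b) {
      block <- c(rep(TRUE, k), rep(FALSE, config$block_size - k))
      if (config$block_size > 1L) block[sample.int(config$block_size)]
      else block
    }), use.names = FALSE)
  })
}

.draw_action <- function(prob) ACTIONS[sample.int(4L, 1L, prob = prob)]

#' Simulate one 5CSRTT session
#'
#' Draws a trial-outcome sequence from a behavioural policy under the task's
#' reward contingency: each `correct` action consumes the next slot of the
#' blockwise reward schedule and becomes `R` if that slot is rewarded, `NR`
#' otherwise (so the planned R:NR ratio holds exactly among correct
#' responses); `incorrect`, `omission` and `premature` actions map directly
#' to their outcomes. Session length is `min(schedule$n_trials,
#' meta$max_trials)`. Fully reproducible given `seed` and `schedule$seed`.
#'
#' @param policy a [behavior_policy()].
#' @param meta a [session_meta()]; `meta$p_reward` must equal
#'   `schedule$p_reward`.
#' @param schedule a [schedule_config()].
#' @param seed integer seed for the action draws; `NULL` uses the current
#'   RNG stream.
#' @param latency_model optional `list(meanlog, sdlog)`: correct-response
#'   latencies (ms) are drawn log-normally for R/NR trials and left `NA`
#'   elsewhere. A coarse device for exercising macro-level correlation
#'   plumbing, with no claim of behavioural realism.
#' @return a [csrtt_session()].
#' @export
simulate_session <- function(policy, meta, schedule, seed = NULL,
                             latency_model = NULL) {
  stopifnot(inherits(policy, "behavior_policy"),
            inherits(meta, "session_meta"),
            inherits(schedule, "schedule_config"))
  if (abs(meta$p_reward - schedule$p_reward) > 1e-12)
    stop("meta$p_reward and schedule$p_reward disagree", call. = FALSE)
  n <- min(schedule$n_trials, meta$max_trials)
  rewards <- make_reward_schedule(schedule)
  actions <- .with_optional_seed(seed, {
    if (policy$kind == "independence") {
      ACTIONS[sample.int(4L, n, replace = TRUE, prob = policy$action_probs)]
    } else {
      acts <- character(n)
      acts[1L] <- .draw_action(policy$initial_action_probs)
      prev_outcome <- NA_character_
      slot <- 0L
      for (t in seq_len(n)) {
        if (t > 1L)
          acts[t] <- .draw_action(policy$conditional_probs[prev_outcome, ])
        if (acts[t] == "correct") {
          slot <- slot + 1L
          prev_outcome <- if (rewards[slot]) "R" else "NR"
        } else prev_outcome <- acts[t]
      }
      acts
    }
  })
  is_correct <- actions == "correct"
  outcomes <- actions
  outcomes[is_correct] <- ifelse(rewards[cumsum(is_correct)[is_correct]],
                                 "R", "NR")
  lat <- NULL
  if (!is.null(latency_model)) {
    lat <- rep(NA_real_, n)
    idx <- outcomes %in% c("R", "NR")
    lat[idx] <- .with_optional_seed(
      if (is.null(seed)) NULL else as.integer(seed) + 1L,
      stats::rlnorm(sum(idx), latency_model$meanlog, latency_model$sdlog))
  }
  csrtt_session(meta, outcomes, lat)
}

#' Perturb a policy on the log-odds scale
#'
#' Adds independent Gaussian noise of scale `sd` to the log-probabilities of
#' every action distribution in the policy and renormalises, yielding a
#' valid policy that differs smoothly from the base. Used to create
#' between-subject variation in [simulate_cohort()].
#'
#' @param policy a [behavior_policy()].
#' @param sd nonnegative noise scale on the log scale; 0 returns the policy
#'   unchanged.
#' @return a [behavior_policy()].
#' @export
perturb_policy <- function(policy, sd) {
  stopifnot(inherits(policy, "behavior_policy"), sd >= 0)
  if (sd == 0) return(policy)
  jitter_vec <- function(p) {
    # floor keeps log() finite for structurally zero actions
    lp <- log(pmax(p, 1e-12)) + stats::rnorm(length(p), sd = sd)
    q <- exp(lp - max(lp))
    q / sum(q)
  }
  if (policy$kind == "independence") {
    behavior_policy("independence",
                    action_probs = jitter_vec(policy$action_probs),
                    initial_action_probs =
                      jitter_vec(policy$initial_action_probs))
  } else {
    cp <- t(apply(policy$conditional_probs, 1L, jitter_vec))
    behavior_policy("first_order", conditional_probs = cp,
                    initial_action_probs =
                      jitter_vec(policy$initial_action_probs))
  }
}

#' Simulate a cohort across conditions
#'
#' Generates one session per subject per condition. Each subject's policy is
#' the base policy perturbed on the log-odds scale with
#' `between_subject_sd` ([perturb_policy()]); condition metadata templates
#' supply p(R), ITI, time-out and the trial cap. All randomness (subject
#' policies, reward schedules, action draws) derives deterministically from
#' `master_seed`.
#'
#' @param n_subjects number of subjects (the studies this emulates used
#'   cohorts of 24 and 36).
#' @param base_policy a [behavior_policy()].
#' @param between_subject_sd log-odds-scale policy variability across
#'   subjects (0 = identical subjects).
#' @param metas list of [session_meta()] condition templates; `subject_id`
#'   is replaced per subject and `session_id` is suffixed per condition.
#' @param master_seed integer master seed.
#' @param block_size reward-schedule block length (default 20).
#' @param latency_model optional latency model passed to
#'   [simulate_session()]; may carry an extra `premature_coupling`
#'   component, a slope applied to each subject's premature-action
#'   propensity (centred on the base policy's) and added to `meanlog`, so
#'   that more impulsive subjects respond faster (negative slope) or slower
#'   (positive slope) on correct trials.
#' @return a list of [csrtt_session()] objects, one per subject x condition.
#' @export
simulate_cohort <- function(n_subjects, base_policy, between_subject_sd = 0,
                            metas, master_seed, block_size = 20L,
                            latency_model = NULL) {
  stopifnot(n_subjects >= 1L, inherits(base_policy, "behavior_policy"),
            length(metas) >= 1L,
            all(vapply(metas, inherits, logical(1L), "session_meta")))
  n_runs <- n_subjects * length(metas)
  seeds <- withr::with_seed(as.integer(master_seed), {
    list(policy = sample.int(.Machine$integer.max, n_subjects),
         schedule = sample.int(.Machine$integer.max, n_runs),
         action = sample.int(.Machine$integer.max, n_runs))
  })
  premature_propensity <- function(p) {
    if (p$kind == "independence") unname(p$action_probs["premature"])
    else mean(p$conditional_probs[, "premature"])
  }
  base_prem <- premature_propensity(base_policy)
  sessions <- vector("list", n_runs)
  run <- 0L
  for (s in seq_len(n_subjects)) {
    pol <- withr::with_seed(seeds$policy[s],
                            perturb_policy(base_policy, between_subject_sd))
    lat_model <- latency_model
    if (!is.null(lat_model) && !is.null(lat_model$premature_coupling))
      lat_model$meanlog <- lat_model$meanlog +
        lat_model$premature_coupling *
        (premature_propensity(pol) - base_prem)
    for (m in seq_along(metas)) {
      run <- run + 1L
      tmpl <- metas[[m]]
      meta <- session_meta(
        subject_id = sprintf("s%02d", s),
        session_id = sprintf("%s_s%02d", tmpl$session_id, s),
        p_reward = tmpl$p_reward, iti_s = tmpl$iti_s,
        timeout_s = tmpl$timeout_s, max_trials = tmpl$max_trials,
        cohort = tmpl$cohort)
      sched <- schedule_config(tmpl$p_reward, tmpl$max_trials,
                               block_size = block_size,
                               seed = seeds$schedule[run])
      sessions[[run]] <- simulate_session(pol, meta, sched,
                                          seed = seeds$action[run],
                                          latency_model = lat_model)
    }
  }
  sessions
}
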