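#' Default history-free baseline policy
#'
#' An independence policy representing a well-trained animal at stable
#' baseline under challenge conditions: correct action 0.55, incorrect
#' 0.12, omission 0.13, premature 0.20. The mix keeps choice accuracy
#' (correct / (correct + incorrect) = 82%) above the 80% stable-baseline
#' criterion and omissions below 20%, while leaving every outcome frequent
#' enough at session scale (rarest marginal 12%) that expected transition
#' counts stay in the range where the chi-squared reference for W is
#' usable.
#'
#' @return a [behavior_policy()].
#' @export
default_independence_policy <- function() {
  behavior_policy("independence",
                  action_probs = c(correct = 0.55, incorrect = 0.12,
                                   omission = 0.13, premature = 0.20))
}

#' Outcome-level transition matrix implied by a policy
#'
#' Converts a behavioural policy plus the reinforcement probability into
#' the 5 x 5 transition matrix over trial outcomes: the `correct` action
#' splits into `R` with probability `p_reward` and `NR` otherwise (the
#' idealised, non-blockwise limit of the schedule), and the other actions
#' map to their like-named outcomes. For an independence policy every row
#' is identical.
#'
#' @param policy a [behavior_policy()].
#' @param p_reward reinforcement probability.
#' @return 5 x 5 matrix, rows = previous outcome, columns = next outcome,
#'   canonical [OUTCOMES] order.
#' @export
outcome_transition_matrix <- function(policy, p_reward) {
  stopifnot(inherits(policy, "behavior_policy"))
  action_rows <- if (policy$kind == "independence")
    matrix(rep(policy$action_probs, each = N_STATES), N_STATES, 4L,
           dimnames = list(OUTCOMES, ACTIONS))
  else policy$conditional_probs
  T <- cbind(R = action_rows[, "correct"] * p_reward,
             NR = action_rows[, "correct"] * (1 - p_reward),
             premature = action_rows[, "premature"],
             incorrect = action_rows[, "incorrect"],
             omission = action_rows[, "omission"])
  rownames(T) <- OUTCOMES
  T
}

#' Stationary distribution of an outcome chain
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalised
#' to a probability vector.
#'
#' @param transition 5 x 5 row-stochastic matrix.
#' @return length-5 probability vector in canonical order.
#' @export
stationary_distribution <- function(transition) {
  stopifnot(is.matrix(transition),
            all(abs(rowSums(transition) - 1) < 1e-9))
  e <- eigen(t(transition))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  stats::setNames(v / sum(v), rownames(transition))
}

#' First-order policy with a calibrated premature-to-premature excess
#'
#' Builds a first-order policy with the qualitative structure reported for
#' partial-reinforcement sessions: premature responding is suppressed after
#' a rewarded trial, elevated after reward omission, and strongly
#' perseverative after a premature response. The premature-action
#' probability after a premature outcome is solved numerically so that it
#' exceeds the chain's stationary marginal premature probability by exactly
#' `premature_excess`; the remaining probability mass in every row is split
#' correct : incorrect : omission = 0.75 : 0.125 : 0.125.
#'
#' @param premature_excess target excess of P(premature | premature) over
#'   the stationary marginal P(premature) (default 0.25).
#' @param p_reward reinforcement probability used for the stationary
#'   calculation (default 0.5, the schedule the deviation analyses focus
#'   on).
#' @param premature_after premature-action probability after `R`, `NR`,
#'   `incorrect` and `omission` outcomes.
#' @return a [behavior_policy()]; the solved premature-after-premature
#'   probability is attached as attribute `"premature_after_premature"`.
#' @export
frustration_policy <- function(premature_excess = 0.25, p_reward = 0.5,
                               premature_after = c(R = 0.10, NR = 0.30,
                                                   incorrect = 0.20,
                                                   omission = 0.20)) {
  build <- function(q) {
    prem <- c(R = premature_after[["R"]], NR = premature_after[["NR"]],
              premature = q,
              incorrect = premature_after[["incorrect"]],
              omission = premature_after[["omission"]])
    rest <- 1 - prem
    cp <- cbind(correct = 0.75 * rest, incorrect = 0.125 * rest,
                omission = 0.125 * rest, premature = prem)
    rownames(cp) <- OUTCOMES
    behavior_policy("first_order", conditional_probs = cp)
  }
  excess_at <- function(q) {
    pi <- stationary_distribution(
      outcome_transition_matrix(build(q), p_reward))
    q - pi[["premature"]] - premature_excess
  }
  # the excess is unimodal in q; search below its maximum
  q <- stats::uniroot(excess_at, c(min(premature_after), 0.75),
                      tol = 1e-10)$root
  pol <- build(q)
  attr(pol, "premature_after_premature") <- q
  pol
}
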