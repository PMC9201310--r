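# Shared builders and independent oracles.

make_session <- function(outcomes, p_reward = 0.5, subject = "r1",
                         session = "s1", max_trials = NULL, ...) {
  meta <- session_meta(subject, session, p_reward = p_reward,
                       max_trials = max_trials %||%
                         max(100L, length(outcomes)), ...)
  csrtt_session(meta, outcomes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent transition-count oracle: base table() on lagged factor pairs.
oracle_counts <- function(outcomes) {
  f <- factor(outcomes, levels = OUTCOMES)
  n <- length(f)
  if (n < 2L)
    return(matrix(0L, 5, 5, dimnames = list(OUTCOMES, OUTCOMES)))
  matrix(as.integer(table(f[-n], f[-1L])), 5L, 5L,
         dimnames = list(OUTCOMES, OUTCOMES))
}

# Independent G / chi-squared / Y oracles: explicit double loops.
oracle_G <- function(O, E) {
  acc <- 0
  for (i in 1:5) for (j in 1:5)
    if (O[i, j] > 0) acc <- acc + 2 * O[i, j] * log(O[i, j] / E[i, j])
  acc
}

oracle_chi2_col <- function(O, E, col) {
  acc <- 0
  for (i in 1:5)
    if (E[i, col] > 0) acc <- acc + (O[i, col] - E[i, col])^2 / E[i, col]
  acc
}

oracle_Y_col <- function(O, E, col) {
  y <- rep(NA_real_, 5)
  for (i in 1:5)
    if (E[i, col] > 0) y[i] <- (O[i, col] - E[i, col]) / sqrt(E[i, col])
  y
}

# Expected frequencies under independence, end margin, from first
# principles (product formula on the raw table).
oracle_expected <- function(O) {
  E <- matrix(0, 5, 5, dimnames = dimnames(O))
  n <- sum(O)
  for (i in 1:5) for (j in 1:5)
    E[i, j] <- sum(O[i, ]) * sum(O[, j]) / n
  E
}

random_outcomes <- function(n, prob = NULL) {
  sample(OUTCOMES, n, replace = TRUE, prob = prob)
}
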