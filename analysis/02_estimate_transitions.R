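#!/usr/bin/env Rscript
# Pool the simulated experiment-1 sessions per reinforcement condition and
# estimate the first-order transition structure next to the independence
# model: observed frequency matrices, row-normalised transition
# probabilities, and expected frequencies under independence.
suppressMessages(library(markov5csrtt))

sessions <- read_trial_log("results/exp1_sessions.csv")
by_p <- split(sessions,
              vapply(sessions, function(s) format(s$meta$p_reward),
                     character(1L)))

for (p in names(by_p)) {
  cnt <- count_transitions(by_p[[p]])
  fo <- estimate_first_order(cnt)
  fit <- estimate_zeroth_order(cnt)
  stub <- file.path("results", sprintf("exp1_pR%s", gsub("\\.", "", p)))
  write_matrix_csv(cnt, paste0(stub, "_counts.csv"))
  write_matrix_csv(fo, paste0(stub, "_probs.csv"))
  write_matrix_csv(fit, paste0(stub, "_expected.csv"))
  cat(sprintf(
    "p(R) = %-4s %4d sessions, %5d transitions; P(prem|prem) = %.3f vs marginal %.3f\n",
    p, cnt$n_sessions, cnt$n_transitions,
    fo$probs["premature", "premature"], fit$state_probs[["premature"]]))
}
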