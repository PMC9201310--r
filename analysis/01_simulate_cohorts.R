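#!/usr/bin/env Rscript
# Simulate the synthetic cohorts every downstream analysis runs on:
#   - exp1: 24 subjects x p(R) in {0.2, 0.5, 0.8, 1} (ITI 5 s, TO 5 s,
#     100-trial sessions), behaviour from the first-order "frustration"
#     policy with between-subject heterogeneity — the partial-reinforcement
#     design whose trial-by-trial dependencies the Markov analysis probes.
#   - null: the same cohort driven by the history-free baseline policy,
#     the negative control for the diagnostics.
#   - screen: 36 subjects x three 200-trial challenge sessions with
#     latencies, input for the impulsivity screen.
suppressMessages(library(markov5csrtt))

dir.create("results", showWarnings = FALSE)
seed <- 20260920L

conds <- lapply(c(0.2, 0.5, 0.8, 1), function(p)
  session_meta("template", sprintf("pR%02d", round(p * 10)), p_reward = p,
               iti_s = 5, timeout_s = 5, max_trials = 100L))

exp1 <- simulate_cohort(24L, frustration_policy(), between_subject_sd = 0.3,
                        metas = conds, master_seed = seed)
write_trial_log(exp1, "results/exp1_sessions.csv")

null <- simulate_cohort(24L, default_independence_policy(),
                        between_subject_sd = 0.3, metas = conds,
                        master_seed = seed + 1L)
write_trial_log(null, "results/null_sessions.csv")

screen_metas <- lapply(1:3, function(k)
  session_meta("template", sprintf("vITI%d", k), p_reward = 1,
               iti_s = 7, timeout_s = 5, max_trials = 200L))
screen <- simulate_cohort(36L, default_independence_policy(),
                          between_subject_sd = 0.5, metas = screen_metas,
                          master_seed = seed + 2L,
                          latency_model = list(meanlog = 6.2, sdlog = 0.15,
                                               premature_coupling = -2))
write_trial_log(screen, "results/screen_sessions.csv")

cat(sprintf("wrote %d exp1, %d null and %d screening sessions (%d trials)\n",
            length(exp1), length(null), length(screen),
            sum(vapply(c(exp1, null, screen), length, integer(1L)))))
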