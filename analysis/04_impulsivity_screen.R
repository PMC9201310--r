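#!/usr/bin/env Rscript
# Macro-level screening analysis on the simulated challenge sessions:
# per-session outcome summaries, the quartile-based HI/MID/LI impulsivity
# screen on mean premature counts, and the premature-vs-latency
# correlation the latency coupling in the generator is designed to show.
suppressMessages(library(markov5csrtt))

sessions <- read_trial_log("results/screen_sessions.csv")
summaries <- summarize_sessions(sessions)
utils::write.csv(summaries, "results/screen_summaries.csv",
                 row.names = FALSE)

screen <- screen_impulsivity(sessions)
utils::write.csv(screen, "results/impulsivity_screen.csv",
                 row.names = FALSE)
cat("impulsivity screen over", nrow(screen), "subjects:\n")
print(table(screen$label))
cat(sprintf("HI mean premature >= %.1f; LI <= %.1f\n",
            min(screen$mean_premature[screen$label == "HI"]),
            max(screen$mean_premature[screen$label == "LI"])))

corr <- premature_latency_correlation(summaries)
cat(sprintf(
  "premature vs correct-latency: r = %.3f (p = %.2g, n = %d sessions)\n",
  corr$r, corr$p, corr$n))
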