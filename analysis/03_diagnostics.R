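#!/usr/bin/env Rscript
# Run the full diagnostic battery per reinforcement condition, for both the
# first-order cohort and the history-free control: W against the 16-dof
# critical value 26.30, the restricted chi-squared on transitions into
# premature against 11.07 (5 dof), the Y = (O - E)/sqrt(E) deviation
# profile, and the split-half homogeneity summary. Everything is written by
# run_pipeline() as CSV/JSON under results/.
suppressMessages(library(markov5csrtt))

for (cohort in c("exp1", "null")) {
  cat("==", cohort, "cohort ==\n")
  res <- run_pipeline(list(input = sprintf("results/%s_sessions.csv", cohort),
                           out_dir = file.path("results", cohort)))
  for (cond in names(res)) {
    r <- res[[cond]]
    cat(sprintf(
      "condition %-10s W = %7.2f (%s)  chi2->prem = %6.2f  Y(prem|prem) = %5.2f  Y(prem|NR) = %5.2f  Y(prem|R) = %5.2f\n",
      cond, r$w$statistic,
      if (r$w$reject) "reject independence" else "keep independence",
      if (is.null(r$chi2_target)) NA else r$chi2_target$statistic,
      r$y_profile$y[["premature"]], r$y_profile$y[["NR"]],
      r$y_profile$y[["R"]]))
  }
}
cat("\nExpect: every exp1 condition rejects with the Y profile peaking at\n")
cat("premature->premature and suppressed R->premature. The null cohort\n")
cat("mostly keeps independence; occasional rejections are real signal,\n")
cat("not error — pooling subjects whose policies differ (and the exact\n")
cat("blockwise schedule) departs slightly from one homogeneous\n")
cat("zeroth-order chain.\n")
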