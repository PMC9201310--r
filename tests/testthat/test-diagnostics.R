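# A table whose observed frequencies already satisfy independence:
# outer-product margins (40, 20, 20, 10, 10) over 100 transitions.
independent_table <- function() {
  m <- outer(c(40, 20, 20, 10, 10), c(40, 20, 20, 10, 10)) / 100
  storage.mode(m) <- "integer"
  as_transition_counts(m)
}

test_that("chi-squared critical values match the fixed decision rules", {
  expect_equal(round(chi2_critical(0.05, 16), 2), 26.30)
  expect_equal(round(chi2_critical(0.05, 5), 2), 11.07)
  expect_gt(chi2_critical(0.05, 17), chi2_critical(0.05, 16))
  expect_error(chi2_critical(0, 5), "alpha")
  expect_error(chi2_critical(0.05, 0), "dof")
})

test_that("W is zero on an independent table and matches the G oracle", {
  cnt <- independent_table()
  fit <- estimate_zeroth_order(cnt)
  w0 <- w_statistic(cnt, fit)
  expect_equal(w0$statistic, 0, tolerance = 1e-12)
  expect_false(w0$reject)
  expect_equal(w0$dof, 16L)

  # strongly history-dependent chain at n = 2000
  pol <- frustration_policy()
  meta <- session_meta("sim", "g", p_reward = 0.5, max_trials = 2000L)
  ses <- simulate_session(pol, meta, schedule_config(0.5, 2000L, seed = 3L),
                          seed = 4L)
  cnt <- count_transitions(ses)
  fit <- estimate_zeroth_order(cnt)
  w <- w_statistic(cnt, fit)
  expect_equal(w$statistic, oracle_G(cnt$counts, fit$expected),
               tolerance = 1e-9)
  expect_gt(w$statistic, 26.30)
  expect_true(w$reject)
  expect_lt(w$p_value, 0.001)
})

test_that("W rejects degenerate tables where O > 0 meets E = 0", {
  m <- matrix(0L, 5, 5)
  m[1, 2] <- 5L; m[2, 1] <- 5L; m[3, 3] <- 2L
  cnt <- as_transition_counts(m)
  fit <- estimate_zeroth_order(cnt)
  fit$expected[3, 3] <- 0  # forged degenerate fit
  expect_error(w_statistic(cnt, fit), "degenerate")
})

test_that("restricted chi-squared isolates transitions into the target", {
  cnt <- independent_table()
  fit <- estimate_zeroth_order(cnt)
  t0 <- chi2_into_state(cnt, fit, target = "premature")
  expect_equal(t0$statistic, 0, tolerance = 1e-12)
  expect_false(t0$reject)
  expect_equal(t0$dof, 5L)

  # +2 sqrt(E) on one start state, against the unperturbed fit: exactly 4
  m <- cnt$counts
  bump <- 2L * as.integer(sqrt(fit$expected["NR", "premature"]))
  expect_equal(bump^2, 4 * fit$expected["NR", "premature"],
               ignore_attr = TRUE) # perfect square by construction
  m["NR", "premature"] <- m["NR", "premature"] + bump
  perturbed <- as_transition_counts(m)
  t1 <- chi2_into_state(perturbed, fit, target = "premature")
  expect_equal(t1$statistic, 4, tolerance = 1e-12)
  expect_equal(t1$statistic,
               oracle_chi2_col(perturbed$counts, fit$expected, 3L),
               tolerance = 1e-12)

  zero <- matrix(0L, 5, 5); zero[1, 1] <- 3L; zero[1, 2] <- 3L
  zero[2, 1] <- 3L
  czero <- as_transition_counts(zero)
  expect_error(chi2_into_state(czero, estimate_zeroth_order(czero),
                               target = "omission"),
               "zero expected")
})

test_that("Y profile is the standardized residual into the target", {
  cnt <- independent_table()
  fit <- estimate_zeroth_order(cnt)
  expect_equal(unname(y_deviation(cnt, fit)$y), rep(0, 5),
               tolerance = 1e-12)

  # unit residual: O = E + sqrt(E) (E = 4 in this cell, a perfect square)
  m <- cnt$counts
  m["NR", "premature"] <- m["NR", "premature"] +
    as.integer(sqrt(fit$expected["NR", "premature"]))
  y <- y_deviation(as_transition_counts(m), fit)
  expect_equal(y$y[["NR"]], 1, tolerance = 1e-12)
  # sign convention follows O - E
  expect_identical(sign(y$y[y$defined]),
                   sign((y$observed - y$expected)[y$defined]))
})

test_that("Y is centred near zero under the independence policy", {
  pol <- default_independence_policy()
  meta <- session_meta("sim", "null", p_reward = 0.5, max_trials = 100L)
  ymat <- withr::with_seed(91L, vapply(1:500, function(i) {
    ses <- simulate_session(pol, meta, schedule_config(0.5, 100L))
    cnt <- count_transitions(ses)
    y_deviation(cnt, estimate_zeroth_order(cnt))$y
  }, numeric(5L)))
  means <- rowMeans(ymat, na.rm = TRUE)
  expect_true(all(means > -0.15 & means < 0.15))
})

test_that("W approximates Pearson chi-squared on well-filled tables", {
  pol <- frustration_policy()
  meta <- session_meta("sim", "big", p_reward = 0.5, max_trials = 5000L)
  ses <- simulate_session(pol, meta, schedule_config(0.5, 5000L, seed = 5L),
                          seed = 6L)
  cnt <- count_transitions(ses)
  fit <- estimate_zeroth_order(cnt)
  expect_true(all(fit$expected >= 5))
  pearson <- sum((cnt$counts - fit$expected)^2 / fit$expected)
  w <- w_statistic(cnt, fit)$statistic
  expect_lt(abs(w - pearson) / pearson, 0.05)
})

test_that("split-half report is symmetric on duplicated blocks", {
  block <- c("R", "NR", "premature", "R", "incorrect", "NR", "omission",
             "premature", "R", "NR")
  rep2 <- make_session(c(block, block))
  sh <- split_half_homogeneity(rep2)
  expect_equal(sh$max_abs_diff_into_target, 0, tolerance = 1e-12)
  expect_false(sh$degenerate)
  expect_equal(sh$first_half$counts$counts, sh$second_half$counts$counts)
})

test_that("split halves of a homogeneous chain agree", {
  pol <- frustration_policy()
  meta <- session_meta("sim", "hom", p_reward = 0.5, max_trials = 5000L)
  ses <- simulate_session(pol, meta, schedule_config(0.5, 5000L, seed = 13L),
                          seed = 14L)
  sh <- split_half_homogeneity(ses)
  expect_lt(sh$max_abs_diff_into_target, 0.1)
  expect_true(sh$first_half$w$reject)
  expect_true(sh$second_half$w$reject)
})

test_that("split-half handles degenerate and short sessions", {
  degen <- make_session(c(rep("R", 6), rep("premature", 6)))
  expect_warning(sh <- split_half_homogeneity(degen),
                 "no start state")
  expect_true(sh$degenerate)
  expect_equal(sh$max_abs_diff_into_target, 0)

  ok <- make_session(c("R", "NR", "premature", "R", "NR", "R"))
  tiny <- make_session(c("R", "NR"))
  expect_warning(sh2 <- split_half_homogeneity(list(ok, tiny)),
                 "shorter than 4")
  expect_equal(sh2$first_half$counts$n_trials, 3L)
  expect_error(suppressWarnings(split_half_homogeneity(tiny)),
               "at least 4")
})
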