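#' Upper-alpha chi-squared critical value
#'
#' The alpha significance point of the chi-squared distribution, i.e. the
#' value exceeded with probability `alpha` under chi-squared with `dof`
#' degrees of freedom. At alpha = 0.05 this is 26.30 for the full 5-state
#' transition table (16 dof) and 11.07 for the restricted 5-dof test.
#'
#' @param alpha significance level in (0, 1).
#' @param dof degrees of freedom (>= 1).
#' @return the upper-alpha quantile of chi-squared(`dof`).
#' @export
#' @examples
#' chi2_critical(0.05, 16) # 26.296...
#' chi2_critical(0.05, 5)  # 11.070...
chi2_critical <- function(alpha, dof) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value in (0, 1)", call. = FALSE)
  if (!is.numeric(dof) || length(dof) != 1L || dof < 1)
    stop("dof must be a positive integer", call. = FALSE)
  stats::qchisq(1 - alpha, df = dof)
}

.make_test_result <- function(statistic, dof, alpha, kind) {
  critical <- chi2_critical(alpha, dof)
  dof <- as.integer(dof)
  structure(
    list(statistic = statistic, dof = dof, alpha = alpha,
         critical_value = critical,
         p_value = stats::pchisq(statistic, df = dof, lower.tail = FALSE),
         reject = statistic > critical,
         kind = kind),
    class = "markov_test")
}

#' @export
print.markov_test <- function(x, ...) {
  cat(sprintf("%s = %.2f on %d dof; critical value (alpha = %g) = %.2f; %s\n",
              x$kind, x$statistic, x$dof, x$alpha, x$critical_value,
              if (x$reject) "independence model REJECTED"
              else "independence model not rejected"))
  cat(sprintf("  p = %.4g\n", x$p_value))
  invisible(x)
}

#' Likelihood-ratio W statistic for the full transition table
#'
#' Tests the first-order Markov chain against the zeroth-order
#' (independence) model using the likelihood-ratio statistic
#' W = 2 * sum_ij O\[i, j\] * ln(O\[i, j\] / E\[i, j\]), the G statistic for
#' contingency tables. W approximates Pearson's chi-squared and is referred
#' to a chi-squared distribution with (S - 1)^2 = 16 degrees of freedom for
#' the 5-state outcome space. The independence model is rejected when W
#' exceeds the upper-alpha critical value (26.30 at alpha = 0.05); the
#' fixed-critical-value rule, not the p-value, drives the `reject` flag.
#'
#' Cells with O = 0 contribute nothing (0 * ln 0 = 0 convention); cells with
#' E = 0 and O = 0 are skipped, while E = 0 with O > 0 is a degenerate table
#' and raises an error.
#'
#' @param counts a [count_transitions()] result.
#' @param fit the [estimate_zeroth_order()] fit computed from `counts`.
#' @param alpha significance level (default 0.05).
#' @return an object of class `markov_test`.
#' @export
w_statistic <- function(counts, fit, alpha = 0.05) {
  stopifnot(inherits(counts, "transition_counts"),
            inherits(fit, "independence_fit"))
  O <- counts$counts
  E <- fit$expected
  if (any(E == 0 & O > 0))
    stop("degenerate table: observed transitions in a cell with zero ",
         "expected frequency", call. = FALSE)
  keep <- O > 0
  W <- 2 * sum(O[keep] * log(O[keep] / E[keep]))
  .make_test_result(W, dof = (N_STATES - 1L)^2, alpha = alpha, kind = "W")
}

#' Restricted chi-squared test on transitions into one state
#'
#' Narrows the full-table test to the transitions that end in a chosen
#' target state (by default the premature response): the statistic is
#' sum_i (O\[i, target\] - E\[i, target\])^2 / E\[i, target\] over start
#' states with positive expected frequency, referred to chi-squared with 5
#' degrees of freedom (critical value 11.07 at alpha = 0.05).
#'
#' @param counts a [count_transitions()] result.
#' @param fit the matching [estimate_zeroth_order()] fit.
#' @param target target end state, one of [OUTCOMES] (default
#'   `"premature"`).
#' @param alpha significance level (default 0.05).
#' @param dof degrees of freedom for the reference distribution; default 5
#'   (one per start state). A 4-dof variant is computable for sensitivity
#'   analysis but 5 is the decision rule applied throughout.
#' @return an object of class `markov_test`.
#' @export
chi2_into_state <- function(counts, fit, target = "premature",
                            alpha = 0.05, dof = 5L) {
  stopifnot(inherits(counts, "transition_counts"),
            inherits(fit, "independence_fit"))
  target <- match.arg(target, OUTCOMES)
  O <- counts$counts[, target]
  E <- fit$expected[, target]
  if (all(E == 0))
    stop("target state ", sQuote(target),
         " has zero expected frequency from every start state",
         call. = FALSE)
  keep <- E > 0
  stat <- sum((O[keep] - E[keep])^2 / E[keep])
  res <- .make_test_result(stat, dof = as.integer(dof), alpha = alpha,
                           kind = sprintf("chi2[-> %s]", target))
  res$target_state <- target
  res
}

#' Standardized deviation profile into a target state
#'
#' For each start state i, the standardized residual
#' Y\[i\] = (O\[i, target\] - E\[i, target\]) / sqrt(E\[i, target\])
#' measures how far the observed frequency of transitions ending in the
#' target state departs from the independence model. Positive values mean
#' more transitions than independence predicts; zero means no deviation.
#' Start states with E = 0 yield an undefined (NA) entry, flagged rather
#' than imputed.
#'
#' @inheritParams chi2_into_state
#' @return an object of class `deviation_profile`: `target_state`, `y`
#'   (named per start state, canonical order), `observed`, `expected` and
#'   `defined`.
#' @export
y_deviation <- function(counts, fit, target = "premature") {
  stopifnot(inherits(counts, "transition_counts"),
            inherits(fit, "independence_fit"))
  target <- match.arg(target, OUTCOMES)
  O <- counts$counts[, target]
  E <- fit$expected[, target]
  defined <- E > 0
  y <- ifelse(defined, (O - E) / sqrt(E), NA_real_)
  structure(
    list(target_state = target, y = y, observed = O, expected = E,
         defined = defined),
    class = "deviation_profile")
}

#' @export
print.deviation_profile <- function(x, digits = 2L, ...) {
  cat(sprintf("<deviation_profile> Y = (O - E)/sqrt(E) into %s\n",
              x$target_state))
  print(round(x$y, digits))
  invisible(x)
}

#' Split-half homogeneity check
#'
#' Splits each session at floor(n / 2) trials (no transition spans the
#' split), pools the first halves and the second halves separately, and
#' re-estimates the first-order transition matrix and the W test within
#' each half under the assumption of within-half homogeneity. The summary
#' statistic is the largest absolute difference between the two halves'
#' transition probabilities into the target state, over start states
#' defined in both halves; when no start state is defined in both halves
#' the difference is reported as 0 with `degenerate = TRUE`.
#'
#' Sessions shorter than 4 trials cannot contribute a transition to both
#' halves and are dropped with a warning.
#'
#' @param sessions a [csrtt_session()] or list of them.
#' @param target target end state (default `"premature"`).
#' @param alpha significance level for the per-half W tests.
#' @return an object of class `split_half_report`: per-half
#'   `transition_matrix` and `markov_test` objects, plus
#'   `max_abs_diff_into_target`, `diff_by_start` and `degenerate`.
#' @export
split_half_homogeneity <- function(sessions, target = "premature",
                                   alpha = 0.05) {
  if (inherits(sessions, "csrtt_session")) sessions <- list(sessions)
  target <- match.arg(target, OUTCOMES)
  lens <- vapply(sessions, length, integer(1L))
  if (any(lens < 4L)) {
    warning(sum(lens < 4L),
            " session(s) shorter than 4 trials excluded from the ",
            "split-half analysis")
    sessions <- sessions[lens >= 4L]
  }
  if (!length(sessions))
    stop("no sessions of at least 4 trials", call. = FALSE)
  halve <- function(s, which) {
    cut <- length(s$outcomes) %/% 2L
    keep <- if (which == 1L) seq_len(cut)
    else seq.int(cut + 1L, length(s$outcomes))
    csrtt_session(s$meta, s$outcomes[keep],
                  if (is.null(s$latencies_ms)) NULL else s$latencies_ms[keep])
  }
  analyse_half <- function(which) {
    cnt <- count_transitions(lapply(sessions, halve, which = which))
    if (cnt$n_transitions == 0L)
      stop("a session half contains zero transitions", call. = FALSE)
    list(counts = cnt,
         matrix = estimate_first_order(cnt),
         w = w_statistic(cnt, estimate_zeroth_order(cnt), alpha = alpha))
  }
  first <- analyse_half(1L)
  second <- analyse_half(2L)
  both <- first$matrix$defined_rows & second$matrix$defined_rows
  diff_by_start <- stats::setNames(rep(NA_real_, N_STATES), OUTCOMES)
  diff_by_start[both] <- abs(first$matrix$probs[both, target] -
                               second$matrix$probs[both, target])
  degenerate <- !any(both)
  if (degenerate)
    warning("no start state is defined in both halves; ",
            "max_abs_diff_into_target reported as 0")
  structure(
    list(first_half = first, second_half = second,
         target_state = target,
         diff_by_start = diff_by_start,
         max_abs_diff_into_target =
           if (degenerate) 0 else max(diff_by_start[both]),
         degenerate = degenerate),
    class = "split_half_report")
}

#' @export
print.split_half_report <- function(x, ...) {
  cat(sprintf(
    "<split_half_report> max |P1 - P2| into %s = %.4f%s\n",
    x$target_state, x$max_abs_diff_into_target,
    if (x$degenerate) " (degenerate: no commonly defined start state)" else ""))
  cat("first half:  "); print(x$first_half$w)
  cat("second half: "); print(x$second_half$w)
  invisible(x)
}
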