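#' Macro-level session summary
#'
#' Tallies the five outcome counts of one session and, when latencies are
#' present, the mean correct-response latency over R/NR trials. These are
#' the macro dependent variables (premature count, correct count, omissions,
#' latency) that sit alongside the trial-by-trial Markov analysis.
#'
#' @param session a [csrtt_session()].
#' @return a one-row data.frame: `subject`, `session`, `p_reward`, `iti_s`,
#'   `timeout_s`, one count column per outcome (canonical order),
#'   `premature_count`, `n_trials`, `mean_correct_latency_ms` (`NA` when no
#'   latencies are available).
#' @export
summarize_session <- function(session) {
  stopifnot(inherits(session, "csrtt_session"))
  counts <- table(outcome_factor(session$outcomes))
  lat <- NA_real_
  if (!is.null(session$latencies_ms)) {
    idx <- session$outcomes %in% c("R", "NR") &
      !is.na(session$latencies_ms)
    if (any(idx)) lat <- mean(session$latencies_ms[idx])
  }
  out <- data.frame(
    subject = session$meta$subject_id,
    session = session$meta$session_id,
    p_reward = session$meta$p_reward,
    iti_s = session$meta$iti_s,
    timeout_s = session$meta$timeout_s,
    stringsAsFactors = FALSE)
  for (o in OUTCOMES) out[[o]] <- as.integer(counts[[o]])
  out$premature_count <- as.integer(counts[["premature"]])
  out$n_trials <- length(session$outcomes)
  out$mean_correct_latency_ms <- lat
  out
}

#' Summarise many sessions
#' @param sessions list of [csrtt_session()] objects.
#' @return a data.frame, one row per session (see [summarize_session()]).
#' @export
summarize_sessions <- function(sessions) {
  if (inherits(sessions, "csrtt_session")) sessions <- list(sessions)
  do.call(rbind, lapply(sessions, summarize_session))
}

#' Quartile-based impulsivity screen
#'
#' Classifies subjects by their mean premature-response count across
#' screening sessions: strictly above the 75th percentile of subject means
#' is high-impulsive (`HI`), strictly below the 25th percentile is
#' low-impulsive (`LI`), everything else — including values tied with
#' either boundary — is mid-impulsive (`MID`). Percentiles use the
#' linear-interpolation convention of `stats::quantile(type = 7)` (R's
#' default). Ties going to `MID` keeps HI and LI strict extremes; with all
#' subjects identical, everyone is `MID`.
#'
#' @param mean_premature named numeric vector: one mean premature count per
#'   subject (names are subject ids); at least 4 subjects.
#' @return a data.frame with `subject`, `mean_premature`, `label`
#'   (`HI`/`MID`/`LI`), ordered as the input.
#' @export
#' @examples
#' classify_impulsivity(setNames(1:8, paste0("r", 1:8)))
classify_impulsivity <- function(mean_premature) {
  if (length(mean_premature) < 4L)
    stop("impulsivity screening needs at least 4 subjects", call. = FALSE)
  if (is.null(names(mean_premature)) || anyNA(names(mean_premature)))
    stop("mean_premature must be named by subject", call. = FALSE)
  if (anyNA(mean_premature))
    stop("mean_premature contains missing values", call. = FALSE)
  q <- stats::quantile(mean_premature, c(0.25, 0.75), names = FALSE,
                       type = 7)
  label <- ifelse(mean_premature > q[2L], "HI",
                  ifelse(mean_premature < q[1L], "LI", "MID"))
  data.frame(subject = names(mean_premature),
             mean_premature = as.numeric(mean_premature),
             label = label, row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen a cohort of sessions for impulsivity
#'
#' Convenience wrapper: averages premature counts per subject over the
#' supplied screening sessions (callers choose which sessions count as
#' challenge sessions) and applies [classify_impulsivity()].
#'
#' @param sessions list of [csrtt_session()] screening sessions.
#' @return see [classify_impulsivity()].
#' @export
screen_impulsivity <- function(sessions) {
  summ <- summarize_sessions(sessions)
  means <- tapply(summ$premature_count, summ$subject, mean)
  classify_impulsivity(stats::setNames(as.numeric(means), names(means)))
}

#' Correlation between premature responding and correct-response latency
#'
#' Pearson correlation (with two-sided p-value) between per-session
#' premature counts and mean correct-response latencies, mirroring the
#' macro-level latency analyses; intended for synthetic data only.
#'
#' @param summaries a data.frame from [summarize_sessions()] with at least
#'   3 rows carrying a latency.
#' @return a list with `r`, `p`, `n`.
#' @export
premature_latency_correlation <- function(summaries) {
  ok <- !is.na(summaries$mean_correct_latency_ms)
  x <- summaries$premature_count[ok]
  y <- summaries$mean_correct_latency_ms[ok]
  if (length(x) < 3L)
    stop("need at least 3 sessions with latencies", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in premature counts or ",
         "latencies", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
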