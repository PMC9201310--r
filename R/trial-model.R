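#' Session metadata
#'
#' Schedule and chamber parameters attached to one 5CSRTT session: the
#' reinforcement probability p(R) applied to correct responses, the
#' inter-trial interval and time-out durations (carried as metadata; the
#' Markov analysis never uses them numerically), and the session trial cap.
#'
#' @param subject_id,session_id opaque identifier strings.
#' @param p_reward probability in (0, 1] that a correct response is rewarded.
#' @param iti_s inter-trial interval in seconds (> 0).
#' @param timeout_s time-out punishment duration in seconds (> 0).
#' @param max_trials session trial cap (>= 1); standard sessions stop at 100
#'   trials, variable-ITI challenge sessions at 200.
#' @param cohort optional cohort label.
#' @return an object of class `session_meta`.
#' @export
session_meta <- function(subject_id, session_id, p_reward = 1,
                         iti_s = 5, timeout_s = 5, max_trials = 100L,
                         cohort = NA_character_) {
  stopifnot(length(subject_id) == 1L, length(session_id) == 1L)
  if (!is.numeric(p_reward) || length(p_reward) != 1L ||
      p_reward <= 0 || p_reward > 1)
    stop("p_reward must be a single value in (0, 1]", call. = FALSE)
  if (!is.numeric(iti_s) || iti_s <= 0) stop("iti_s must be > 0", call. = FALSE)
  if (!is.numeric(timeout_s) || timeout_s <= 0)
    stop("timeout_s must be > 0", call. = FALSE)
  max_trials <- as.integer(max_trials)
  if (is.na(max_trials) || max_trials < 1L)
    stop("max_trials must be >= 1", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         p_reward = as.numeric(p_reward),
         iti_s = as.numeric(iti_s),
         timeout_s = as.numeric(timeout_s),
         max_trials = max_trials,
         cohort = as.character(cohort)),
    class = "session_meta")
}

#' A single 5CSRTT session
#'
#' An ordered sequence of trial outcomes (1-based trial index, no gaps) with
#' its metadata and, optionally, per-trial response latencies in
#' milliseconds (`NA` allowed; latencies are never required by the Markov
#' analysis).
#'
#' @param meta a [session_meta()] object.
#' @param outcomes character vector of canonical outcome labels (see
#'   [OUTCOMES]); free-form labels are normalised via [normalize_outcome()].
#' @param latencies_ms optional numeric vector, same length as `outcomes`,
#'   nonnegative or `NA`.
#' @return an object of class `csrtt_session`.
#' @export
csrtt_session <- function(meta, outcomes, latencies_ms = NULL) {
  stopifnot(inherits(meta, "session_meta"))
  outcomes <- normalize_outcome(outcomes)
  n <- length(outcomes)
  if (n < 1L || n > meta$max_trials)
    stop("session must have between 1 and max_trials (", meta$max_trials,
         ") trials, got ", n, call. = FALSE)
  if (meta$p_reward == 1 && any(outcomes == "NR"))
    stop("session with p_reward = 1 cannot contain NR outcomes",
         call. = FALSE)
  if (!is.null(latencies_ms)) {
    if (length(latencies_ms) != n)
      stop("latencies_ms must match the number of trials", call. = FALSE)
    latencies_ms <- as.numeric(latencies_ms)
    if (any(latencies_ms < 0, na.rm = TRUE))
      stop("latencies must be nonnegative", call. = FALSE)
  }
  structure(
    list(meta = meta, outcomes = outcomes, latencies_ms = latencies_ms),
    class = "csrtt_session")
}

#' @export
print.csrtt_session <- function(x, ...) {
  cat(sprintf("<csrtt_session> subject %s, session %s: %d trials, p(R) = %g\n",
              x$meta$subject_id, x$meta$session_id,
              length(x$outcomes), x$meta$p_reward))
  print(table(outcome_factor(x$outcomes)))
  invisible(x)
}

#' @export
length.csrtt_session <- function(x) length(x$outcomes)

.LOG_COLUMNS <- c("subject", "session", "trial", "outcome",
                  "p_reward", "iti_s", "timeout_s")

#' Read a trial log
#'
#' Reads a delimited trial log (one row per trial, UTF-8, header
#' `subject,session,trial,outcome,p_reward,iti_s,timeout_s[,latency_ms]`,
#' optionally also `max_trials` and `cohort`) and returns sessions grouped
#' by `(subject, session)` with outcomes ordered by trial index. Outcome
#' labels are matched case- and whitespace-insensitively against the alias
#' table of [normalize_outcome()].
#'
#' @param path path to a delimited text file (or a connection).
#' @param sep field separator, default comma.
#' @return a list of [csrtt_session()] objects (empty for a header-only file).
#' @export
read_trial_log <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = NA,
                          blank.lines.skip = TRUE)
  missing_cols <- setdiff(.LOG_COLUMNS, names(df))
  if (length(missing_cols))
    stop("trial log is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) return(list())
  raw_outcome <- as.character(df$outcome)
  canon <- tryCatch(normalize_outcome(raw_outcome), error = function(e) e)
  if (inherits(canon, "error")) {
    bad_rows <- which(is.na(.OUTCOME_ALIASES[
      gsub("\\s+", " ", gsub("[_\\-]+", " ", tolower(trimws(raw_outcome))))]))
    stop("unparseable outcome label at data row(s) ",
         paste(utils::head(bad_rows, 5L), collapse = ", "), ": ",
         conditionMessage(canon), call. = FALSE)
  }
  df$outcome <- canon
  key <- interaction(df$subject, df$session, drop = TRUE, lex.order = TRUE)
  lapply(split(df, key), function(grp) {
    grp <- grp[order(grp$trial), , drop = FALSE]
    idx <- as.integer(grp$trial)
    if (anyDuplicated(idx) || !identical(idx, seq_along(idx)))
      stop("non-contiguous or duplicated trial indices for subject ",
           grp$subject[1L], ", session ", grp$session[1L], call. = FALSE)
    for (col in c("p_reward", "iti_s", "timeout_s")) {
      if (length(unique(grp[[col]])) != 1L)
        stop("inconsistent ", col, " within session ", grp$session[1L],
             call. = FALSE)
    }
    meta <- session_meta(
      subject_id = grp$subject[1L], session_id = grp$session[1L],
      p_reward = grp$p_reward[1L], iti_s = grp$iti_s[1L],
      timeout_s = grp$timeout_s[1L],
      max_trials = if ("max_trials" %in% names(grp))
        grp$max_trials[1L] else max(100L, nrow(grp)),
      cohort = if ("cohort" %in% names(grp)) grp$cohort[1L] else NA_character_)
    lat <- if ("latency_ms" %in% names(grp))
      as.numeric(grp$latency_ms) else NULL
    if (!is.null(lat) && all(is.na(lat))) lat <- NULL
    csrtt_session(meta, grp$outcome, lat)
  })
}

#' Write a trial log
#'
#' Writes sessions to the delimited trial-log format read by
#' [read_trial_log()]. Round-trip safe: reading the written file reproduces
#' the sessions field for field. Missing latencies are written as empty
#' fields.
#'
#' @param sessions a list of [csrtt_session()] objects (may be empty).
#' @param path output path or connection.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(sessions, path) {
  stopifnot(is.list(sessions),
            all(vapply(sessions, inherits, logical(1L), "csrtt_session")))
  rows <- lapply(sessions, function(s) {
    n <- length(s$outcomes)
    data.frame(
      subject = s$meta$subject_id, session = s$meta$session_id,
      trial = seq_len(n), outcome = s$outcomes,
      p_reward = s$meta$p_reward, iti_s = s$meta$iti_s,
      timeout_s = s$meta$timeout_s, max_trials = s$meta$max_trials,
      cohort = s$meta$cohort,
      latency_ms = if (is.null(s$latencies_ms)) NA_real_ else s$latencies_ms,
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(
      as.data.frame(matrix(nrow = 0L, ncol = length(.LOG_COLUMNS) + 3L)),
      c(.LOG_COLUMNS, "max_trials", "cohort", "latency_ms"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
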