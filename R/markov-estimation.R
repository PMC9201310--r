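#' Count one-step transitions
#'
#' Tallies the observed transition frequencies O\[i, j\] between adjacent
#' trial outcomes (start state i at trial t-1, end state j at trial t)
#' within each session. When several sessions are supplied their tables are
#' summed; transitions never bridge a session boundary, so a list of k
#' sessions with n_1, ..., n_k trials contributes sum(n_m - 1) transition
#' pairs.
#'
#' @param sessions a single [csrtt_session()] or a list of them.
#' @param pool if `TRUE` (default) sum the tables across sessions; if
#'   `FALSE`, return one `transition_counts` per session.
#' @return an object of class `transition_counts` with components:
#'   \describe{
#'     \item{counts}{5 x 5 integer matrix in canonical outcome order,
#'       start states as rows, end states as columns.}
#'     \item{n_transitions}{total number of adjacent pairs.}
#'     \item{start_totals}{row margins: per-state counts over trials with a
#'       successor (trials 1..n-1 of each session).}
#'     \item{end_totals}{column margins: per-state counts over trials 2..n.}
#'     \item{state_totals}{per-state counts over all trials (used by the
#'       all-trials margin of [estimate_zeroth_order()]).}
#'     \item{n_trials, n_sessions}{bookkeeping totals.}
#'   }
#' @export
#' @examples
#' s <- csrtt_session(session_meta("r1", "base"), c("R", "R", "premature"))
#' count_transitions(s)$counts
count_transitions <- function(sessions, pool = TRUE) {
  if (inherits(sessions, "csrtt_session")) sessions <- list(sessions)
  if (!length(sessions)) stop("no sessions supplied", call. = FALSE)
  stopifnot(all(vapply(sessions, inherits, logical(1L), "csrtt_session")))
  if (!pool) return(lapply(sessions, count_transitions))
  counts <- matrix(0L, N_STATES, N_STATES,
                   dimnames = list(start = OUTCOMES, end = OUTCOMES))
  state_totals <- stats::setNames(integer(N_STATES), OUTCOMES)
  n_trials <- 0L
  for (s in sessions) {
    idx <- match(s$outcomes, OUTCOMES)
    n <- length(idx)
    n_trials <- n_trials + n
    state_totals <- state_totals + tabulate(idx, N_STATES)
    if (n >= 2L) {
      from <- idx[-n]
      to <- idx[-1L]
      # accumulate pairs through their flattened cell index
      cell <- tabulate(from + N_STATES * (to - 1L), N_STATES * N_STATES)
      counts <- counts + matrix(cell, N_STATES, N_STATES)
    }
  }
  structure(
    list(counts = counts,
         n_transitions = sum(counts),
         start_totals = rowSums(counts),
         end_totals = colSums(counts),
         state_totals = state_totals,
         n_trials = n_trials,
         n_sessions = length(sessions)),
    class = "transition_counts")
}

#' Wrap a pre-tabulated transition frequency matrix
#'
#' Builds a `transition_counts` object from an already-tabulated 5 x 5
#' frequency matrix (e.g. a published pooled table), so the estimators and
#' diagnostics can be applied without the raw trial sequences. The
#' all-trials margin is unrecoverable from a table alone, so `state_totals`
#' is set to the end margin; only the `"all"` margin of
#' [estimate_zeroth_order()] is affected.
#'
#' @param m 5 x 5 matrix of nonnegative integers, canonical [OUTCOMES]
#'   order (start states as rows).
#' @param n_sessions number of sessions the table pools (bookkeeping only).
#' @return a `transition_counts` object.
#' @export
as_transition_counts <- function(m, n_sessions = 1L) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == N_STATES), all(m >= 0),
            all(abs(m - round(m)) < 1e-9))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(start = OUTCOMES, end = OUTCOMES)
  structure(
    list(counts = m,
         n_transitions = sum(m),
         start_totals = rowSums(m),
         end_totals = colSums(m),
         state_totals = colSums(m),
         n_trials = sum(m) + n_sessions,
         n_sessions = as.integer(n_sessions)),
    class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat(sprintf(
    "<transition_counts> %d transitions from %d trials in %d session(s)\n",
    x$n_transitions, x$n_trials, x$n_sessions))
  print(x$counts)
  invisible(x)
}

#' First-order transition probability estimates
#'
#' Row-normalises a transition frequency table into the maximum-likelihood
#' estimate of a homogeneous first-order Markov chain:
#' P(X_t = j | X_t-1 = i) = O\[i, j\] / (row total of i). A start state that
#' never occurs with a successor yields an undefined row, flagged in
#' `defined_rows` and filled with `NA` rather than imputed or smoothed.
#'
#' @param counts a [count_transitions()] result.
#' @return an object of class `transition_matrix` with `probs` (5 x 5),
#'   `defined_rows` (logical per start state) and `start_totals`.
#' @export
estimate_first_order <- function(counts) {
  stopifnot(inherits(counts, "transition_counts"))
  defined <- counts$start_totals > 0L
  probs <- counts$counts / ifelse(defined, counts$start_totals, NA_real_)
  probs[!defined, ] <- NA_real_
  structure(
    list(probs = probs, defined_rows = defined,
         start_totals = counts$start_totals),
    class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 3L, ...) {
  cat("<transition_matrix> P(end | start); undefined rows shown as NA\n")
  print(round(x$probs, digits))
  invisible(x)
}

#' Zeroth-order (independence) model fit
#'
#' Estimates the independence model in which the outcome at trial t does not
#' depend on history: state probabilities p\[j\] = P(X_t = j) are the
#' normalised per-state frequencies of the chosen margin, and the expected
#' transition frequency under independence is
#' E\[i, j\] = p\[j\] * (start total of i) — with the end margin this is the
#' textbook product form (#end-state j) x (#start-state i) / (#transitions).
#'
#' @param counts a [count_transitions()] result with at least one transition.
#' @param margin which per-state frequencies estimate p\[j\]: `"end"`
#'   (trials 2..n of each session; the default, matching the product
#'   formula), `"start"` (trials 1..n-1), or `"all"` (all trials). At
#'   session lengths near 100 the three differ by at most one count per
#'   state and are exposed only for sensitivity checks.
#' @return an object of class `independence_fit` with `state_probs`
#'   (length-5 probability vector), `expected` (5 x 5 matrix) and `margin`.
#' @export
estimate_zeroth_order <- function(counts,
                                  margin = c("end", "start", "all")) {
  stopifnot(inherits(counts, "transition_counts"))
  margin <- match.arg(margin)
  if (counts$n_transitions < 1L)
    stop("cannot fit the independence model with zero transitions",
         call. = FALSE)
  freq <- switch(margin,
                 end = counts$end_totals,
                 start = counts$start_totals,
                 all = counts$state_totals)
  state_probs <- freq / sum(freq)
  expected <- outer(counts$start_totals, state_probs)
  dimnames(expected) <- dimnames(counts$counts)
  structure(
    list(state_probs = state_probs, expected = expected, margin = margin),
    class = "independence_fit")
}

#' @export
print.independence_fit <- function(x, digits = 3L, ...) {
  cat(sprintf("<independence_fit> margin = %s\n", x$margin))
  print(round(x$state_probs, digits))
  invisible(x)
}

#' Export a labelled matrix as CSV
#'
#' Writes a transition frequency or probability matrix with outcome labels
#' as row and column headers, start states as rows and end states as
#' columns, in canonical outcome order.
#'
#' @param x a `transition_counts`, `transition_matrix`, `independence_fit`
#'   or plain matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path) {
  m <- if (inherits(x, "transition_counts")) x$counts
  else if (inherits(x, "transition_matrix")) x$probs
  else if (inherits(x, "independence_fit")) x$expected
  else as.matrix(x)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
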