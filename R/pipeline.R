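#' Build a behavioural policy from a plain-list specification
#'
#' Used when pipeline configs are read from YAML/JSON: `kind` plus either
#' `action_probs` (length 4, [ACTIONS] order) or `conditional_probs` (a 5 x
#' 4 matrix, or a list of 5 length-4 rows in [OUTCOMES] order).
#'
#' @param spec a list.
#' @return a [behavior_policy()].
#' @export
policy_from_config <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$kind))
  cp <- spec$conditional_probs
  if (!is.null(cp) && is.list(cp))
    cp <- do.call(rbind, lapply(cp, as.numeric))
  behavior_policy(kind = spec$kind,
                  action_probs = spec$action_probs,
                  conditional_probs = cp,
                  initial_action_probs = spec$initial_action_probs)
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the yaml package is required to read YAML configs",
             call. = FALSE)
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}

.generate_sessions <- function(gen, seed) {
  metas <- lapply(seq_along(gen$conditions), function(i) {
    cond <- gen$conditions[[i]]
    session_meta(
      subject_id = "template",
      session_id = if (!is.null(cond$label)) cond$label
      else sprintf("cond%02d", i),
      p_reward = cond$p_reward,
      iti_s = if (is.null(cond$iti_s)) 5 else cond$iti_s,
      timeout_s = if (is.null(cond$timeout_s)) 5 else cond$timeout_s,
      max_trials = if (is.null(cond$max_trials)) 100L else cond$max_trials)
  })
  simulate_cohort(
    n_subjects = gen$n_subjects,
    base_policy = policy_from_config(gen$policy),
    between_subject_sd = if (is.null(gen$between_subject_sd)) 0
    else gen$between_subject_sd,
    metas = metas,
    master_seed = if (!is.null(gen$master_seed)) gen$master_seed else seed,
    block_size = if (is.null(gen$block_size)) 20L else gen$block_size,
    latency_model = gen$latency_model)
}

#' Analyse one pooled condition group
#'
#' The per-condition analysis unit of the pipeline: pools transition counts
#' across the supplied sessions (never bridging session boundaries), fits
#' the first-order chain and the independence model, and runs the full
#' diagnostic battery.
#'
#' @param sessions list of [csrtt_session()] objects belonging to one
#'   condition.
#' @param alpha significance level.
#' @param target target end state for the restricted test and Y profile.
#' @return a list: `counts`, `first_order`, `independence`, `w`,
#'   `chi2_target`, `y_profile`, `split_half` (or `NULL` with a warning if
#'   degenerate), `summaries`.
#' @export
analyze_condition <- function(sessions, alpha = 0.05,
                              target = "premature") {
  counts <- count_transitions(sessions)
  fit0 <- estimate_zeroth_order(counts)
  list(
    counts = counts,
    first_order = estimate_first_order(counts),
    independence = fit0,
    w = w_statistic(counts, fit0, alpha = alpha),
    # the restricted test is undefined when the target is never expected
    # (e.g. a condition with no premature responses at all)
    chi2_target = tryCatch(
      chi2_into_state(counts, fit0, target = target, alpha = alpha),
      error = function(e) NULL),
    y_profile = y_deviation(counts, fit0, target = target),
    split_half = tryCatch(
      suppressWarnings(split_half_homogeneity(sessions, target = target,
                                              alpha = alpha)),
      error = function(e) NULL),
    summaries = summarize_sessions(sessions))
}

#' Run the generate/estimate/diagnose/report pipeline
#'
#' Takes sessions from a trial log or from the synthetic generator, groups
#' them by condition (by default the schedule variables p(R), ITI and
#' time-out), and for each condition writes pooled transition-count and
#' probability matrices (CSV), a diagnostics report (JSON: W, restricted
#' chi-squared, Y profile, split-half summary), session summaries (CSV) and
#' a plain-text run manifest.
#'
#' @param config a list, or path to a YAML/JSON file, with fields:
#'   \describe{
#'     \item{input}{path to a trial log (exclusive with `generator`).}
#'     \item{generator}{synthetic-cohort spec: `policy` (see
#'       [policy_from_config()]), `n_subjects`, `conditions` (list of
#'       `p_reward`/`iti_s`/`timeout_s`/`max_trials`/`label`),
#'       `between_subject_sd`, `block_size`, `latency_model`.}
#'     \item{group_by}{metadata fields defining a condition; default
#'       `c("p_reward", "iti_s", "timeout_s")`.}
#'     \item{alpha}{significance level, default 0.05.}
#'     \item{target}{target end state, default `"premature"`.}
#'     \item{out_dir}{output directory (created if needed).}
#'     \item{seed}{integer seed for generation.}
#'   }
#' @param out_dir overrides `config$out_dir` when given.
#' @return invisibly, a named list of [analyze_condition()] results, one
#'   per condition.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- .load_config(config)
  if (is.null(config$input) == is.null(config$generator))
    stop("config must set exactly one of 'input' or 'generator'",
         call. = FALSE)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("no output directory given", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  alpha <- config$alpha %||% 0.05
  target <- config$target %||% "premature"
  group_by <- config$group_by %||% c("p_reward", "iti_s", "timeout_s")
  seed <- config$seed %||% 1L

  sessions <- if (!is.null(config$input)) read_trial_log(config$input)
  else .generate_sessions(config$generator, seed)
  if (!is.null(config$generator))
    write_trial_log(sessions, file.path(out_dir, "sessions.csv"))

  keys <- vapply(sessions, function(s)
    paste(vapply(group_by, function(g) format(s$meta[[g]]), character(1L)),
          collapse = "_"), character(1L))
  groups <- split(sessions, keys)

  results <- list()
  for (name in names(groups)) {
    grp <- groups[[name]]
    if (!length(grp)) next
    res <- analyze_condition(grp, alpha = alpha, target = target)
    results[[name]] <- res
    prefix <- file.path(out_dir, paste0("condition_", name))
    write_matrix_csv(res$counts, paste0(prefix, "_counts.csv"))
    write_matrix_csv(res$first_order, paste0(prefix, "_probs.csv"))
    write_matrix_csv(res$independence, paste0(prefix, "_expected.csv"))
    utils::write.csv(res$summaries, paste0(prefix, "_summaries.csv"),
                     row.names = FALSE)
    report <- list(
      condition = name,
      n_sessions = res$counts$n_sessions,
      n_trials = res$counts$n_trials,
      n_transitions = res$counts$n_transitions,
      W = res$w[c("statistic", "dof", "critical_value", "p_value",
                  "reject")],
      chi2_target = if (is.null(res$chi2_target)) NULL else
        res$chi2_target[c("statistic", "dof", "critical_value",
                          "p_value", "reject", "target_state")],
      y_profile = as.list(res$y_profile$y),
      split_half = if (is.null(res$split_half)) NULL else
        list(max_abs_diff_into_target =
               res$split_half$max_abs_diff_into_target,
             degenerate = res$split_half$degenerate,
             w_first = res$split_half$first_half$w$statistic,
             w_second = res$split_half$second_half$w$statistic))
    jsonlite::write_json(report, paste0(prefix, "_diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  manifest <- c(
    sprintf("markov5csrtt %s",
            as.character(utils::packageVersion("markov5csrtt"))),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("alpha: %g; target: %s", alpha, target),
    sprintf("grouping: %s", paste(group_by, collapse = ", ")),
    sprintf("conditions: %s", paste(names(groups), collapse = "; ")),
    sprintf("sessions: %d", length(sessions)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
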