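#' Canonical 5CSRTT trial outcomes
#'
#' The five possible end states of a 5CSRTT trial under partial
#' reinforcement: correct rewarded (`"R"`), correct non-rewarded (`"NR"`),
#' `"premature"` (a nose-poke before cue onset), `"incorrect"` (response in a
#' non-target aperture) and `"omission"` (no response within the limited
#' hold). This vector fixes the canonical ordering used for all matrix
#' indexing throughout the package: rows and columns of every transition
#' table follow it.
#'
#' @format A character vector of length 5.
#' @export
OUTCOMES <- c("R", "NR", "premature", "incorrect", "omission")

#' Number of chain states
#' @keywords internal
N_STATES <- 5L

# Alias table for ingesting hand-made trial logs: long-form phrases map to
# the canonical labels. Keys are compared after lower-casing and collapsing
# whitespace/underscores/hyphens.
.OUTCOME_ALIASES <- c(
  "r"                    = "R",
  "correct rewarded"     = "R",
  "rewarded"             = "R",
  "nr"                   = "NR",
  "correct non rewarded" = "NR",
  "correct nonrewarded"  = "NR",
  "non rewarded"         = "NR",
  "premature"            = "premature",
  "incorrect"            = "incorrect",
  "omission"             = "omission",
  "omitted"              = "omission"
)

#' Normalise outcome labels
#'
#' Maps free-form outcome labels (case-, whitespace-, hyphen- and
#' underscore-insensitive; e.g. `"Correct  Rewarded"`, `"correct_non-rewarded"`)
#' to the canonical labels in [OUTCOMES].
#'
#' @param x character vector of raw labels.
#' @return character vector of canonical labels.
#' @export
#' @examples
#' normalize_outcome(c("Correct Rewarded", "PREMATURE", "nr"))
normalize_outcome <- function(x) {
  key <- tolower(trimws(as.character(x)))
  key <- gsub("[_\\-]+", " ", key)
  key <- gsub("\\s+", " ", key)
  out <- .OUTCOME_ALIASES[key]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown outcome label(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}

#' Outcome factor in canonical order
#' @param x character vector of canonical labels.
#' @return factor with levels [OUTCOMES].
#' @keywords internal
outcome_factor <- function(x) factor(x, levels = OUTCOMES)
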