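#' Consecutive-agreement aggregation policy
#'
#' Constructs the policy object governing how ordered classification streams
#' are collapsed into collective decisions. A record is finalised at the first
#' run of `k` identical verdicts. What happens when contributors disagree
#' before a run forms is controlled by `conflict_mode`:
#'
#' * `"streak_continue"` (default): scanning continues past disagreements
#'   until a run of `k` occurs or `max_assessments` classifications have been
#'   consumed, after which the record needs resolution.
#' * `"strict_first_k"`: any disagreement before the first `k`
#'   classifications agree sends the record to resolution immediately.
#'
#' @param k Required streak length (positive integer, default 3 -- three
#'   consecutive agreeing classifications).
#' @param conflict_mode `"streak_continue"` or `"strict_first_k"`.
#' @param max_assessments Cap on classifications consumed per record before
#'   arbitration; defaults to `2 * k + 1`. Must be at least `k`. Only
#'   binding in `"streak_continue"` mode.
#' @param deadline_hours Task deadline in hours (default 48); used by the
#'   simulator, not by stream aggregation itself.
#'
#' @return An object of class `agreement_policy`.
#' @examples
#' agreement_policy()                       # k = 3, streak_continue, cap 7
#' agreement_policy(k = 2, conflict_mode = "strict_first_k")
#' @export
agreement_policy <- function(k = 3,
                             conflict_mode = c("streak_continue", "strict_first_k"),
                             max_assessments = 2 * k + 1,
                             deadline_hours = 48) {
  conflict_mode <- match.arg(conflict_mode)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != floor(k)) {
    rlang::abort("`k` must be a positive integer.", class = "crowdscreen_policy_error")
  }
  if (!is.numeric(max_assessments) || length(max_assessments) != 1L ||
      is.na(max_assessments) || max_assessments != floor(max_assessments)) {
    rlang::abort("`max_assessments` must be a positive integer.",
                 class = "crowdscreen_policy_error")
  }
  if (max_assessments < k) {
    rlang::abort("`max_assessments` must be >= `k`.",
                 class = "crowdscreen_policy_error")
  }
  if (!is.numeric(deadline_hours) || length(deadline_hours) != 1L ||
      is.na(deadline_hours) || deadline_hours <= 0) {
    rlang::abort("`deadline_hours` must be a positive number.",
                 class = "crowdscreen_policy_error")
  }
  structure(
    list(
      k = as.integer(k),
      conflict_mode = conflict_mode,
      max_assessments = as.integer(max_assessments),
      deadline_hours = as.numeric(deadline_hours)
    ),
    class = "agreement_policy"
  )
}

#' @export
print.agreement_policy <- function(x, ...) {
  cat("<agreement_policy>\n")
  cat("  k:               ", x$k, "\n", sep = "")
  cat("  conflict_mode:   ", x$conflict_mode, "\n", sep = "")
  cat("  max_assessments: ", x$max_assessments, "\n", sep = "")
  cat("  deadline_hours:  ", x$deadline_hours, "\n", sep = "")
  invisible(x)
}

# verdict / status / label vocabularies used across the package
verdict_levels <- function() c("possibly_relevant", "not_relevant")
status_levels <- function() c("possibly_relevant", "not_relevant", "needs_resolution")
reference_levels <- function() c("relevant", "not_relevant", "unknown")

check_verdicts <- function(x, what = "verdict") {
  bad <- setdiff(unique(as.character(x)), verdict_levels())
  if (length(bad)) {
    rlang::abort(
      sprintf("Invalid %s value(s): %s. Allowed: %s.",
              what, paste(sQuote(bad), collapse = ", "),
              paste(verdict_levels(), collapse = ", ")),
      class = "crowdscreen_vocab_error"
    )
  }
  invisible(x)
}
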