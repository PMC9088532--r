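# Author-team workflows: how collective crowd decisions are consumed
# downstream, and what each route costs in human assessments.

workflow_modes <- function() {
  c("sensitivity_max", "speed_max", "specificity_max")
}

#' Route crowd decisions through an author-team workflow
#'
#' Three workflow variants trade sensitivity against speed and specificity:
#'
#' * `sensitivity_max`: conflicted records go to author-team dual
#'   assessment (two assessments per record) and consensus
#'   possibly-relevant records to author single assessment; consensus
#'   not-relevant records are auto-excluded.
#' * `speed_max`: consensus possibly-relevant records *and* conflicted
#'   records go to author single assessment; consensus not-relevant records
#'   are auto-excluded. (Conflicts are routed to the authors rather than
#'   dropped.)
#' * `specificity_max`: conflicted records are first finalised by a crowd
#'   resolver (one crowd assessment each); all records whose final crowd
#'   verdict is possibly relevant then go to author single assessment, the
#'   rest are excluded.
#'
#' @param decisions Decision tibble (see [aggregate_task()]).
#' @param mode One of `"sensitivity_max"`, `"speed_max"`,
#'   `"specificity_max"`.
#' @param resolver_labels Data frame `record_id`, `verdict`; required for
#'   `specificity_max` unless every conflicted decision already carries a
#'   `resolver_verdict`.
#' @return A list of class `crowd_workflow`: `mode`, `author_queue`
#'   (record ids for the author team, with an `assessments` column),
#'   `excluded` (record ids never seen by the authors), and `workload`
#'   (one-row tibble: `author_single_assessments`,
#'   `author_dual_assessments`, `crowd_resolver_assessments`,
#'   `records_autoexcluded`).
#' @examples
#' \dontrun{
#' apply_workflow(decisions, "speed_max")
#' }
#' @export
apply_workflow <- function(decisions, mode = workflow_modes(),
                           resolver_labels = NULL) {
  mode <- match.arg(mode, workflow_modes())
  decisions <- tibble::as_tibble(decisions)
  if (nrow(decisions) == 0L) {
    rlang::abort("No decisions to route.", class = "crowdscreen_workflow_error")
  }
  cons_p <- decisions$reached_by_consensus & decisions$status == "possibly_relevant"
  cons_n <- decisions$reached_by_consensus & decisions$status == "not_relevant"
  conflicted <- !decisions$reached_by_consensus

  if (mode == "sensitivity_max") {
    queue <- tibble::tibble(
      record_id = c(decisions$record_id[conflicted], decisions$record_id[cons_p]),
      route = rep(c("dual", "single"), c(sum(conflicted), sum(cons_p))),
      assessments = rep(c(2L, 1L), c(sum(conflicted), sum(cons_p)))
    )
    excluded <- decisions$record_id[cons_n]
    workload <- tibble::tibble(
      author_single_assessments = sum(cons_p),
      author_dual_assessments = 2L * sum(conflicted),
      crowd_resolver_assessments = 0L,
      records_autoexcluded = sum(cons_n)
    )
  } else if (mode == "speed_max") {
    pick <- cons_p | conflicted
    queue <- tibble::tibble(
      record_id = decisions$record_id[pick],
      route = "single",
      assessments = 1L
    )
    excluded <- decisions$record_id[cons_n]
    workload <- tibble::tibble(
      author_single_assessments = sum(pick),
      author_dual_assessments = 0L,
      crowd_resolver_assessments = 0L,
      records_autoexcluded = sum(cons_n)
    )
  } else { # specificity_max
    if (!is.null(resolver_labels)) {
      decisions <- apply_resolver(decisions, resolver_labels)
    }
    fv <- final_verdict(decisions)
    if (anyNA(fv)) {
      rlang::abort(
        sprintf("specificity_max needs resolver labels for conflicted record(s): %s.",
                paste(utils::head(decisions$record_id[is.na(fv)], 5L), collapse = ", ")),
        class = "crowdscreen_workflow_error"
      )
    }
    queue <- tibble::tibble(
      record_id = decisions$record_id[fv == "possibly_relevant"],
      route = "single",
      assessments = 1L
    )
    excluded <- decisions$record_id[fv == "not_relevant"]
    workload <- tibble::tibble(
      author_single_assessments = sum(fv == "possibly_relevant"),
      author_dual_assessments = 0L,
      crowd_resolver_assessments = sum(conflicted),
      records_autoexcluded = sum(fv == "not_relevant")
    )
  }
  structure(list(mode = mode, author_queue = queue,
                 excluded = excluded, workload = workload),
            class = "crowd_workflow")
}

#' @export
print.crowd_workflow <- function(x, ...) {
  cat("<crowd_workflow>", x$mode, "\n")
  w <- x$workload
  cat(sprintf("  author singles %d, author duals %d, resolver %d, auto-excluded %d\n",
              w$author_single_assessments, w$author_dual_assessments,
              w$crowd_resolver_assessments, w$records_autoexcluded))
  invisible(x)
}

#' Tidy a workflow's workload estimate
#'
#' @param x A `crowd_workflow` from [apply_workflow()].
#' @param ... Unused.
#' @return One-row tibble: mode plus the workload counts.
#' @method tidy crowd_workflow
#' @export
tidy.crowd_workflow <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(mode = x$mode), x$workload)
}

#' Fraction of records the author team never sees
#'
#' The screening saving of a workflow: records auto-excluded by the crowd
#' divided by all records.
#'
#' @inheritParams apply_workflow
#' @return Fraction in \[0, 1\].
#' @export
workflow_screening_saving <- function(decisions, mode = workflow_modes(),
                                      resolver_labels = NULL) {
  wf <- apply_workflow(decisions, mode, resolver_labels)
  length(wf$excluded) / nrow(tibble::as_tibble(decisions))
}
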