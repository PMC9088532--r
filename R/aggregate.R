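#' @importFrom rlang .data
NULL

# --- stream validation --------------------------------------------------

stream_columns <- function() {
  c("record_id", "contributor_id", "ordinal", "verdict")
}

#' Validate a classification stream
#'
#' Checks the invariants every classification stream must satisfy: required
#' columns present, verdict vocabulary respected, ordinals consecutive from 1
#' within each record, no contributor classifying the same record twice, and
#' timestamps (when present) non-decreasing in ordinal.
#'
#' @param events A data frame of classification events with columns
#'   `record_id`, `contributor_id`, `ordinal`, `verdict` and optionally
#'   `timestamp_hours`.
#' @return The events, invisibly, as a tibble sorted by record and ordinal.
#' @export
validate_stream <- function(events) {
  events <- tibble::as_tibble(events)
  missing <- setdiff(stream_columns(), names(events))
  if (length(missing)) {
    rlang::abort(
      sprintf("Stream is missing column(s): %s.", paste(missing, collapse = ", ")),
      class = "crowdscreen_stream_error"
    )
  }
  check_verdicts(events$verdict)
  if (nrow(events) == 0L) {
    return(invisible(events))
  }
  events <- dplyr::arrange(events, .data$record_id, .data$ordinal)
  # ordinals consecutive from 1 within each record
  first <- !duplicated(events$record_id)
  pos <- seq_len(nrow(events)) -
    cummax(ifelse(first, seq_len(nrow(events)), 0L)) + 1L
  if (any(events$ordinal != pos)) {
    bad <- unique(events$record_id[events$ordinal != pos])
    rlang::abort(
      sprintf("Ordinals must be consecutive starting at 1; violated for record(s): %s.",
              paste(utils::head(bad, 5L), collapse = ", ")),
      class = "crowdscreen_stream_error"
    )
  }
  dup <- duplicated(events[c("record_id", "contributor_id")])
  if (any(dup)) {
    bad <- unique(events$record_id[dup])
    rlang::abort(
      sprintf("A contributor may classify a record at most once; violated for record(s): %s.",
              paste(utils::head(bad, 5L), collapse = ", ")),
      class = "crowdscreen_stream_error"
    )
  }
  if ("timestamp_hours" %in% names(events) && !all(is.na(events$timestamp_hours))) {
    lagged <- dplyr::lag(events$timestamp_hours)
    decreasing <- !first & !is.na(lagged) & !is.na(events$timestamp_hours) &
      events$timestamp_hours < lagged
    if (any(decreasing)) {
      rlang::abort(
        sprintf("Timestamps must be non-decreasing in ordinal; violated for record(s): %s.",
                paste(utils::head(unique(events$record_id[decreasing]), 5L), collapse = ", ")),
        class = "crowdscreen_stream_error"
      )
    }
  }
  invisible(events)
}

# --- the consecutive-agreement scanner ---------------------------------

# Vectorised over records: events must be sorted by record_id, ordinal and
# already validated. Returns one decision row per distinct record_id, in
# order of first appearance in `record_order`.
scan_streams <- function(events, policy, record_order) {
  n <- nrow(events)
  empty <- tibble::tibble(
    record_id = record_order,
    status = character(length(record_order)),
    reached_by_consensus = logical(length(record_order)),
    n_classifications = integer(length(record_order)),
    resolver_verdict = rep(NA_character_, length(record_order))
  )
  if (n == 0L) {
    empty$status <- rep("needs_resolution", length(record_order))
    return(empty)
  }
  idx <- seq_len(n)
  v <- as.character(events$verdict)
  ord <- as.integer(events$ordinal)
  rec_start <- !duplicated(events$record_id)
  len <- tabulate(match(events$record_id, unique(events$record_id)))
  rec_len <- stats::setNames(len, unique(events$record_id))

  if (policy$conflict_mode == "strict_first_k") {
    first_idx <- cummax(ifelse(rec_start, idx, 0L))
    disagree <- v != v[first_idx] & ord <= policy$k
    hit <- idx[disagree][!duplicated(events$record_id[idx[disagree]])]
    conflict_n <- stats::setNames(ord[hit], events$record_id[hit])

    ids <- record_order
    length_of <- unname(rec_len[ids])
    length_of[is.na(length_of)] <- 0L
    conflict_at <- unname(conflict_n[ids])
    consensus <- is.na(conflict_at) & length_of >= policy$k
    first_v <- stats::setNames(v[rec_start], events$record_id[rec_start])
    status <- ifelse(consensus, unname(first_v[ids]), "needs_resolution")
    n_used <- ifelse(!is.na(conflict_at), conflict_at,
                     ifelse(consensus, policy$k, length_of))
  } else {
    run_start <- rec_start | v != c("", v[-n])
    run_first <- cummax(ifelse(run_start, idx, 0L))
    run_pos <- idx - run_first + 1L
    cand <- run_pos >= policy$k & ord <= policy$max_assessments
    hit <- idx[cand][!duplicated(events$record_id[idx[cand]])]
    final_n <- stats::setNames(ord[hit], events$record_id[hit])
    final_v <- stats::setNames(v[hit], events$record_id[hit])

    ids <- record_order
    length_of <- unname(rec_len[ids])
    length_of[is.na(length_of)] <- 0L
    n_at <- unname(final_n[ids])
    consensus <- !is.na(n_at)
    status <- ifelse(consensus, unname(final_v[ids]), "needs_resolution")
    n_used <- ifelse(consensus, n_at, pmin(length_of, policy$max_assessments))
  }

  tibble::tibble(
    record_id = record_order,
    status = status,
    reached_by_consensus = consensus,
    n_classifications = as.integer(n_used),
    resolver_verdict = NA_character_
  )
}

# --- user-facing aggregation -------------------------------------------

#' Aggregate one record's classification stream
#'
#' Scans the verdicts of a single record in ordinal order and finalises the
#' record at the first run of `k` identical verdicts, per the policy's
#' conflict mode (see [agreement_policy()]).
#'
#' @param events Classification events for exactly one record.
#' @param policy An [agreement_policy()].
#' @return A one-row tibble: `record_id`, `status` (one of
#'   `possibly_relevant`, `not_relevant`, `needs_resolution`),
#'   `reached_by_consensus`, `n_classifications` (events consumed), and
#'   `resolver_verdict` (always `NA` here; see [aggregate_task()]).
#' @examples
#' ev <- tibble::tibble(
#'   record_id = "r1", contributor_id = paste0("c", 1:3),
#'   ordinal = 1:3, verdict = rep("possibly_relevant", 3)
#' )
#' aggregate_stream(ev, agreement_policy(k = 3))
#' @export
aggregate_stream <- function(events, policy = agreement_policy()) {
  stopifnot(inherits(policy, "agreement_policy"))
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0L) {
    rlang::warn("Empty stream: record needs resolution with 0 classifications.")
    return(tibble::tibble(
      record_id = NA_character_, status = "needs_resolution",
      reached_by_consensus = FALSE, n_classifications = 0L,
      resolver_verdict = NA_character_
    ))
  }
  ids <- unique(events$record_id)
  if (length(ids) != 1L) {
    rlang::abort(
      sprintf("Malformed stream: expected one record_id, found %d.", length(ids)),
      class = "crowdscreen_stream_error"
    )
  }
  events <- validate_stream(events)
  scan_streams(events, policy, record_order = ids)
}

#' Aggregate a whole task's classification stream
#'
#' Partitions the stream by record and applies the consecutive-agreement
#' scan to each record. When `resolver_labels` is supplied, records that
#' needed resolution receive the resolver's final verdict; resolver labels
#' for records already finalised by consensus are ignored with a warning.
#'
#' @param events Classification events for any number of records.
#' @param policy An [agreement_policy()].
#' @param resolver_labels Optional data frame `record_id`, `verdict` mapping
#'   unresolved records to a resolver's final verdict.
#' @return A tibble of decisions, one row per distinct record, in order of
#'   first appearance in the stream. Columns as in [aggregate_stream()].
#' @examples
#' ev <- tibble::tibble(
#'   record_id = rep(c("r1", "r2"), c(3, 2)),
#'   contributor_id = c("a", "b", "c", "a", "b"),
#'   ordinal = c(1:3, 1:2),
#'   verdict = c(rep("possibly_relevant", 4), "not_relevant")
#' )
#' aggregate_task(ev, agreement_policy(conflict_mode = "strict_first_k"),
#'                resolver_labels = data.frame(record_id = "r2",
#'                                             verdict = "not_relevant"))
#' @export
aggregate_task <- function(events, policy = agreement_policy(),
                           resolver_labels = NULL) {
  stopifnot(inherits(policy, "agreement_policy"))
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0L) {
    return(tibble::tibble(
      record_id = character(), status = character(),
      reached_by_consensus = logical(), n_classifications = integer(),
      resolver_verdict = character()
    ))
  }
  record_order <- unique(events$record_id)
  sorted <- validate_stream(events)
  decisions <- scan_streams(sorted, policy, record_order)
  if (!is.null(resolver_labels)) {
    decisions <- apply_resolver(decisions, resolver_labels)
  }
  decisions
}

#' Apply resolver verdicts to unresolved decisions
#'
#' @param decisions A decision tibble from [aggregate_task()].
#' @param resolver_labels Data frame `record_id`, `verdict`.
#' @return The decisions with `resolver_verdict` filled in for records that
#'   needed resolution and appear in the map; other records are unchanged.
#' @export
apply_resolver <- function(decisions, resolver_labels) {
  resolver_labels <- tibble::as_tibble(resolver_labels)
  if (!all(c("record_id", "verdict") %in% names(resolver_labels))) {
    rlang::abort("`resolver_labels` needs columns record_id and verdict.",
                 class = "crowdscreen_stream_error")
  }
  check_verdicts(resolver_labels$verdict, "resolver verdict")
  hit <- match(decisions$record_id, resolver_labels$record_id)
  targeted <- !is.na(hit)
  on_consensus <- targeted & decisions$reached_by_consensus
  if (any(on_consensus)) {
    rlang::warn(sprintf(
      "Resolver label(s) for record(s) already finalised by consensus ignored: %s.",
      paste(utils::head(decisions$record_id[on_consensus], 5L), collapse = ", ")
    ))
  }
  use <- targeted & !decisions$reached_by_consensus
  decisions$resolver_verdict[use] <- resolver_labels$verdict[hit[use]]
  decisions
}

#' Re-aggregate a recorded stream under a different policy
#'
#' Replays full recorded classification histories under an alternative
#' policy (for example a streak of 2 instead of 3) without regenerating any
#' classifications, so the effect of the streak length can be compared on
#' fixed data.
#'
#' @inheritParams aggregate_task
#' @return A decision tibble as from [aggregate_task()].
#' @export
replay_with_policy <- function(events, policy) {
  aggregate_task(events, policy)
}

#' Final verdict of each decision
#'
#' The collective status for records finalised by consensus, or the
#' resolver's verdict otherwise; `NA` for records still unresolved.
#'
#' @param decisions A decision tibble.
#' @return Character vector of `possibly_relevant` / `not_relevant` / `NA`.
#' @export
final_verdict <- function(decisions) {
  ifelse(decisions$status != "needs_resolution",
         decisions$status, decisions$resolver_verdict)
}
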