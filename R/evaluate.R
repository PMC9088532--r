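# --- rounding -----------------------------------------------------------

#' Round half-up
#'
#' Commercial (half-up) rounding, as used for reported percentages: exact
#' halves round away from zero, so 96.875 prints as 96.9. Base R's
#' [round()] rounds halves to even and would print 96.8.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# --- confusion counting -------------------------------------------------

#' Confusion counts of collective decisions against a reference standard
#'
#' Cross-tabulates each record's final collective verdict (consensus or
#' resolver) against the reference standard. A true positive is a record
#' correctly classified as possibly relevant; a false negative is a truly
#' relevant record the crowd rejected. Records whose reference label is
#' `"unknown"` are excluded from counting.
#'
#' @param decisions Decision tibble (see [aggregate_task()]); every decision
#'   must carry a final verdict (consensus or resolver).
#' @param reference Data frame `record_id`, `reference_label` with values
#'   `relevant` / `not_relevant` / `unknown`.
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @export
crowd_confusion <- function(decisions, reference) {
  reference <- tibble::as_tibble(reference)
  if (!all(c("record_id", "reference_label") %in% names(reference))) {
    rlang::abort("`reference` needs columns record_id and reference_label.",
                 class = "crowdscreen_reference_error")
  }
  bad <- setdiff(unique(reference$reference_label), reference_levels())
  if (length(bad)) {
    rlang::abort(sprintf("Invalid reference label(s): %s.",
                         paste(sQuote(bad), collapse = ", ")),
                 class = "crowdscreen_reference_error")
  }
  fv <- final_verdict(decisions)
  if (anyNA(fv)) {
    rlang::abort(
      sprintf("Unresolved record(s) present: %s. Supply resolver labels before scoring.",
              paste(utils::head(decisions$record_id[is.na(fv)], 5L), collapse = ", ")),
      class = "crowdscreen_unresolved_error"
    )
  }
  lab <- reference$reference_label[match(decisions$record_id, reference$record_id)]
  if (anyNA(lab)) {
    rlang::abort(
      sprintf("Missing reference label for record(s): %s.",
              paste(utils::head(decisions$record_id[is.na(lab)], 5L), collapse = ", ")),
      class = "crowdscreen_reference_error"
    )
  }
  keep <- lab != "unknown"
  fv <- fv[keep]
  lab <- lab[keep]
  tibble::tibble(
    tp = sum(fv == "possibly_relevant" & lab == "relevant"),
    tn = sum(fv == "not_relevant" & lab == "not_relevant"),
    fp = sum(fv == "possibly_relevant" & lab == "not_relevant"),
    fn = sum(fv == "not_relevant" & lab == "relevant")
  )
}

as_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- as.list(counts)
  counts <- counts[c("tp", "tn", "fp", "fn")]
  if (anyNA(names(counts)) || any(!vapply(counts, is.numeric, logical(1)))) {
    rlang::abort("Counts must provide numeric tp, tn, fp, fn.",
                 class = "crowdscreen_metric_error")
  }
  counts
}

maybe_round <- function(x, digits) {
  if (is.null(digits)) x else round_half_up(x, digits)
}

#' Crowd sensitivity
#'
#' Proportion (in percent) of truly relevant records the crowd collectively
#' flagged as possibly relevant: `100 * tp / (tp + fn)`.
#'
#' @param counts Confusion counts: a one-row data frame or named list with
#'   `tp`, `tn`, `fp`, `fn` (see [crowd_confusion()]).
#' @param digits Decimal places for half-up rounding (default 1, the
#'   reporting convention); `NULL` returns the unrounded value.
#' @return Percentage in \[0, 100\].
#' @examples
#' sensitivity_pct(list(tp = 45, tn = 3942, fp = 1617, fn = 2))  # 95.7
#' @export
sensitivity_pct <- function(counts, digits = 1) {
  counts <- as_counts(counts)
  denom <- counts$tp + counts$fn
  if (denom == 0) {
    rlang::abort("Sensitivity undefined: no relevant records (tp + fn = 0).",
                 class = "crowdscreen_metric_error")
  }
  maybe_round(100 * counts$tp / denom, digits)
}

#' Crowd specificity
#'
#' Proportion (in percent) of truly non-relevant records the crowd
#' collectively rejected: `100 * tn / (tn + fp)`.
#'
#' @inheritParams sensitivity_pct
#' @return Percentage in \[0, 100\].
#' @examples
#' specificity_pct(list(tp = 45, tn = 3942, fp = 1617, fn = 2))  # 70.9
#' @export
specificity_pct <- function(counts, digits = 1) {
  counts <- as_counts(counts)
  denom <- counts$tn + counts$fp
  if (denom == 0) {
    rlang::abort("Specificity undefined: no non-relevant records (tn + fp = 0).",
                 class = "crowdscreen_metric_error")
  }
  maybe_round(100 * counts$tn / denom, digits)
}

#' Crowd consensus
#'
#' Proportion (in percent) of records finalised without arbitration, i.e.
#' by a run of agreeing classifications alone. Resolver-finalised records
#' never count toward consensus.
#'
#' @param decisions Decision tibble.
#' @param digits Decimal places for half-up rounding (default 2, the
#'   reporting convention); `NULL` returns the unrounded value.
#' @return Percentage in \[0, 100\].
#' @export
consensus_pct <- function(decisions, digits = 2) {
  if (nrow(decisions) == 0L) {
    rlang::abort("Consensus undefined for an empty decision list.",
                 class = "crowdscreen_metric_error")
  }
  maybe_round(100 * mean(decisions$reached_by_consensus), digits)
}

#' Consensus within a subgroup of records
#'
#' [consensus_pct()] restricted to the records selected by a predicate on
#' the record table -- e.g. the truly relevant records, or the title-only
#' records. Consensus is typically lower in both subgroups: relevant
#' records and abstract-less records attract more disagreement.
#'
#' @param decisions Decision tibble.
#' @param records Record table containing `record_id` plus whatever columns
#'   the predicate uses (e.g. `reference_label`, `title_only`).
#' @param predicate Unquoted filter expression evaluated in `records`, e.g.
#'   `reference_label == "relevant"` or `title_only`.
#' @inheritParams consensus_pct
#' @return Percentage in \[0, 100\].
#' @examples
#' \dontrun{
#' subgroup_consensus(decisions, corpus, reference_label == "relevant")
#' subgroup_consensus(decisions, corpus, title_only)
#' }
#' @export
subgroup_consensus <- function(decisions, records, predicate, digits = 2) {
  records <- tibble::as_tibble(records)
  keep <- rlang::eval_tidy(rlang::enquo(predicate), data = records)
  ids <- records$record_id[keep %in% TRUE]
  sub <- decisions[decisions$record_id %in% ids, , drop = FALSE]
  if (nrow(sub) == 0L) {
    rlang::abort("Subgroup consensus undefined: predicate selects no decided records.",
                 class = "crowdscreen_metric_error")
  }
  consensus_pct(sub, digits = digits)
}

#' Report the relevant records the crowd rejected
#'
#' Returns the false-negative records -- truly relevant studies the crowd's
#' final collective verdict rejected -- joined to their titles for
#' human-readable reporting.
#'
#' @inheritParams crowd_confusion
#' @param records Record table with `record_id` and `title` (and any other
#'   descriptive columns to carry along).
#' @return Tibble of missed records (possibly empty).
#' @export
missed_study_report <- function(decisions, reference, records) {
  reference <- tibble::as_tibble(reference)
  fv <- final_verdict(decisions)
  if (anyNA(fv)) {
    rlang::abort(
      sprintf("Unresolved record(s) present: %s.",
              paste(utils::head(decisions$record_id[is.na(fv)], 5L), collapse = ", ")),
      class = "crowdscreen_unresolved_error"
    )
  }
  lab <- reference$reference_label[match(decisions$record_id, reference$record_id)]
  missed <- decisions$record_id[!is.na(lab) & lab == "relevant" & fv == "not_relevant"]
  out <- tibble::tibble(record_id = missed)
  dplyr::left_join(out, tibble::as_tibble(records), by = "record_id")
}

#' Pooled miss rate across several screening tasks
#'
#' Total false negatives over total truly relevant records, in percent:
#' `100 * sum(fn) / sum(tp + fn)`.
#'
#' @param reports A data frame with columns `tp` and `fn` (one row per
#'   task), or a list of [crowd_performance()] objects.
#' @inheritParams sensitivity_pct
#' @return Percentage in \[0, 100\].
#' @examples
#' pooled_miss_rate_pct(data.frame(tp = c(45, 31, 17, 12), fn = c(2, 1, 1, 0)))
#' @export
pooled_miss_rate_pct <- function(reports, digits = 1) {
  if (is.data.frame(reports)) {
    tab <- tibble::as_tibble(reports)
  } else if (is.list(reports) && all(vapply(reports, inherits, logical(1), "crowd_performance"))) {
    tab <- dplyr::bind_rows(lapply(reports, function(r) r$counts))
  } else {
    rlang::abort("`reports` must be a data frame with tp/fn or a list of crowd_performance objects.",
                 class = "crowdscreen_metric_error")
  }
  if (!all(c("tp", "fn") %in% names(tab))) {
    rlang::abort("`reports` needs columns tp and fn.", class = "crowdscreen_metric_error")
  }
  denom <- sum(tab$tp) + sum(tab$fn)
  if (denom == 0) {
    rlang::abort("Pooled miss rate undefined: no relevant records.",
                 class = "crowdscreen_metric_error")
  }
  maybe_round(100 * sum(tab$fn) / denom, digits)
}

#' Forward citation recovery of missed studies
#'
#' Which of the records the crowd missed would have been recovered by
#' forward citation tracking: a missed record is recoverable if at least
#' one correctly included record cites it.
#'
#' @param missed_ids Identifiers of the false-negative records.
#' @param included_ids Identifiers of the correctly included (true
#'   positive) records.
#' @param citation_edges Data frame `citing_id`, `cited_id`.
#' @return Character vector: the subset of `missed_ids` cited by at least
#'   one included record.
#' @export
citation_recovery <- function(missed_ids, included_ids, citation_edges) {
  citation_edges <- tibble::as_tibble(citation_edges)
  if (nrow(citation_edges) == 0L) {
    return(character())
  }
  if (!all(c("citing_id", "cited_id") %in% names(citation_edges))) {
    rlang::abort("`citation_edges` needs columns citing_id and cited_id.",
                 class = "crowdscreen_reference_error")
  }
  known <- union(missed_ids, included_ids)
  stray <- !(citation_edges$citing_id %in% known) & !(citation_edges$cited_id %in% known)
  if (any(stray)) {
    rlang::warn(sprintf("%d citation edge(s) reference unknown record ids; ignored.",
                        sum(stray)))
  }
  hits <- citation_edges$cited_id[citation_edges$citing_id %in% included_ids]
  intersect(missed_ids, hits)
}

# --- the full performance report ---------------------------------------

#' Score a screening task against its reference standard
#'
#' Computes the full accuracy and consensus report for one screening task:
#' confusion counts, sensitivity, specificity, overall consensus, consensus
#' among the truly relevant (included) records, consensus among title-only
#' records, and the identities of missed studies. Percentages are stored
#' unrounded; rounding is applied at presentation ([tidy()], [print()]).
#'
#' @param decisions Decision tibble with final verdicts for every record.
#' @param reference Reference standard (`record_id`, `reference_label`).
#' @param records Optional record table (`record_id`, `title`,
#'   `title_only`); enables the title-only subgroup and titled miss report.
#' @return An object of class `crowd_performance`.
#' @export
crowd_performance <- function(decisions, reference, records = NULL) {
  counts <- crowd_confusion(decisions, reference)
  reference <- tibble::as_tibble(reference)
  rel_ids <- reference$record_id[reference$reference_label == "relevant"]
  included_consensus <- if (any(decisions$record_id %in% rel_ids)) {
    sub <- decisions[decisions$record_id %in% rel_ids, , drop = FALSE]
    consensus_pct(sub, digits = NULL)
  } else {
    NA_real_
  }
  title_only_consensus <- NA_real_
  missed <- tibble::tibble(record_id = character())
  if (!is.null(records)) {
    records <- tibble::as_tibble(records)
    if ("title_only" %in% names(records) && any(records$title_only)) {
      to_ids <- records$record_id[records$title_only]
      if (any(decisions$record_id %in% to_ids)) {
        sub <- decisions[decisions$record_id %in% to_ids, , drop = FALSE]
        title_only_consensus <- consensus_pct(sub, digits = NULL)
      }
    }
    missed <- missed_study_report(decisions, reference, records)
  } else {
    fv <- final_verdict(decisions)
    lab <- reference$reference_label[match(decisions$record_id, reference$record_id)]
    missed <- tibble::tibble(
      record_id = decisions$record_id[!is.na(lab) & lab == "relevant" & fv == "not_relevant"]
    )
  }
  structure(
    list(
      counts = counts,
      n_records = nrow(decisions),
      sensitivity_pct = sensitivity_pct(counts, digits = NULL),
      specificity_pct = specificity_pct(counts, digits = NULL),
      consensus_pct = consensus_pct(decisions, digits = NULL),
      included_consensus_pct = included_consensus,
      title_only_consensus_pct = title_only_consensus,
      missed = missed
    ),
    class = "crowd_performance"
  )
}

#' @export
print.crowd_performance <- function(x, ...) {
  cat("<crowd_performance> on", x$n_records, "records\n")
  with(x$counts, cat(sprintf("  TP %d  TN %d  FP %d  FN %d\n", tp, tn, fp, fn)))
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  consensus %.2f%%\n",
              round_half_up(x$sensitivity_pct, 1),
              round_half_up(x$specificity_pct, 1),
              round_half_up(x$consensus_pct, 2)))
  if (!is.na(x$included_consensus_pct)) {
    cat(sprintf("  consensus among relevant records: %.2f%%\n",
                round_half_up(x$included_consensus_pct, 2)))
  }
  if (!is.na(x$title_only_consensus_pct)) {
    cat(sprintf("  consensus among title-only records: %.2f%%\n",
                round_half_up(x$title_only_consensus_pct, 2)))
  }
  if (nrow(x$missed)) {
    cat("  missed relevant record(s):",
        paste(x$missed$record_id, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a crowd performance report
#'
#' @param x A [crowd_performance()] object.
#' @param ... Unused.
#' @return A tibble with one row per metric: `metric`, `value` (rounded at
#'   the reporting convention: 1 decimal for accuracy, 2 for consensus).
#' @method tidy crowd_performance
#' @export
tidy.crowd_performance <- function(x, ...) {
  tibble::tibble(
    metric = c("sensitivity_pct", "specificity_pct", "consensus_pct",
               "included_consensus_pct", "title_only_consensus_pct"),
    value = c(round_half_up(x$sensitivity_pct, 1),
              round_half_up(x$specificity_pct, 1),
              round_half_up(x$consensus_pct, 2),
              round_half_up(x$included_consensus_pct, 2),
              round_half_up(x$title_only_consensus_pct, 2))
  )
}

#' One-row summary of a crowd performance report
#'
#' @param x A [crowd_performance()] object.
#' @param ... Unused.
#' @return A one-row tibble with counts and unrounded percentages.
#' @method glance crowd_performance
#' @export
glance.crowd_performance <- function(x, ...) {
  tibble::tibble(
    n_records = x$n_records,
    tp = x$counts$tp, tn = x$counts$tn, fp = x$counts$fp, fn = x$counts$fn,
    sensitivity_pct = x$sensitivity_pct,
    specificity_pct = x$specificity_pct,
    consensus_pct = x$consensus_pct,
    included_consensus_pct = x$included_consensus_pct,
    title_only_consensus_pct = x$title_only_consensus_pct,
    n_missed = nrow(x$missed)
  )
}

#' Plot a crowd performance report
#'
#' Bar chart of the report's percentage metrics.
#'
#' @param object A [crowd_performance()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export autoplot
#' @method autoplot crowd_performance
#' @export
autoplot.crowd_performance <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$value), , drop = FALSE]
  d$metric <- factor(d$metric, levels = rev(d$metric))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$metric)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$value)),
                       hjust = -0.15, size = 3) +
    ggplot2::xlim(0, 105) +
    ggplot2::labs(x = "percent", y = NULL,
                  title = "Crowd screening performance") +
    ggplot2::theme_minimal()
}
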