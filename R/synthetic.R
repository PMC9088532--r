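# Synthetic crowds: corpora with planted labels, contributor pools with
# per-classification accuracies, qualification gating, and an event-driven
# screening loop under a deadline.

local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    withr::defer(assign(".Random.seed", old, envir = globalenv()), envir = env)
  } else {
    withr::defer(suppressWarnings(rm(".Random.seed", envir = globalenv())), envir = env)
  }
  set.seed(seed)
  invisible(NULL)
}

#' Generate a synthetic screening corpus
#'
#' Builds a record set with a planted reference standard: exactly
#' `round(n_records * prevalence)` records are truly relevant and exactly
#' `round(n_records * title_only_fraction)` lack an abstract, with positions
#' shuffled by the seed. Counts are fixed by rounding rather than drawn, so
#' a corpus is exactly reproducible from its spec. Titles and abstracts are
#' synthetic placeholder text.
#'
#' @param n_records Number of records (the search-result set size).
#' @param prevalence Fraction of records that are truly relevant. Screening
#'   corpora typically sit at 0.5--2\%.
#' @param title_only_fraction Fraction of records lacking an abstract
#'   (default 0.065, typical of bibliographic search exports).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble: `record_id`, `title`, `abstract` (`NA` for title-only
#'   records), `title_only`, `reference_label`.
#' @examples
#' corpus <- generate_corpus(948, prevalence = 12 / 948, seed = 1)
#' sum(corpus$reference_label == "relevant")  # 12
#' @export
generate_corpus <- function(n_records, prevalence,
                            title_only_fraction = 0.065, seed = NULL) {
  stopifnot(n_records >= 1, prevalence >= 0, prevalence <= 1,
            title_only_fraction >= 0, title_only_fraction <= 1)
  local_seed(seed)
  n_rel <- as.integer(round_half_up(n_records * prevalence))
  n_to <- as.integer(round_half_up(n_records * title_only_fraction))
  if (prevalence > 0 && n_rel == 0L) {
    rlang::warn("prevalence * n_records < 0.5: corpus contains no relevant records.")
  }
  label <- rep(c("relevant", "not_relevant"), c(n_rel, n_records - n_rel))
  label <- label[sample.int(n_records)]
  title_only <- rep(c(TRUE, FALSE), c(n_to, n_records - n_to))
  title_only <- title_only[sample.int(n_records)]
  ids <- sprintf("rec%05d", seq_len(n_records))
  tibble::tibble(
    record_id = ids,
    title = paste("Synthetic citation", seq_len(n_records)),
    abstract = ifelse(title_only, NA_character_,
                      paste("Synthetic abstract for citation", seq_len(n_records))),
    title_only = title_only,
    reference_label = label
  )
}

#' Qualification test specification
#'
#' A practice assessment gating access to the live task: `n_items` practice
#' records, passed with a score of at least `pass_fraction`.
#'
#' @param n_items Number of practice records (default 16).
#' @param pass_fraction Minimum passing score as a fraction (default 0.80).
#' @return An object of class `qualification_spec`.
#' @export
qualification_spec <- function(n_items = 16, pass_fraction = 0.80) {
  stopifnot(n_items >= 1, pass_fraction > 0, pass_fraction <= 1)
  structure(list(n_items = as.integer(n_items),
                 pass_fraction = pass_fraction),
            class = "qualification_spec")
}

#' Simulate the qualification test for a pool of contributors
#'
#' Each contributor answers `n_items` independent practice records (half
#' truly relevant, rounding up, half not) with per-item accuracy equal to
#' the mean of their sensitivity and specificity, and passes if the number
#' correct reaches `ceiling(pass_fraction * n_items)`. The pass probability
#' is therefore an upper binomial tail in the contributor's mean accuracy.
#'
#' @param profiles Data frame with columns `sens` and `spec` (one row per
#'   contributor).
#' @param qualification A [qualification_spec()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Logical vector: pass / fail per contributor.
#' @export
run_qualification <- function(profiles, qualification = qualification_spec(),
                              seed = NULL) {
  profiles <- tibble::as_tibble(profiles)
  stopifnot(all(c("sens", "spec") %in% names(profiles)))
  local_seed(seed)
  acc <- (profiles$sens + profiles$spec) / 2
  pass_mark <- ceiling(qualification$pass_fraction * qualification$n_items)
  correct <- stats::rbinom(nrow(profiles), qualification$n_items, acc)
  correct >= pass_mark
}

#' Simulate a contributor pool
#'
#' Draws per-classification sensitivities and specificities from bell-shaped
#' (normal) distributions truncated to \[0, 1\] by rejection sampling, applies
#' an absolute accuracy penalty for title-only (abstract-less) records, and
#' gates each contributor through the qualification test.
#'
#' @param n Pool size (candidates invited to qualify).
#' @param sens_mean,spec_mean Mean per-classification sensitivity and
#'   specificity. Individual screeners typically sit near 0.85.
#' @param spread Standard deviation of both accuracy distributions
#'   (absolute, default 0.05).
#' @param rate_per_hour Classifications produced per active hour
#'   (default 20, about one title-abstract assessment every three minutes).
#' @param title_only_penalty Absolute accuracy drop on records without an
#'   abstract (default 0.05).
#' @param qualification A [qualification_spec()]; set `NULL` to mark all
#'   contributors qualified.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble: `contributor_id`, `sens`, `spec`, `title_only_sens`,
#'   `title_only_spec`, `rate_per_hour`, `qualified`.
#' @export
simulate_contributors <- function(n, sens_mean = 0.85, spec_mean = 0.85,
                                  spread = 0.05, rate_per_hour = 20,
                                  title_only_penalty = 0.05,
                                  qualification = qualification_spec(),
                                  seed = NULL) {
  stopifnot(n >= 1, spread >= 0, rate_per_hour > 0)
  local_seed(seed)
  rtruncnorm01 <- function(n, mean, sd) {
    if (sd == 0) return(rep(pmin(pmax(mean, 0), 1), n))
    x <- stats::rnorm(n, mean, sd)
    bad <- x < 0 | x > 1
    while (any(bad)) {
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
      bad <- x < 0 | x > 1
    }
    x
  }
  sens <- rtruncnorm01(n, sens_mean, spread)
  spec <- rtruncnorm01(n, spec_mean, spread)
  profiles <- tibble::tibble(
    contributor_id = sprintf("c%03d", seq_len(n)),
    sens = sens,
    spec = spec,
    title_only_sens = pmax(sens - title_only_penalty, 0),
    title_only_spec = pmax(spec - title_only_penalty, 0),
    rate_per_hour = rep_len(rate_per_hour, n)
  )
  profiles$qualified <- if (is.null(qualification)) {
    rep(TRUE, n)
  } else {
    run_qualification(profiles, qualification)
  }
  profiles
}

#' One contributor's verdicts on a set of records
#'
#' Models a single classification as a Bernoulli draw: a relevant record is
#' flagged possibly relevant with probability `sens` (`title_only_sens` when
#' the record has no abstract), and a non-relevant record is rejected with
#' probability `spec` (`title_only_spec` likewise).
#'
#' @param profile One contributor row (see [simulate_contributors()]); must
#'   be qualified.
#' @param records Record tibble (see [generate_corpus()]).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Character vector of verdicts, one per record.
#' @export
classify_records <- function(profile, records, seed = NULL) {
  profile <- tibble::as_tibble(profile)
  stopifnot(nrow(profile) == 1L)
  if (!isTRUE(profile$qualified)) {
    rlang::abort("Contributor has not passed the qualification test.",
                 class = "crowdscreen_gating_error")
  }
  local_seed(seed)
  records <- tibble::as_tibble(records)
  to <- if ("title_only" %in% names(records)) records$title_only else FALSE
  p_correct <- ifelse(
    records$reference_label == "relevant",
    ifelse(to, profile$title_only_sens, profile$sens),
    ifelse(to, profile$title_only_spec, profile$spec)
  )
  correct <- stats::runif(nrow(records)) < p_correct
  ifelse(records$reference_label == "relevant",
         ifelse(correct, "possibly_relevant", "not_relevant"),
         ifelse(correct, "not_relevant", "possibly_relevant"))
}

#' Simulate a full crowd screening task
#'
#' Event-driven simulation of a screening task under a deadline. Each
#' qualified contributor produces classifications as a Poisson process at
#' their `rate_per_hour`; at each classification the scheduler serves the
#' contributor a record chosen uniformly at random among records that are
#' not yet finalised and that the contributor has not yet classified (a
#' contributor never sees the same record twice). Records finalise per the
#' agreement policy as their streams grow; a record whose pool is exhausted
#' (every contributor has classified it) without a streak is routed to
#' resolution early, provided consensus was possible at all (pool size at
#' least `k`). The task completes when every record is finalised or the
#' deadline passes.
#'
#' @param corpus Record tibble from [generate_corpus()].
#' @param contributors Contributor tibble from [simulate_contributors()];
#'   only qualified contributors take part.
#' @param policy An [agreement_policy()].
#' @param deadline_hours Task deadline; defaults to the policy's.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An object of class `crowd_simulation`: a list with `stream`
#'   (the full recorded classification events, for replay), `decisions`
#'   (per-record outcomes; unfinalised records are `needs_resolution`),
#'   `completion_hours` (`NA` if the deadline passed first),
#'   `n_unfinalised`, `deadline_hours`, `policy`.
#' @export
simulate_task <- function(corpus, contributors, policy = agreement_policy(),
                          deadline_hours = policy$deadline_hours, seed = NULL) {
  stopifnot(inherits(policy, "agreement_policy"))
  corpus <- tibble::as_tibble(corpus)
  contributors <- tibble::as_tibble(contributors)
  local_seed(seed)
  active <- contributors[contributors$qualified, , drop = FALSE]
  n_rec <- nrow(corpus)
  n_con <- nrow(active)
  if (n_con < policy$k) {
    rlang::warn(sprintf(
      "Only %d qualified contributor(s) but k = %d distinct verdicts are needed; no record can be finalised by consensus.",
      n_con, policy$k))
  }

  strict <- policy$conflict_mode == "strict_first_k"
  is_rel <- corpus$reference_label == "relevant"
  to <- if ("title_only" %in% names(corpus)) corpus$title_only else rep(FALSE, n_rec)
  # per-record aggregation state
  n_seen <- integer(n_rec)          # classifications consumed
  run_len <- integer(n_rec)         # current streak length (streak_continue)
  last_v <- character(n_rec)        # last verdict / first verdict (strict)
  finalised <- rep(FALSE, n_rec)
  status <- rep("needs_resolution", n_rec)
  consensus <- rep(FALSE, n_rec)
  seen <- matrix(FALSE, nrow = max(n_con, 1L), ncol = n_rec)

  cap <- n_rec * policy$max_assessments + 16L
  ev_rec <- integer(cap); ev_con <- character(cap)
  ev_ord <- integer(cap); ev_verd <- character(cap); ev_t <- numeric(cap)
  n_ev <- 0L

  completion <- NA_real_
  if (n_con > 0L && n_rec > 0L) {
    next_t <- stats::rexp(n_con, rate = active$rate_per_hour)
    n_final <- 0L
    repeat {
      ci <- which.min(next_t)
      t_now <- next_t[ci]
      if (!is.finite(t_now) || t_now > deadline_hours) break
      eligible <- which(!finalised & !seen[ci, ])
      if (!length(eligible)) {
        next_t[ci] <- Inf
        next
      }
      ri <- if (length(eligible) == 1L) eligible else
        eligible[sample.int(length(eligible), 1L)]
      # draw the verdict
      p_correct <- if (is_rel[ri]) {
        if (to[ri]) active$title_only_sens[ci] else active$sens[ci]
      } else {
        if (to[ri]) active$title_only_spec[ci] else active$spec[ci]
      }
      correct <- stats::runif(1) < p_correct
      v <- if (is_rel[ri]) {
        if (correct) "possibly_relevant" else "not_relevant"
      } else {
        if (correct) "not_relevant" else "possibly_relevant"
      }
      seen[ci, ri] <- TRUE
      n_seen[ri] <- n_seen[ri] + 1L
      n_ev <- n_ev + 1L
      ev_rec[n_ev] <- ri; ev_con[n_ev] <- active$contributor_id[ci]
      ev_ord[n_ev] <- n_seen[ri]; ev_verd[n_ev] <- v; ev_t[n_ev] <- t_now

      if (strict) {
        if (n_seen[ri] == 1L) {
          last_v[ri] <- v
          if (policy$k == 1L) {
            finalised[ri] <- TRUE; status[ri] <- v; consensus[ri] <- TRUE
          }
        } else if (v != last_v[ri]) {
          finalised[ri] <- TRUE       # conflict: straight to resolution
        } else if (n_seen[ri] == policy$k) {
          finalised[ri] <- TRUE; status[ri] <- v; consensus[ri] <- TRUE
        }
      } else {
        run_len[ri] <- if (n_seen[ri] > 1L && v == last_v[ri]) run_len[ri] + 1L else 1L
        last_v[ri] <- v
        if (run_len[ri] >= policy$k) {
          finalised[ri] <- TRUE; status[ri] <- v; consensus[ri] <- TRUE
        } else if (n_seen[ri] >= policy$max_assessments) {
          finalised[ri] <- TRUE
        }
      }
      # pool exhausted for this record: nobody left to extend the stream
      if (!finalised[ri] && n_con >= policy$k && n_seen[ri] >= n_con) {
        finalised[ri] <- TRUE
      }
      if (finalised[ri]) {
        n_final <- n_final + 1L
        if (n_final == n_rec) {
          completion <- t_now
          break
        }
      }
      next_t[ci] <- t_now + stats::rexp(1, rate = active$rate_per_hour[ci])
    }
  }

  keep <- seq_len(n_ev)
  stream <- tibble::tibble(
    record_id = corpus$record_id[ev_rec[keep]],
    contributor_id = ev_con[keep],
    ordinal = ev_ord[keep],
    verdict = ev_verd[keep],
    timestamp_hours = ev_t[keep]
  )
  decisions <- tibble::tibble(
    record_id = corpus$record_id,
    status = status,
    reached_by_consensus = consensus,
    n_classifications = n_seen,
    resolver_verdict = NA_character_
  )
  structure(
    list(
      stream = stream,
      decisions = decisions,
      completion_hours = completion,
      n_unfinalised = sum(!finalised),
      deadline_hours = deadline_hours,
      policy = policy
    ),
    class = "crowd_simulation"
  )
}

#' @export
print.crowd_simulation <- function(x, ...) {
  cat("<crowd_simulation>", nrow(x$decisions), "records,",
      nrow(x$stream), "classifications\n")
  if (is.na(x$completion_hours)) {
    cat(sprintf("  INCOMPLETE at %.1f h deadline: %d record(s) unfinalised\n",
                x$deadline_hours, x$n_unfinalised))
  } else {
    cat(sprintf("  completed in %.2f h (deadline %.1f h)\n",
                x$completion_hours, x$deadline_hours))
  }
  invisible(x)
}

#' One-row summary of a simulated screening task
#'
#' @param x A `crowd_simulation` from [simulate_task()].
#' @param ... Unused.
#' @return A one-row tibble: record and event counts, consensus rate,
#'   completion time (`NA` if incomplete) and unfinalised count.
#' @method glance crowd_simulation
#' @export
glance.crowd_simulation <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x$decisions),
    n_classifications = nrow(x$stream),
    consensus_pct = if (nrow(x$decisions)) consensus_pct(x$decisions, digits = NULL) else NA_real_,
    completion_hours = x$completion_hours,
    n_unfinalised = x$n_unfinalised,
    deadline_hours = x$deadline_hours
  )
}

#' Strict-mode operating point under independent classifications
#'
#' Closed forms for the strict conflict mode, where a record is finalised
#' by consensus only if its first `k` classifications agree. With
#' independent per-classification accuracies: a relevant record reaches
#' consensus with probability `sens^k + (1 - sens)^k` (all agree, either
#' way), is collectively flagged possibly relevant with probability
#' `sens^k`, and symmetrically for non-relevant records; the marginal
#' consensus probability mixes the two by prevalence. Consensus declines in
#' `k` -- longer streaks are harder to assemble -- which is how raising `k`
#' trades resolution workload for collective accuracy.
#'
#' @param sens,spec Per-classification sensitivity and specificity.
#' @param prevalence Fraction of records truly relevant.
#' @param k Streak length.
#' @return A tibble (vectorised over the inputs): `sens`, `spec`,
#'   `prevalence`, `k`, `p_consensus_relevant`, `p_consensus_not_relevant`,
#'   `p_consensus`, `p_collective_P_given_relevant`,
#'   `p_collective_N_given_not`.
#' @examples
#' strict_mode_operating_point(sens = 0.85, spec = 0.85,
#'                             prevalence = 0.01, k = 3)
#' @export
strict_mode_operating_point <- function(sens, spec, prevalence, k) {
  stopifnot(all(sens >= 0 & sens <= 1), all(spec >= 0 & spec <= 1),
            all(prevalence >= 0 & prevalence <= 1), all(k >= 1))
  d <- tibble::tibble(sens = sens, spec = spec, prevalence = prevalence, k = k)
  d$p_consensus_relevant <- d$sens^d$k + (1 - d$sens)^d$k
  d$p_consensus_not_relevant <- d$spec^d$k + (1 - d$spec)^d$k
  d$p_consensus <- d$prevalence * d$p_consensus_relevant +
    (1 - d$prevalence) * d$p_consensus_not_relevant
  d$p_collective_P_given_relevant <- d$sens^d$k
  d$p_collective_N_given_not <- d$spec^d$k
  d
}

#' Estimate contributor accuracies from a recorded stream
#'
#' Recovers each contributor's per-classification sensitivity and
#' specificity as the fraction of their verdicts that match the planted
#' reference labels, split by record class. Useful for checking that a
#' simulated stream carries the accuracy structure it was generated with,
#' and for profiling real streams against a resolved reference.
#'
#' @param stream Classification events.
#' @param records Record tibble with `record_id` and `reference_label`.
#' @return A tibble per contributor: `contributor_id`, `n_classifications`,
#'   `n_relevant`, `sens_hat`, `n_not_relevant`, `spec_hat`.
#' @export
estimate_contributor_accuracy <- function(stream, records) {
  stream <- tibble::as_tibble(stream)
  records <- tibble::as_tibble(records)
  d <- dplyr::left_join(stream,
                        records[, c("record_id", "reference_label")],
                        by = "record_id")
  if (anyNA(d$reference_label)) {
    rlang::abort("Stream contains record ids absent from `records`.",
                 class = "crowdscreen_reference_error")
  }
  d |>
    dplyr::group_by(.data$contributor_id) |>
    dplyr::summarise(
      n_classifications = dplyr::n(),
      n_relevant = sum(.data$reference_label == "relevant"),
      sens_hat = ifelse(n_relevant > 0,
                        sum(.data$verdict == "possibly_relevant" &
                              .data$reference_label == "relevant") / n_relevant,
                        NA_real_),
      n_not_relevant = sum(.data$reference_label == "not_relevant"),
      spec_hat = ifelse(n_not_relevant > 0,
                        sum(.data$verdict == "not_relevant" &
                              .data$reference_label == "not_relevant") / n_not_relevant,
                        NA_real_),
      .groups = "drop"
    )
}
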