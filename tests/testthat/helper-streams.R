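# Fixture builders and an independent brute-force oracle for the
# consecutive-agreement scan.

P <- "possibly_relevant"
N <- "not_relevant"

# Build a stream tibble from a named list of verdict vectors (one entry per
# record). Contributors are distinct within each record.
make_stream <- function(verdicts, ids = NULL) {
  if (!is.list(verdicts)) verdicts <- list(verdicts)
  if (is.null(ids)) ids <- names(verdicts) %||% paste0("r", seq_along(verdicts))
  dplyr::bind_rows(lapply(seq_along(verdicts), function(i) {
    v <- verdicts[[i]]
    tibble::tibble(
      record_id = ids[[i]],
      contributor_id = paste0("c", seq_along(v)),
      ordinal = seq_along(v),
      verdict = v
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracle: tests every window of length k for a run, instead of
# scanning run lengths. Returns (status, consensus, n consumed).
brute_decide <- function(v, k, mode = "streak_continue", max_a = 2 * k + 1) {
  n <- length(v)
  if (n == 0L) {
    return(list(status = "needs_resolution", consensus = FALSE, n = 0L))
  }
  if (mode == "strict_first_k") {
    lim <- min(n, k)
    if (lim >= 2) {
      for (j in 2:lim) {
        if (v[j] != v[1]) {
          return(list(status = "needs_resolution", consensus = FALSE, n = j))
        }
      }
    }
    if (n >= k) return(list(status = v[1], consensus = TRUE, n = k))
    return(list(status = "needs_resolution", consensus = FALSE, n = n))
  }
  m <- min(n, max_a)
  if (m >= k) {
    for (i in seq_len(m - k + 1)) {
      w <- v[i:(i + k - 1)]
      if (length(unique(w)) == 1L) {
        return(list(status = w[1], consensus = TRUE, n = i + k - 1L))
      }
    }
  }
  list(status = "needs_resolution", consensus = FALSE, n = m)
}

# All verdict sequences of a given length, as a list of character vectors.
all_sequences <- function(len) {
  grid <- expand.grid(rep(list(c(P, N)), len), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ], use.names = FALSE))
}

# Random Bernoulli verdict streams for a set of records with planted labels.
random_streams <- function(n_records, len, p_agree = 0.7) {
  lapply(seq_len(n_records), function(i) {
    ifelse(stats::runif(len) < p_agree, P, N)
  })
}

# Decisions reproducing a given confusion-count row, plus the matching
# reference standard (consensus decisions throughout).
decisions_from_counts <- function(tp, tn, fp, fn) {
  n <- tp + tn + fp + fn
  status <- rep(c(P, N, P, N), c(tp, tn, fp, fn))
  label <- rep(c("relevant", "not_relevant", "not_relevant", "relevant"),
               c(tp, tn, fp, fn))
  ids <- sprintf("d%05d", seq_len(n))
  list(
    decisions = tibble::tibble(
      record_id = ids, status = status,
      reached_by_consensus = TRUE,
      n_classifications = 3L,
      resolver_verdict = NA_character_
    ),
    reference = tibble::tibble(record_id = ids, reference_label = label)
  )
}
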