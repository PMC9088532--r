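# Readers and writers for the exchange formats: bibliographic records
# (RIS or CSV), classification streams, reference standards, decisions,
# reports and run manifests. CSV is the canonical interchange; RIS is
# read-only input.

#' Read bibliographic records
#'
#' Reads a record set from RIS (tags `TY`/`ER` delimit records; `TI` or
#' `T1` is the title, `AB` or `N2` the abstract, `ID` the identifier) or
#' from CSV with columns `record_id`, `title`, `abstract` and optionally
#' `reference_label`. Records with a missing or empty abstract are marked
#' `title_only`. RIS records without an `ID` tag get sequential ids.
#'
#' @param path File path.
#' @param format `"ris"` or `"csv"`; guessed from the file extension by
#'   default.
#' @return A record tibble: `record_id`, `title`, `abstract`,
#'   `title_only`, `reference_label` (`"unknown"` when the file carries no
#'   labels).
#' @export
read_records <- function(path, format = c("auto", "ris", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ris$", path, ignore.case = TRUE)) "ris" else "csv"
  }
  out <- if (format == "ris") read_records_ris(path) else read_records_csv(path)
  if (anyDuplicated(out$record_id)) {
    dup <- unique(out$record_id[duplicated(out$record_id)])
    rlang::abort(sprintf("Duplicate record_id(s): %s.",
                         paste(utils::head(dup, 5L), collapse = ", ")),
                 class = "crowdscreen_io_error")
  }
  out
}

read_records_ris <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  tag_re <- "^([A-Z][A-Z0-9])  - ?(.*)$"
  recs <- list()
  cur <- NULL
  cur_tag <- NA_character_
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    tibble::tibble(
      record_id = cur$id %||% NA_character_,
      title = cur$title %||% NA_character_,
      abstract = cur$abstract %||% NA_character_
    )
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (grepl(tag_re, ln)) {
      m <- regmatches(ln, regexec(tag_re, ln))[[1]]
      tag <- m[2]; val <- trimws(m[3])
      if (tag == "TY") {
        recs <- c(recs, list(flush(cur)))
        cur <- list()
        cur_tag <- NA_character_
      } else if (tag == "ER") {
        recs <- c(recs, list(flush(cur)))
        cur <- NULL
        cur_tag <- NA_character_
      } else if (is.null(cur)) {
        rlang::abort(sprintf("RIS parse error at line %d: tag outside a record.", i),
                     class = "crowdscreen_io_error")
      } else if (tag %in% c("TI", "T1")) {
        cur$title <- val; cur_tag <- "title"
      } else if (tag %in% c("AB", "N2")) {
        cur$abstract <- val; cur_tag <- "abstract"
      } else if (tag == "ID") {
        cur$id <- val; cur_tag <- NA_character_
      } else {
        cur_tag <- NA_character_
      }
    } else if (!is.null(cur) && !is.na(cur_tag)) {
      # continuation line of a multi-line field
      cur[[cur_tag]] <- paste(cur[[cur_tag]], trimws(ln))
    } else if (is.null(cur)) {
      rlang::abort(sprintf("RIS parse error at line %d: %s", i, sQuote(ln)),
                   class = "crowdscreen_io_error")
    }
  }
  recs <- c(recs, list(flush(cur)))
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) {
    return(tibble::tibble(record_id = character(), title = character(),
                          abstract = character(), title_only = logical(),
                          reference_label = character()))
  }
  out <- dplyr::bind_rows(recs)
  need_id <- is.na(out$record_id)
  out$record_id[need_id] <- sprintf("ris%05d", which(need_id))
  out$abstract[!is.na(out$abstract) & out$abstract == ""] <- NA_character_
  out$title_only <- is.na(out$abstract)
  out$reference_label <- "unknown"
  out
}

read_records_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stop_on_parse_problems(out, path)
  need <- c("record_id", "title")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    rlang::abort(sprintf("Record CSV is missing column(s): %s.",
                         paste(missing, collapse = ", ")),
                 class = "crowdscreen_io_error")
  }
  if (!"abstract" %in% names(out)) out$abstract <- NA_character_
  out$record_id <- as.character(out$record_id)
  out$abstract <- as.character(out$abstract)
  out$abstract[!is.na(out$abstract) & out$abstract == ""] <- NA_character_
  out$title_only <- is.na(out$abstract)
  if (!"reference_label" %in% names(out)) {
    out$reference_label <- "unknown"
  } else {
    bad <- setdiff(unique(out$reference_label), reference_levels())
    if (length(bad)) {
      rlang::abort(sprintf("Invalid reference_label value(s): %s.",
                           paste(sQuote(bad), collapse = ", ")),
                   class = "crowdscreen_io_error")
    }
  }
  out[c("record_id", "title", "abstract", "title_only", "reference_label")]
}

stop_on_parse_problems <- function(df, path) {
  probs <- readr::problems(df)
  if (nrow(probs)) {
    rlang::abort(sprintf("Parse error in %s at line %d: %s.",
                         path, probs$row[1], probs$expected[1]),
                 class = "crowdscreen_io_error")
  }
  invisible(df)
}

#' Write bibliographic records to CSV
#'
#' @param records Record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  readr::write_csv(tibble::as_tibble(records), path, na = "")
  invisible(path)
}

#' Read / write a classification stream
#'
#' Classification-stream CSV: header `record_id,contributor_id,ordinal,`
#' `verdict,timestamp_hours` (timestamps optional), verdicts spelled
#' `possibly_relevant` / `not_relevant`. Reading validates the stream
#' invariants (see [validate_stream()]).
#'
#' @param path File path.
#' @return `read_stream()`: the validated event tibble.
#' @export
read_stream <- function(path) {
  out <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      record_id = readr::col_character(),
      contributor_id = readr::col_character(),
      ordinal = readr::col_integer(),
      verdict = readr::col_character(),
      .default = readr::col_double()
    )
  )
  stop_on_parse_problems(out, path)
  missing <- setdiff(stream_columns(), names(out))
  if (length(missing)) {
    rlang::abort(sprintf("Stream CSV is missing column(s): %s.",
                         paste(missing, collapse = ", ")),
                 class = "crowdscreen_io_error")
  }
  v <- validate_stream(out)
  tibble::as_tibble(v)
}

#' @param events Event tibble.
#' @rdname read_stream
#' @return `write_stream()`: `path`, invisibly.
#' @export
write_stream <- function(events, path) {
  readr::write_csv(tibble::as_tibble(events), path, na = "")
  invisible(path)
}

#' Read a reference standard
#'
#' Reference-standard CSV: header `record_id,reference_label` with values
#' `relevant` / `not_relevant` (and optionally `unknown`).
#'
#' @param path File path.
#' @return Tibble `record_id`, `reference_label`.
#' @export
read_reference <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  stop_on_parse_problems(out, path)
  if (!all(c("record_id", "reference_label") %in% names(out))) {
    rlang::abort("Reference CSV needs columns record_id and reference_label.",
                 class = "crowdscreen_io_error")
  }
  bad <- setdiff(unique(out$reference_label), reference_levels())
  if (length(bad)) {
    rlang::abort(sprintf("Invalid reference_label value(s): %s.",
                         paste(sQuote(bad), collapse = ", ")),
                 class = "crowdscreen_io_error")
  }
  out[c("record_id", "reference_label")]
}

#' Read / write collective decisions
#'
#' Decision CSV: header `record_id,status,reached_by_consensus,`
#' `n_classifications,resolver_verdict` (empty resolver_verdict when none).
#'
#' @param path File path.
#' @return `read_decisions()`: the decision tibble.
#' @export
read_decisions <- function(path) {
  out <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      record_id = readr::col_character(),
      status = readr::col_character(),
      reached_by_consensus = readr::col_logical(),
      n_classifications = readr::col_integer(),
      resolver_verdict = readr::col_character()
    )
  )
  stop_on_parse_problems(out, path)
  need <- c("record_id", "status", "reached_by_consensus",
            "n_classifications", "resolver_verdict")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    rlang::abort(sprintf("Decision CSV is missing column(s): %s.",
                         paste(missing, collapse = ", ")),
                 class = "crowdscreen_io_error")
  }
  bad <- setdiff(unique(out$status), status_levels())
  if (length(bad)) {
    rlang::abort(sprintf("Invalid status value(s): %s.",
                         paste(sQuote(bad), collapse = ", ")),
                 class = "crowdscreen_io_error")
  }
  check_verdicts(out$resolver_verdict[!is.na(out$resolver_verdict)],
                 "resolver verdict")
  out[need]
}

#' @param decisions Decision tibble.
#' @rdname read_decisions
#' @return `write_decisions()`: `path`, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  readr::write_csv(tibble::as_tibble(decisions), path, na = "")
  invisible(path)
}

#' Write a performance report
#'
#' Emits a [crowd_performance()] report as machine-readable JSON (all
#' percentages unrounded) and optionally as human-readable Markdown
#' (percentages rounded at the reporting convention).
#'
#' @param report A [crowd_performance()] object.
#' @param json_path Output path for JSON.
#' @param md_path Optional output path for Markdown.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, md_path = NULL) {
  stopifnot(inherits(report, "crowd_performance"))
  payload <- list(
    n_records = report$n_records,
    counts = as.list(report$counts),
    sensitivity_pct = report$sensitivity_pct,
    specificity_pct = report$specificity_pct,
    consensus_pct = report$consensus_pct,
    included_consensus_pct = report$included_consensus_pct,
    title_only_consensus_pct = report$title_only_consensus_pct,
    missed_record_ids = report$missed$record_id
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(md_path)) {
    g <- glance(report)
    lines <- c(
      "# Crowd screening performance",
      "",
      sprintf("Records evaluated: %d", g$n_records),
      "",
      "| metric | value |",
      "|---|---|",
      sprintf("| TP / TN / FP / FN | %d / %d / %d / %d |", g$tp, g$tn, g$fp, g$fn),
      sprintf("| sensitivity | %.1f%% |", round_half_up(g$sensitivity_pct, 1)),
      sprintf("| specificity | %.1f%% |", round_half_up(g$specificity_pct, 1)),
      sprintf("| consensus | %.2f%% |", round_half_up(g$consensus_pct, 2))
    )
    if (!is.na(g$included_consensus_pct)) {
      lines <- c(lines, sprintf("| consensus (relevant records) | %.2f%% |",
                                round_half_up(g$included_consensus_pct, 2)))
    }
    if (!is.na(g$title_only_consensus_pct)) {
      lines <- c(lines, sprintf("| consensus (title-only records) | %.2f%% |",
                                round_half_up(g$title_only_consensus_pct, 2)))
    }
    if (nrow(report$missed)) {
      titles <- if ("title" %in% names(report$missed)) report$missed$title else NA_character_
      lines <- c(lines, "", "## Missed relevant records", "",
                 paste0("- ", report$missed$record_id,
                        ifelse(is.na(titles) | !nzchar(titles),
                               "", paste0(": ", titles))))
    }
    writeLines(lines, md_path)
  }
  invisible(json_path)
}

#' Write a run manifest
#'
#' Records everything needed to re-run a CLI invocation bit-identically:
#' the configuration echo, seeds, package version, input/output paths with
#' MD5 digests, and per-stage timings.
#'
#' @param path Output path (JSON).
#' @param config Configuration list to echo.
#' @param seed Seed(s) used.
#' @param inputs,outputs Character vectors of file paths (digested).
#' @param timings Named numeric vector of per-stage elapsed seconds.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NULL,
                           inputs = character(), outputs = character(),
                           timings = numeric()) {
  digest_files <- function(paths) {
    if (!length(paths)) return(stats::setNames(list(), character()))
    as.list(tools::md5sum(paths))
  }
  payload <- list(
    package = "crowdscreen",
    version = as.character(utils::packageVersion("crowdscreen")),
    seed = seed,
    config = config,
    inputs = digest_files(inputs),
    outputs = digest_files(outputs),
    timings_seconds = as.list(timings)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
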