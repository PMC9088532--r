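test_that("confusion counts cross-tabulate final verdicts against the reference", {
  d <- tibble::tibble(
    record_id = c("a", "b", "c"),
    status = c(P, P, N),
    reached_by_consensus = TRUE,
    n_classifications = 3L,
    resolver_verdict = NA_character_
  )
  ref <- tibble::tibble(record_id = c("a", "b", "c"),
                        reference_label = c("relevant", "not_relevant", "not_relevant"))
  cc <- crowd_confusion(d, ref)
  expect_equal(as.list(cc), list(tp = 1L, tn = 1L, fp = 1L, fn = 0L))
  expect_equal(sum(unlist(cc)), nrow(d))

  # resolver verdicts count toward accuracy
  d$status[2] <- "needs_resolution"
  d$reached_by_consensus[2] <- FALSE
  d$resolver_verdict[2] <- N
  cc2 <- crowd_confusion(d, ref)
  expect_equal(as.list(cc2), list(tp = 1L, tn = 2L, fp = 0L, fn = 0L))

  # unresolved records and missing labels are hard errors that name ids
  d$resolver_verdict[2] <- NA_character_
  expect_error(crowd_confusion(d, ref), "b", class = "crowdscreen_unresolved_error")
  d$resolver_verdict[2] <- N
  expect_error(crowd_confusion(d, ref[1:2, ]), class = "crowdscreen_reference_error")

  # unknown labels are excluded from counting
  ref$reference_label[3] <- "unknown"
  cc3 <- crowd_confusion(d, ref)
  expect_equal(sum(unlist(cc3)), 2)
})

test_that("label/verdict symmetry swaps the confusion quadrants and metrics", {
  set.seed(5)
  n <- 60
  d <- tibble::tibble(
    record_id = sprintf("r%02d", 1:n),
    status = sample(c(P, N), n, replace = TRUE),
    reached_by_consensus = TRUE, n_classifications = 3L,
    resolver_verdict = NA_character_
  )
  ref <- tibble::tibble(record_id = d$record_id,
                        reference_label = sample(c("relevant", "not_relevant"),
                                                 n, replace = TRUE))
  cc <- crowd_confusion(d, ref)
  flip <- function(x, a, b) ifelse(x == a, b, a)
  d2 <- d
  d2$status <- flip(d$status, P, N)
  ref2 <- ref
  ref2$reference_label <- flip(ref$reference_label, "relevant", "not_relevant")
  cc2 <- crowd_confusion(d2, ref2)
  expect_equal(cc2$tp, cc$tn)
  expect_equal(cc2$fn, cc$fp)
  expect_equal(sensitivity_pct(cc2, digits = NULL), specificity_pct(cc, digits = NULL))
})

test_that("reported metrics use half-up rounding", {
  expect_equal(round_half_up(96.875, 1), 96.9)  # round() would give 96.8
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(sensitivity_pct(list(tp = 31, tn = 0, fp = 0, fn = 1)), 96.9)
  expect_equal(sensitivity_pct(list(tp = 12, tn = 1, fp = 1, fn = 0)), 100.0)
  expect_equal(sensitivity_pct(list(tp = 0, tn = 0, fp = 0, fn = 5)), 0.0)
  expect_equal(specificity_pct(list(tp = 0, tn = 0, fp = 10, fn = 0)), 0.0)
  expect_error(sensitivity_pct(list(tp = 0, tn = 5, fp = 2, fn = 0)),
               class = "crowdscreen_metric_error")
  expect_error(specificity_pct(list(tp = 5, tn = 0, fp = 0, fn = 2)),
               class = "crowdscreen_metric_error")
})

test_that("consensus is the share of records decided without arbitration", {
  d <- tibble::tibble(
    record_id = paste0("r", 1:4),
    status = c(P, N, N, "needs_resolution"),
    reached_by_consensus = c(TRUE, TRUE, TRUE, FALSE),
    n_classifications = 3L,
    resolver_verdict = c(NA, NA, NA, P)
  )
  expect_equal(consensus_pct(d), 75.00)
  expect_equal(consensus_pct(d[1:3, ]), 100.00)
  expect_error(consensus_pct(d[0, ]), class = "crowdscreen_metric_error")
  # invariant to record order
  expect_equal(consensus_pct(d[sample(4), ]), consensus_pct(d))
})

test_that("subgroup consensus restricts to the selected records", {
  recs <- tibble::tibble(
    record_id = paste0("r", 1:6),
    title_only = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    reference_label = c("relevant", rep("not_relevant", 5))
  )
  d <- tibble::tibble(
    record_id = recs$record_id,
    status = c("needs_resolution", N, N, N, "needs_resolution", N),
    reached_by_consensus = c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE),
    n_classifications = 3L, resolver_verdict = NA_character_
  )
  expect_equal(subgroup_consensus(d, recs, TRUE), consensus_pct(d))
  expect_equal(subgroup_consensus(d, recs, title_only), 50.00)
  expect_equal(subgroup_consensus(d, recs, reference_label == "relevant"), 0.0)
  expect_error(subgroup_consensus(d, recs, record_id == "zzz"),
               class = "crowdscreen_metric_error")
})

test_that("strict-mode consensus among relevant records sits below overall consensus
           at low prevalence when sensitivity < specificity", {
  # closed form: relevant-side consensus s^k + (1-s)^k vs the prevalence
  # mixture, checked against a simulated strict aggregation
  op <- strict_mode_operating_point(sens = 0.82, spec = 0.90,
                                    prevalence = 0.02, k = 3)
  expect_lt(op$p_consensus_relevant, op$p_consensus)

  set.seed(303)
  corpus <- generate_corpus(2000, prevalence = 0.02, title_only_fraction = 0)
  pool <- simulate_contributors(9, sens_mean = 0.82, spec_mean = 0.90,
                                spread = 0, qualification = NULL)
  sim <- simulate_task(corpus, pool,
                       agreement_policy(k = 3, conflict_mode = "strict_first_k"),
                       deadline_hours = 48)
  expect_lt(subgroup_consensus(sim$decisions, corpus, reference_label == "relevant"),
            consensus_pct(sim$decisions))
})

test_that("missed-study reporting returns the false negatives with titles", {
  fx <- decisions_from_counts(tp = 5, tn = 100, fp = 3, fn = 1)
  recs <- tibble::tibble(record_id = fx$reference$record_id,
                         title = paste("T", seq_len(nrow(fx$reference))))
  missed <- missed_study_report(fx$decisions, fx$reference, recs)
  expect_equal(nrow(missed), 1L)
  expect_true(missed$record_id %in%
                fx$reference$record_id[fx$reference$reference_label == "relevant"])
  expect_true("title" %in% names(missed))

  none <- decisions_from_counts(tp = 5, tn = 10, fp = 0, fn = 0)
  expect_equal(nrow(missed_study_report(none$decisions, none$reference,
                                        recs[1:15, ])), 0L)
})

test_that("pooled miss rate aggregates false negatives over relevant totals", {
  tab <- data.frame(tp = c(45, 31, 17, 12), fn = c(2, 1, 1, 0))
  expect_equal(pooled_miss_rate_pct(tab), 3.7)
  expect_equal(pooled_miss_rate_pct(data.frame(tp = 9, fn = 1)), 10.0)
  expect_equal(pooled_miss_rate_pct(data.frame(tp = c(4, 5), fn = c(0, 0))), 0.0)
  expect_error(pooled_miss_rate_pct(data.frame(tp = 0, fn = 0)),
               class = "crowdscreen_metric_error")
})

test_that("citation recovery finds missed records cited by included ones", {
  expect_equal(citation_recovery("m1", "i1",
                                 data.frame(citing_id = character(),
                                            cited_id = character())),
               character())
  edges <- data.frame(citing_id = c("i1", "i2", "m1"),
                      cited_id = c("m1", "i1", "m2"))
  got <- citation_recovery(c("m1", "m2", "m3", "m4"), c("i1", "i2"), edges)
  expect_equal(got, "m1")  # m2 is cited only by a missed record
  expect_warning(
    citation_recovery("m1", "i1",
                      data.frame(citing_id = "x9", cited_id = "x8")),
    "unknown"
  )
})

test_that("crowd_performance assembles the full report with tidy/glance methods", {
  fx <- decisions_from_counts(tp = 45, tn = 3942, fp = 1617, fn = 2)
  # make some of the decisions resolver-finalised so consensus < 100
  idx <- seq_len(500)
  fx$decisions$reached_by_consensus[idx] <- FALSE
  fx$decisions$resolver_verdict[idx] <- fx$decisions$status[idx]
  fx$decisions$status[idx] <- "needs_resolution"
  recs <- tibble::tibble(record_id = fx$reference$record_id,
                         title = "t", title_only = FALSE)
  recs$title_only[1:100] <- TRUE
  rep <- crowd_performance(fx$decisions, fx$reference, recs)
  expect_s3_class(rep, "crowd_performance")
  expect_equal(round_half_up(rep$sensitivity_pct, 1), 95.7)
  expect_equal(round_half_up(rep$specificity_pct, 1), 70.9)
  expect_equal(rep$counts$fn, nrow(rep$missed))

  td <- tidy(rep)
  expect_true(all(c("metric", "value") %in% names(td)))
  g <- glance(rep)
  expect_equal(g$n_records, 5606)
  expect_equal(g$n_missed, 2)
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
})
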