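test_that("corpus generation plants exact relevant and title-only counts", {
  corpus <- generate_corpus(948, prevalence = 12 / 948, seed = 1)
  expect_equal(nrow(corpus), 948L)
  expect_equal(sum(corpus$reference_label == "relevant"), 12L)

  corpus0 <- generate_corpus(500, prevalence = 0, seed = 1)
  expect_equal(sum(corpus0$reference_label == "relevant"), 0L)

  corpus_to <- generate_corpus(1000, prevalence = 0.01,
                               title_only_fraction = 0.07, seed = 9)
  expect_equal(sum(corpus_to$title_only), 70L)
  # the title-only flag is tied to abstract absence
  expect_equal(corpus_to$title_only, is.na(corpus_to$abstract))

  expect_warning(generate_corpus(100, prevalence = 0.001),
                 "no relevant records")
  # identical seed, identical corpus
  expect_identical(generate_corpus(200, 0.05, seed = 3),
                   generate_corpus(200, 0.05, seed = 3))
})

test_that("qualification passing matches the binomial upper tail", {
  q <- qualification_spec()  # 16 items, pass at 80% => 13 correct
  perfect <- data.frame(sens = 1, spec = 1)
  hopeless <- data.frame(sens = 0, spec = 0)
  expect_true(all(run_qualification(perfect[rep(1, 50), ], q, seed = 1)))
  expect_false(any(run_qualification(hopeless[rep(1, 50), ], q, seed = 1)))

  # brute-force enumeration oracle for the pass probability at accuracy 0.85
  acc <- 0.85
  p_pass <- sum(vapply(13:16, function(s) {
    choose(16, s) * acc^s * (1 - acc)^(16 - s)
  }, 1))
  many <- data.frame(sens = acc, spec = acc)[rep(1, 4000), ]
  got <- mean(run_qualification(many, q, seed = 42))
  se <- sqrt(p_pass * (1 - p_pass) / 4000)
  expect_lt(abs(got - p_pass), 3 * se)
})

test_that("a single classification is a Bernoulli draw at the profile accuracy", {
  pool <- simulate_contributors(1, sens_mean = 0.85, spec_mean = 0.9,
                                spread = 0, qualification = NULL, seed = 2)
  rel <- generate_corpus(10000, prevalence = 1, title_only_fraction = 0, seed = 4)
  v <- classify_records(pool[1, ], rel, seed = 5)
  se <- sqrt(0.85 * 0.15 / 10000)
  expect_lt(abs(mean(v == P) - 0.85), 3 * se)

  sure <- pool
  sure$sens <- 1; sure$spec <- 1
  expect_true(all(classify_records(sure, rel[1:50, ]) == P))
  not <- generate_corpus(50, prevalence = 0, title_only_fraction = 0, seed = 6)
  expect_true(all(classify_records(sure, not) == N))

  unq <- pool
  unq$qualified <- FALSE
  expect_error(classify_records(unq, rel[1:2, ]),
               class = "crowdscreen_gating_error")
})

test_that("simulated tasks finalise every record when the pool is able and honest", {
  corpus <- generate_corpus(120, prevalence = 0.05, seed = 10)
  perfect <- simulate_contributors(4, spread = 0, qualification = NULL, seed = 11)
  perfect$sens <- 1; perfect$spec <- 1
  perfect$title_only_sens <- 1; perfect$title_only_spec <- 1
  sim <- simulate_task(corpus, perfect, agreement_policy(k = 3), seed = 12)
  expect_equal(sim$n_unfinalised, 0L)
  expect_true(all(sim$decisions$reached_by_consensus))
  cc <- crowd_confusion(sim$decisions, corpus)
  expect_equal(sensitivity_pct(cc), 100.0)
  expect_equal(specificity_pct(cc), 100.0)
  expect_equal(consensus_pct(sim$decisions), 100.00)
})

test_that("a pool smaller than k can never finalise a record", {
  corpus <- generate_corpus(30, prevalence = 0.1, seed = 20)
  two <- simulate_contributors(2, qualification = NULL, seed = 21)
  expect_warning(sim <- simulate_task(corpus, two, agreement_policy(k = 3),
                                      seed = 22),
                 "no record can be finalised")
  expect_true(is.na(sim$completion_hours))
  expect_equal(sim$n_unfinalised, 30L)
  expect_false(any(sim$decisions$reached_by_consensus))
})

test_that("simulation is bit-identical under an identical seed and replayable", {
  corpus <- generate_corpus(150, prevalence = 0.08, seed = 30)
  pool <- simulate_contributors(6, qualification = NULL, seed = 31)
  pol <- agreement_policy(k = 3)
  s1 <- simulate_task(corpus, pool, pol, seed = 32)
  s2 <- simulate_task(corpus, pool, pol, seed = 32)
  expect_identical(s1$stream, s2$stream)
  expect_identical(s1$decisions, s2$decisions)
  expect_identical(s1$completion_hours, s2$completion_hours)

  # the simulator's in-flight decisions match offline re-aggregation of the
  # recorded stream under the same policy
  replayed <- aggregate_task(s1$stream, pol)
  merged <- dplyr::inner_join(s1$decisions, replayed, by = "record_id",
                              suffix = c("_sim", "_replay"))
  expect_equal(nrow(merged), nrow(s1$decisions))
  expect_equal(merged$status_sim, merged$status_replay)
  expect_equal(merged$n_classifications_sim, merged$n_classifications_replay)
})

test_that("strict-mode relevant consensus declines in k and collective
           sensitivity with an oracle resolver beats a single classification", {
  k <- 2:6
  op <- strict_mode_operating_point(sens = 0.85, spec = 0.85,
                                    prevalence = 0.1, k = k)
  expect_true(all(diff(op$p_consensus_relevant) < 0))
  expect_equal(op$p_collective_P_given_relevant[op$k == 3], 0.85^3)
  expect_equal(strict_mode_operating_point(1, 1, 0.5, 4)$p_consensus_relevant, 1)

  # collective gain: streak of k errors is needed to lose a relevant record
  set.seed(50)
  sens_vals <- replicate(20, {
    corpus <- generate_corpus(400, prevalence = 0.1, title_only_fraction = 0)
    pool <- simulate_contributors(8, sens_mean = 0.8, spec_mean = 0.85,
                                  spread = 0, qualification = NULL)
    sim <- simulate_task(corpus, pool, agreement_policy(k = 3))
    fv <- final_verdict(sim$decisions)
    # oracle resolver: unresolved records resolved to their true label
    lab <- corpus$reference_label[match(sim$decisions$record_id, corpus$record_id)]
    fv[is.na(fv)] <- ifelse(lab[is.na(fv)] == "relevant", P, N)
    sum(fv == P & lab == "relevant") / sum(lab == "relevant")
  })
  expect_gt(mean(sens_vals), 0.8)
})

test_that("completion time is non-increasing in pool size in expectation", {
  mean_completion <- function(pool_size) {
    mean(vapply(1:20, function(s) {
      corpus <- generate_corpus(100, prevalence = 0.05, seed = 60 + s)
      pool <- simulate_contributors(pool_size, qualification = NULL,
                                    seed = 80 + s)
      sim <- simulate_task(corpus, pool, agreement_policy(k = 3),
                           seed = 100 + s)
      sim$completion_hours
    }, 1))
  }
  expect_gt(mean_completion(4), mean_completion(12))
})
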