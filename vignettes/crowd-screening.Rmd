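---
title: "Consecutive-agreement crowd screening: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consecutive-agreement crowd screening: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdscreen)
```

## The screening model

A screening task presents each record (a title–abstract citation) to crowd
contributors one at a time; every contributor issues one of exactly two
verdicts, *possibly relevant* or *not relevant* — there is no abstain
state, and a contributor never classifies the same record twice. The
record's ordered verdict stream is collapsed by the
**consecutive-agreement rule**: the record is finalised, by consensus, at
the first run of `k` identical verdicts (default `k = 3`). Streams that
never produce a streak are routed to a resolver, an experienced
contributor whose verdict finalises the record but does not count as
consensus.

What happens *between* a disagreement and a streak is not uniquely
determined by that description, so the policy object exposes both
defensible readings:

* `streak_continue` (default): the scan continues past disagreements
  until a streak forms or `max_assessments` classifications (default
  `2k + 1`) have been consumed. This is the reading under which every
  record receives a bounded number of crowd assessments before
  arbitration.
* `strict_first_k`: any disagreement before the first `k` classifications
  agree sends the record to the resolver immediately. Consensus then
  requires the *first* `k` verdicts to agree, which gives clean closed
  forms (below).

Production platforms do not document which variant they run; rather than
guess, both are implemented and `replay_with_policy()` re-aggregates any
recorded stream under any policy, so the choice can be studied on fixed
data.

### Evaluation metrics

With the author team's final decisions as reference standard, the package
computes sensitivity `100·tp/(tp+fn)`, specificity `100·tn/(tn+fp)`,
crowd consensus (share of records finalised without arbitration), the
same consensus restricted to arbitrary subgroups (`subgroup_consensus()`
with a tidy predicate — typically the truly relevant records and the
title-only records), a pooled miss rate `100·Σfn/Σ(tp+fn)` across tasks,
a titled report of missed studies, and forward citation recovery (which
missed records are cited by a correctly included one).

Three semantic rules are worth stating explicitly because they are easy to
get silently wrong:

* resolver verdicts count toward **accuracy** but never toward
  **consensus** — consensus is defined as *not requiring arbitration*;
* records with an `unknown` reference label are excluded from confusion
  counting but retained in consensus, which is reference-free;
* confusion counting refuses to run while any record lacks a final
  verdict, naming the unresolved ids, rather than dropping them.

### Strict-mode closed forms

Under `strict_first_k` with independent classifications at
per-classification sensitivity `s`, a truly relevant record reaches
consensus with probability `s^k + (1-s)^k`, is collectively included with
probability `s^k`, and symmetrically in specificity for ineligible
records; `strict_mode_operating_point()` returns these and their
prevalence mixture. The consensus form is strictly decreasing in `k` for
`s ∈ (0, 1)`: longer streaks buy accuracy with resolution workload.

```{r}
strict_mode_operating_point(sens = c(0.85, 0.85), spec = 0.85,
                            prevalence = 0.01, k = c(2, 3))[,
  c("k", "p_consensus_relevant", "p_collective_P_given_relevant")]
```

## Reporting conventions

Percentages are stored and serialised unrounded; rounding is applied only
at presentation, and it is **half-up**, not R's default round-half-even:
a sensitivity of 31/32 prints as 96.9, where `round()` would print 96.8.
Accuracy metrics print with 1 decimal and consensus with 2, matching the
conventions of published screening evaluations.

The bundled `rapid_review_tasks()` table carries the reported summary
statistics of a published evaluation in which a crowd screened four
COVID-19 rapid-review search-result sets (948–5,606 records, 12–65
contributors, ~0.8–1.3% prevalence) under a 48-hour deadline. Two of its
printed specificities (73.0 and 88.7) are inconsistent with their own
confusion counts (which give 73.1 and 88.4 under any rounding), and one
task's counts sum to one less than its stated set size. The table carries
the printed values verbatim; everything this package reports is recomputed
from the counts, which are treated as authoritative.

## The synthetic crowd

The simulator emulates the statistical structure of real screening tasks;
it is how the aggregation and evaluation layers are exercised at scale
without platform data.

* **Corpus** (`generate_corpus()`): `round(n·prevalence)` relevant and
  `round(n·title_only_fraction)` abstract-less records, positions
  shuffled by seed. Counts are fixed by rounding, not drawn, so a corpus
  is bit-reproducible from its spec; defaults reflect typical screening
  sets (prevalence well under 5%, ~6.5% title-only).
* **Contributors** (`simulate_contributors()`): sensitivity and
  specificity drawn from normal distributions truncated to \[0, 1\] by
  rejection sampling, mean 0.85 and spread 0.05 by default — individual
  screeners in published evaluations sit at roughly 0.82–0.91. Title-only
  records get a 0.05 absolute accuracy penalty (consensus is observed to
  be lowest on abstract-less records); both are configurable.
* **Qualification** (`run_qualification()`): 16 practice items, pass at
  80% (i.e. 13 of 16). Per-item accuracy is the mean of the contributor's
  sensitivity and specificity — the item set is modelled half relevant,
  half not — so the pass probability is exactly a binomial upper tail,
  which the tests check by enumeration.
* **Classification** (`classify_records()`): a single verdict is one
  Bernoulli draw at the profile's class- and subgroup-specific accuracy.
  Errors are independent across contributors and records.
* **The task loop** (`simulate_task()`): each qualified contributor
  produces classifications as a Poisson process at `rate_per_hour`
  (default 20, about one title–abstract assessment every three minutes —
  consistent with completing a few-thousand-record task within a couple of
  days at observed pool sizes). The scheduler serves each contributor a
  uniformly random record they have not seen that is not yet finalised;
  the paper trail (`$stream`) is recorded in full so any run can be
  re-aggregated offline, and the tests assert that the in-flight decisions
  equal `aggregate_task()` replayed on the recorded stream.

Degenerate regimes are handled explicitly rather than left to hang: a pool
smaller than `k` can never finalise anything (warned, and the task ends
INCOMPLETE at the deadline); a record that exhausts a pool of at least `k`
contributors without a streak is routed to resolution early, since nobody
is left to extend its stream; an empty stream aggregates to
needs-resolution with zero classifications (a warning, not an error),
which is also how records still open at the deadline appear.

### What the simulator does *not* model

Contributor errors are independent. Real disagreement is concentrated on
genuinely ambiguous records, so real consensus on the easy bulk of a
corpus is much higher than independence predicts — simulated *overall*
consensus should not be compared against published overall consensus
figures. The included-record subgroup is less affected (those records are
closer to exchangeable in difficulty), which is why the benchmark-band
check below is phrased on included-study consensus only, and as a band.
Also unmodelled: learning over time, dropout, diurnal activity patterns,
and heavy-tailed per-contributor effort (real per-person record counts
range over three orders of magnitude; the default rate model is
homogeneous).

## Design choices in the checks

* **Oracle equivalence.** The scanner is verified against an independent
  brute-force oracle that tests every window of length `k`, exhaustively
  over all verdict sequences of length ≤ 8 in both conflict modes.
* **Nesting.** A run of `k+1` contains a run of `k`, so on full-stream
  replay the `k = 3` consensus set nests inside the `k = 2` set — *when
  the assessment cap is held fixed*. With the default cap `2k + 1` the cap
  itself moves with `k` and nesting can fail (a streak ending at position
  7 is visible at `k = 3`, cap 7, but beyond the `k = 2` cap of 5); the
  nesting tests therefore pin the cap.
* **Strict-mode agreement.** Simulated strict-mode consensus at 100,000
  replicates per cell is compared to `s^k + (1-s)^k` within three binomial
  standard errors over a 3 × 3 grid of `(s, k)`, and checked monotone
  decreasing in `k`.
* **Parameter recovery.** Contributor accuracies are re-estimated from a
  simulated stream (2,500 records at prevalence 0.20 for power, pool of
  10) and required to fall within three binomial standard errors of truth
  for every contributor with ≥ 200 classifications.
* **Benchmark band.** Each of the four bundled tasks is simulated
  at its reported size, prevalence, pool and individual accuracies, and
  the included-study consensus is required to land in 55–75% — the band
  containing the reported 60–65% — not to match exactly, because
  inter-contributor correlation is unmodelled. These simulations use
  `strict_first_k`: it is the variant whose consensus semantics matches
  the reported subgroup consensus; under independence a streak-continuing
  scan re-tries after every dissent and pushes subgroup consensus above
  90%, outside anything observed. Replicates per task are set for roughly
  equal Monte-Carlo error (about 1,000 relevant records per task in the
  tests, 300 in the acceptance script, which favours speed).

## Limitations

The simulator is a null model of an idealised crowd; it is suited to
studying the aggregation rule, workload and workflow trade-offs, and
statistical identifiability, not to forecasting a particular crowd's
accuracy. Collective accuracy estimates inherit the small denominators of
screening evaluations (tens of included studies), so single-run subgroup
percentages are noisy; the package's own checks average over replicates
and so should any downstream use. RIS support is a minimal tag reader
(`TY`/`ER`, `TI`/`T1`, `AB`/`N2`, `ID`) for title–abstract screening
inputs, not a general bibliographic parser, and RIS is read-only — CSV is
the canonical interchange.
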