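---
title: "Methods: clickstream networks, awareness-conditioned centrality, and abstinence models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clickstream networks, awareness-conditioned centrality, and abstinence models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cessnet` turns raw clickstream logs of an online smoking-cessation
community into a directed social network, tracks each trial
participant's position in that network week by week, and models 30-day
abstinence from those trajectories. This vignette documents the methods,
the assumptions behind them, and the design decisions taken where more
than one defensible choice existed.

## 1. From clickstream to ties

Every user action is a time-stamped event `(user, action, channel,
content, thread, author)` with actions `view`, `post`, `respond`,
`send_pm` over channels `blog`, `group`, `wall`, `board`, `pm`.

**Tie rule.** A directed tie author → reader forms at the reader's first
view of any content by that author in an included channel
(`build_ties()`). Degree therefore counts distinct members, not
documents: reading three posts by the same author yields one tie, with
the first-formed channel recorded. Self-views form no tie. Ties
aggregate over blogs, group discussions and private messages; the
message board is excluded because board clickstreams do not identify
reading unambiguously, and the wall (profile page) is likewise outside
the tie channels. Staff and bot accounts arrive pre-flagged and are
excluded from every network computation.

In the event schema a view references a single content item, so a view
ties the reader to that item's author. On platforms where one rendered
page shows several authors' messages, the upstream log should emit one
view event per content item shown; the tie rule then connects the
reader to every author on the page.

**Awareness.** Out-degree accumulates whether or not the author ever
learns they were read, which makes it a weak predictor of the author's
own behaviour. The *out-degree-aware* restriction
(`mark_awareness()`) keeps only ties Mary → John where the log contains
the full chain

1. John viewed content by Mary in thread *T*, then
2. John responded in *T*, and
3. Mary later viewed John's response.

Ordering is strict in event-sequence terms (the log carries a
deterministic sequence number that breaks timestamp ties at second
resolution), and `aware_at` is the earliest time Mary saw a qualifying
response. Private-message "threads" are the pair's conversation; the
same chain applies.

## 2. Weekly centrality trajectories

Week boundaries are participant-relative: week *w* spans
`[registration + 7(w−1), registration + 7w)` days, because enrollment in
such studies spans years and "the first week after registration" is the
behaviourally meaningful anchor. Ties are cumulative — each weekly
network contains all ties formed up to that week's end — so every series
is non-decreasing, `out_degree_aware ≤ out_degree` pointwise (an aware
tie is an out-tie whose `aware_at` has passed), and ties to background
community members count: a participant's audience is the whole
community, not just other trial participants. Twelve weeks is the
default horizon, matching the 3-month outcome window.

The model predictors (`sqrt_change_features()`) are the week-1 value and
the weeks 2–12 change of in-degree and out-degree-aware, all on the
square-root scale: `change = sqrt(week12) − sqrt(week1)`. The square
root stabilizes the heavy right tail of degree distributions while
keeping zero at zero; the change is computed *after* the transform, so
accumulating nine ties from a zero start is 3 square-root units. These
four predictors are deliberately left unstandardized so that
odds ratios per square-root tie remain interpretable and extrapolate to
*k* ties as `OR(k) = OR^sqrt(k)` (`or_at_k_ties()`), with confidence
limits transformed endpoint-wise. The endpoint transformation (rather
than a delta-method interval on the transformed scale) is exact for a
monotone transformation of a Wald interval and reproduces printed
nine-tie intervals from per-unit ones.

## 3. Whole-network summaries

`network_summary()` reports the largest strongly connected component
(LSCC), the mean directed shortest-path length over ordered pairs
within the LSCC, and clustering. "Probability of triads" does not pin
down a clustering variant, so two are reported and labelled: the
average local clustering coefficient of the undirected projection
(nodes with fewer than two neighbours contributing zero — the common
convention in network libraries) and the global transitivity ratio.
Degree distributions are exported as complementary cumulative count
tables. Graph algorithms are delegated to `igraph`; the test suite
checks them against brute-force transitive-closure, matrix-power
shortest-path and explicit triangle-count oracles on hundreds of random
digraphs.

Only members whose content has been read (posters) can have outgoing
ties, so the LSCC share is bounded above by the poster share — an
invariant the tests exercise.

## 4. Sessions, utilization, and engagement groups

Page views are grouped into sessions by the standard 30-minute
inactivity rule (`sessionize()`): a gap of *more than* 30 minutes ends
a session, so a gap of exactly 30 minutes does not split. Session
duration is last view minus first view (zero for single-view sessions).
Only view events define sessions; posting is assumed to co-occur with a
page view. Calendar days use the site's single reference time zone
(UTC here).

Utilization profiles (`utilization()`) cover each member's first 84
days after registration — 12 exact weeks, chosen to coincide with the
centrality horizon rather than a calendar "3 months". `total_posts`
counts authored messages in blogs, group discussions and the message
board; wall posts and private messages are tallied separately and
excluded from `total_posts`. This matters for classification
(`classify_engagement()`): non-users have no posts and no page views,
passive users have views only, active users have both. Under the posts
definition a member whose only contributions are wall posts or PMs
classifies as passive — which is why real cohorts show the occasional
"passive" user with nonzero wall activity. The degenerate case of posts
without any recorded view is assigned to active and written to an audit
log rather than silently reclassified.

Between-group comparisons (`compare_groups()`) dispatch to the
conventional tests — one-way ANOVA and chi-square for baseline
variables, Kruskal–Wallis for skewed utilization metrics, Fisher's
exact test for sparse 2×k tables — all delegated to base R; the
bespoke content is only the dispatch, which the tests calibrate under
permuted (null) labels.

## 5. Abstinence models

`robust_logit()` fits ordinary maximum-likelihood logistic regression
and reports sandwich standard errors (`sandwich::vcovHC`, HC0). With
one record per independent subject this *is* the GEE
working-independence estimator: identical point estimates, and the
robust covariance reduces to the heteroskedasticity-consistent
sandwich `A⁻¹BA⁻¹`. The tests verify this identity against a
hand-computed sandwich. Wald 95% intervals use the 1.96 normal
quantile, matching OR (LCL, UCL) presentation. Aliased
(constant-in-sample) columns are kept in the coefficient table as `NA`
rows rather than erroring, because week-1 out-degree-aware is
structurally near-zero in realistic cohorts. Non-convergence raises an
error carrying the iteration count; quasi-separation is flagged on the
fit.

**Reference models.** `stepwise_select()` chooses group-specific
reference models from baseline and utilization covariates by stepwise
logistic regression at α = .10. "Stepwise" admits several variants;
the implemented one is forward selection with backward pruning, both on
Wald p-values (enter the smallest-p candidate if p < α, then drop any
included term whose p has risen to ≥ α, iterate to a fixed point), with
ties broken by candidate order so selection is deterministic given the
data. An information-criterion variant would be equally defensible; the
p-value variant was chosen because the selection threshold is stated as
a significance level. Network terms never compete in selection — they
are added afterwards, in-degree terms only for passive users (whose
out-degree is zero by definition) and all four terms for active users.

**Covariate scaling.** Continuous baseline and utilization covariates
are centered at the group median and scaled by (Q3 − median), so a unit
increase means "one quartile above the group median". Quantiles use
linear interpolation between order statistics (R type 7) — the scaled
coefficients depend on this rule, so it is fixed and documented. A
degenerate spread (Q3 ≤ median, common for zero-inflated counts) falls
back to centering only, flagged in the scaling table. Network terms are
never quartile-scaled.

**Predictiveness.** `cv_auc()` reports the apparent AUC and a ten-fold
cross-validated AUC: folds stratified by outcome from a stored seed,
refit on nine folds, held-out scores pooled, AUC computed once as the
Wilcoxon rank statistic (ties counted one half, invariant under
monotone transforms of the score). If a fold assignment leaves a
training set with one outcome class it is re-randomized up to a bounded
number of retries before erroring.

## 6. The synthetic community generator

No platform's raw data can ship with an analysis package, so
`generate_community()` provides the study conditions synthetically: a
trial cohort (default 2,657 participants, registrations uniform over a
120-day enrollment window) embedded in a larger background membership
(default 5,000, active throughout), plus a handful of pre-flagged
staff/bot accounts, observed for 84 days per participant.

What it emulates, and why:

- **Heavy-tailed activity.** Per-user viewing and posting rates are a
  base rate times a log-normal multiplier (`sdlog` 1.4, mean 1). The
  log-normal is the simplest family that reproduces the empirical
  pattern that most members have low degrees while a few have very
  high ones; the tests check mean > median of the nonzero degree
  distributions.
- **Lurkers.** A configurable fraction (default 0.66, matching the
  passive share observed in large cessation communities) never posts;
  members who post at all contribute at least one post, so the
  zero-post share converges to `lurker_fraction` exactly.
- **Threaded interaction.** Browsing views pick uniformly among
  existing non-PM content; readers respond in-thread with probability
  0.15, and the content's author views the response with probability
  0.6 — the chain that generates aware ties. Private messages are
  addressed to a uniformly chosen member and read with probability
  0.8. User arrival is uniform within windows; nothing in the package
  depends on the arrival process, and no claim is made that it mirrors
  any real platform's growth.
- **Planted outcome.** The abstinence outcome is drawn from a logistic
  model on the four square-root centrality features *computed from the
  generated events by the same code path used at analysis time*, plus
  standardized age and confidence-to-quit (default coefficients:
  intercept −2.2 giving a ~10% base rate, log 1.19 per square-root
  in-degree-change tie, log 1.29 per out-degree-aware-change tie,
  log 0.85 per age SD, log 1.3 per confidence SD). The planted truth is
  returned alongside the data, making parameter-recovery tests
  self-consistent: if the pipeline's tie, awareness or centrality logic
  drifted from the generator's, recovery would fail.

What it does **not** emulate: message content and sentiment,
intervention arms, seasonal or campaign-driven traffic, preferential
attachment to popular authors, churn in reading behaviour, or
informative survey non-response (the response indicator is independent
of the outcome). Passing tests therefore demonstrate the correctness
and statistical calibration of the machinery under a realistic but
simplified data-generating process — not that any particular real-world
effect size is reproduced.

Determinism: the generator seeds R's RNG from `config$seed`; identical
configuration and seed give byte-identical event logs and cohorts, and
`run_pipeline()` re-runs reproduce identical output files.

## 7. Numerical choices and degenerate inputs

- Timestamps are stored at second resolution; simultaneous events are
  ordered by a deterministic sequence number that all ordering-
  sensitive logic (tie formation, awareness chains) uses.
- A session gap of exactly 30 minutes does not split; the rule is
  "more than 30 minutes".
- Empty inputs have defined outputs: an empty tie list yields an empty
  network summary with zero nodes, a member with no events gets an
  all-zero profile and series, an empty candidate set gives an
  intercept-only model, and an empty cohort aborts the pipeline with a
  clean error.
- Quantiles everywhere are R type 7; the 95% CI multiplier is the
  normal 1.96; `pct()` rounds shares to one decimal, the convention
  used for every reported percentage.

## 8. Problem sizes used by the test suite

The suite validates statistical behaviour at sizes chosen to make
Monte-Carlo error small relative to the tolerances asserted: oracle
equivalence on 500 random digraphs (≤ 12 nodes) and 200 random event
logs (≤ 50 events); parameter recovery over 100 replicate communities
of 2,000 participants each, asserting ≥ 90% coverage of planted
coefficients by 95% robust intervals and ~95% coverage of 1 by null
predictors' OR intervals; and calibration of the group tests over 200
label permutations. These sizes are the package's own reproducibility
standard and run comfortably on a single CPU.

## 9. Known limitations

- Degree-based centralities ignore *who* one's neighbours are; no
  betweenness, eigenvector or core–periphery measures are provided,
  and ties carry no weights or decay.
- The awareness chain requires an explicit response view; platforms
  that notify authors out-of-band (email digests) will under-count
  awareness.
- "PMs received" is proxied by the recipient's read of the message,
  since the event schema carries no recipient column; unread PMs are
  invisible to the profile.
- The stepwise reference-model procedure inherits the usual caveats of
  p-value-driven selection; it is provided because it is the
  conventional epidemiological workflow this package mirrors, not as a
  recommendation for inference on the selected baseline terms.
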