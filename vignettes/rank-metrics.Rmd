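---
title: "Comparing dominance rank metrics to infer competitive regimes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing dominance rank metrics to infer competitive regimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domrank)
```

## The question the package answers

In many group-living animals, same-sex adults can be arranged in a linear
dominance hierarchy that governs priority of access to contested resources.
Two ordinal summaries of a hierarchy position are in wide use:

* **simple ordinal rank** `k`: the integer position 1..n, 1 most dominant;
* **proportional rank** `1 - (k - 1)/(n - 1)`: the proportion of the other
  `n - 1` hierarchy members the individual outranks (1 = top, 0 = bottom).

Within a single hierarchy of fixed size the two are perfectly (negatively)
correlated and interchangeable. They diverge as soon as hierarchy size `n`
varies — across groups, or within a group over time. An individual holding
ordinal rank 5 while four immigrants join below it keeps ordinal rank 5 but
moves from proportional rank 0 (bottom of 5) to 0.5 (middle of 9).

Which metric is the *right* measure of competition depends on how the
resource base scales with hierarchy size:

* **Density-dependent competition**: the resource base is fixed regardless
  of how many individuals compete for it (for instance, the number of
  oestrous females available on a given day barely grows with the number of
  adult males). Access works like a queue: what matters is how many
  individuals stand ahead of you, i.e. your ordinal rank.
* **Density-independent competition**: the resource base grows in
  proportion to hierarchy size (a larger group ranges over a proportionally
  larger feeding area), so per-capita access is constant and what matters is
  the *fraction* of the group you outrank, i.e. your proportional rank.

The package operationalizes this as a model-comparison test. For a trait
measured alongside rank data, fit three models that differ only in the rank
term — ordinal, proportional, or none — on an identical row set, and compare
their AICs. Whichever rank metric wins by at least 2 AIC units identifies
the competitive regime shaping that trait; tallies of wins across traits
(and sexes) are then tested with exact binomial and Fisher tests.

## From agonistic bouts to ranks

Hierarchies are inferred from decided dyadic agonistic bouts between
same-sex individuals. Bouts are pooled per calendar month (a `window`
argument allows multi-month pooling) into a win–loss matrix per
(group, sex, month): `counts[i, j]` = bouts in which `i` beat `j`.

`order_hierarchy()` places individuals in descending rank so as to minimize
the total count of entries falling below the matrix diagonal — bouts won
"upward" against the ordering. The objective alone does not determine an
algorithm or a unique optimum, so the package makes three explicit choices:

* **Search.** For hierarchies of up to 8 individuals, all `n!` orderings are
  scored exhaustively (vectorized over a cached permutation table; 8! =
  40,320 candidates), guaranteeing the global minimum. Above 8, a
  deterministic first-improvement descent over single-individual
  relocations runs from the tie-break baseline until no move lowers the
  score; this finds a local minimum under all pairwise relocations. Exact
  where cheap, deterministic everywhere.
* **Tie-breaks.** Many matrices (sparse months especially) admit several
  minimal orderings. The package prefers the ordering closest, position by
  position, to a baseline built from (1) the previous month's relative
  order when supplied, then (2) descending win proportion, then
  (3) lexicographic id. Monthly rank calculation in an ongoing study implies
  temporal continuity, which is why the prior order leads. The rule is
  total, so results are a deterministic function of (matrix, prior).
  Individuals with no bouts that month are retained only if a roster names
  them, and are placed by the same tie-break rules; their win proportion is
  treated as 0.
* **Chaining.** `build_ranks()` walks each (group, sex) series in
  chronological order, feeding each month's ordering in as the next month's
  prior.

`rank_table()` turns orderings into per-individual-month records with both
metrics. A hierarchy of one has no within-group competitors and the
proportional-rank denominator vanishes; such records carry `NA` proportional
rank (with a warning) and are excluded from model datasets. For traits
measured in immatures, `assign_maternal_rank()` substitutes the mother's
record; the convention month defaults to the trait-measurement month, with
the birth month selectable, since either is defensible and analyses should
state their choice. `metric_divergence()` summarizes, for one individual,
how far the two metrics' trajectories have drifted apart over time, as the
rank correlation between the negated ordinal and the proportional series —
exactly 1 while hierarchy size is constant, undefined (`NA`) if a
trajectory is flat, and below 1 when size changes decoupled the metrics.
The summary is a deliberate, simple stand-in for richer change-point
diagnostics.

## The three-model AIC comparison

`compare_rank_metrics()` fits the trait three times — ordinal term,
proportional term, no rank term — on one shared row set (rows missing any
used column, including an undefined proportional rank, are dropped before
any fit). Numerical choices:

* **Full maximum likelihood, never restricted likelihood.** The three specs
  differ in fixed effects, and restricted-likelihood AICs are not
  comparable across fixed-effect structures.
* **Plain AIC**, `2p - 2logL`, with `p` counting every estimated parameter
  including dispersion and variance components; the Cox family contributes
  its partial likelihood and counts only regression coefficients.
* **Preference threshold 2** (configurable): a model is preferred when its
  AIC is at least 2 below the competitor's, the conventional cut-off
  approximating p = 0.05. `|ΔAIC| < 2` between the two metrics classifies
  the trait `INDISTINGUISHABLE`. Whether the preferred metric also beats
  the null model is reported as a separate flag rather than folded into the
  classification: a trait can discriminate between metrics while neither
  clears the null, and vice versa, and conflating the two judgements loses
  information.
* **Convergence.** Any non-convergent member fit — including boundary
  binomial fits where all fitted probabilities are numerically 0 or 1, as
  happens under complete separation or an all-successes response —
  invalidates the whole comparison rather than contributing a misleading
  AIC.

Fitting is delegated to the standard engines — `stats::glm` for gaussian,
binomial and Poisson, `MASS::glm.nb` for negative binomial,
`survival::coxph` for survival traits, and `glmmTMB` (with `REML = FALSE`)
whenever a random intercept is requested — behind a uniform `fit_result`
contract (log-likelihood, parameter count, AIC, convergence flag), so other
backends can be attached without touching the comparison logic.

Classification tallies are tested with `tally_and_test()`: per sex, the
share of ordinal wins among traits where one metric was preferred is tested
against chance with a two-tailed exact binomial test (the small-p-values
method: the p-value sums the probabilities of all outcomes no more probable
than the one observed), and the sexes' ordinal/proportional splits are
contrasted with a two-sided Fisher exact test on the 2×2 table. Both are
exact enumerations, appropriate at the small trait counts these analyses
involve.

## The competitive-regime simulator

`simulate_regime()` generates data whose ground truth is known, to validate
the whole pipeline. It emulates a multi-group longitudinal field study:

* several groups followed monthly, each with a latent linear hierarchy;
* group size grows by immigrants joining at the bottom of the hierarchy
  (the canonical way newcomers enter a queue; random-rank entry is not
  modeled);
* every dyad fights a fixed number of decided bouts per month, the
  higher-ranked winning each with probability `1 - epsilon` — `epsilon` is
  the upset rate, bounded below 0.5 so the latent order remains meaningful;
* traits are generated from the **latent** ranks, so rank-inference error
  enters the validation realistically when the analysis pipeline re-infers
  ranks from the simulated bouts alone.

Two trait generators embody the two regimes. The **linear** generator adds
a gaussian rank effect: `alpha - beta_ordinal * k` under density dependence,
`alpha + beta_prop * p` under density independence, with residual sd
`sigma`. The **queue** generator implements priority of access directly:
each day, `m` resource units are drawn as a count with mean `R(n)` (Poisson
by default, or deterministic), and the `m` top-ranked members score that
day; the trait is the monthly access fraction over 30 days. `R(n)` is the
regime's resource curve: a constant `r1` under density dependence
(per-capita access `r1/n`, declining), `r1 * n` under density independence
(per-capita access constant at `r1`). The default `r1 = 0.2` corresponds to
roughly one contested resource unit per five competitors — e.g. oestrous
females available to a male hierarchy — and the count draw is the simplest
distribution consistent with specifying only a mean.

Validation experiments in the test suite use the conditions stated in
`inst/extdata/recovery_config.json`: 4 groups, 24 months, hierarchy sizes
growing from 5 toward 15 (monthly join probability 0.45), upset rate 0.1,
2 bouts per dyad per month, linear traits with `beta_ordinal = 1`,
`sigma = 1` — a signal-to-noise ratio of 1 per rank step — and
`beta_prop = 9`, which spreads the same per-step signal over the unit
proportional-rank interval at a typical hierarchy size of 10; 100
replicates per regime. `regime_recovery_experiment()` runs
simulate → infer → join → compare per replicate and reports how often the
classification matches the generating regime, and how often a metric is
both preferred and beats the null when no rank effect exists at all
(`beta = 0`).

What passing these experiments shows — and what it does not: the procedure
reliably identifies a *purely* density-dependent or density-independent
generating process at field-realistic sample sizes, with inferred (not
true) ranks, and rarely manufactures a preference under the null. Real
competitive landscapes are mixtures of the two regimes; real data add
demographic turnover beyond bottom-entry immigration (deaths, fissions,
rank reversals among residents), observation effort that varies across
dyads, and model misspecification. None of these are simulated, so a clean
recovery here does not certify the procedure's behavior under such
violations — it certifies the arithmetic and the wiring.

## Degenerate inputs and edge conventions

* Hierarchy of one: ordinal rank 1, proportional rank `NA` with a warning.
* All-zero win–loss matrix: every ordering is minimal; tie-breaks decide
  (prior order, then ids), inconsistencies 0.
* Empty bout set: an error unless a roster defines membership.
* A sex with no classified traits: its binomial test is emitted as missing;
  the Fisher contrast requires two sexes with classified traits.
* Ties in exact tests: an outcome whose probability equals the observed
  one's (up to a 1e-7 relative tolerance) is included in the p-value.

## Known limitations

* The ordering objective counts inconsistencies only; it does not weight
  them by how many bouts or how far apart the individuals are, and cardinal
  metrics (Elo, David's score) are out of scope by design.
* Above 8 individuals the ordering is a deterministic local optimum, not a
  certified global one.
* The divergence summary is a single correlation per individual; it flags
  that the metrics drifted apart but not when.
* Per-trait model families and covariate sets are user-specified
  configuration; the package does not guess them.
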