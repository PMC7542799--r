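# domrank

Dominance rank metrics and competitive regime inference for longitudinal
studies of social animals.

## The problem

Studies of how dominance rank predicts traits — physiology, injury risk,
reproductive performance — must pick a rank metric, and the common choices
embed opposite assumptions about competition:

* **Simple ordinal rank** `k` (1, 2, …, n; 1 = most dominant) assumes
  **density-dependent** competition: the resource base does not grow with
  hierarchy size, access works like a queue, and what matters is how many
  individuals are ranked above you.
* **Proportional (relative/standardized) rank** `1 − (k − 1)/(n − 1)` —
  the proportion of other hierarchy members you outrank — assumes
  **density-independent** competition: the resource base grows in
  proportion to hierarchy size, per-capita access is constant, and what
  matters is the fraction of the group below you.

At fixed hierarchy size the two are perfectly correlated; when hierarchy
size `n` varies across groups or over time, they diverge, and which one
better predicts a trait reveals the competitive regime shaping it.
`domrank` implements the full decision procedure for researchers with
long-term agonistic and trait data:

1. **Hierarchy inference** — monthly, sex-specific win–loss matrices from
   dyadic agonistic bouts, ordered to minimize entries below the matrix
   diagonal (exhaustive search up to 8 individuals, deterministic
   relocation descent above, with temporal-continuity tie-breaks).
2. **Rank metrics** — ordinal and proportional ranks per individual-month,
   maternal-rank assignment for immatures, and a divergence diagnostic for
   the two metrics' trajectories.
3. **Model comparison** — per trait, three models on an identical row set
   (ordinal term, proportional term, none), classified by AIC with the
   conventional |ΔAIC| ≥ 2 preference rule; tallies across traits tested
   with exact two-tailed binomial and two-sided Fisher tests.
4. **Regime simulator** — multi-group longitudinal bouts, hierarchies with
   bottom-joining immigrants and stochastic upsets, and traits generated
   under an explicitly density-dependent or density-independent resource
   curve (`R(n) = r1` vs `R(n) = r1·n`), for end-to-end validation.

## Worked example

Simulate two groups followed for a year under density-dependent
competition, re-infer the hierarchies from the bouts alone, and ask which
metric predicts the trait:

```r
library(domrank)
cfg <- sim_config(n_groups = 2, months = 12, seed = 42)
sim <- simulate_regime(cfg)

ranks <- build_ranks(sim$bouts)
ranks$orderings[[1]]
#> Hierarchy [2000-01 / G01 / male]: G01-I001 > G01-I002 > G01-I003 > G01-I004 > G01-I005 (inconsistencies: 0)
head(ranks$records)
#>   individual  period group  sex ordinal n proportional
#> 1   G01-I001 2000-01   G01 male       1 5         1.00
#> 2   G01-I002 2000-01   G01 male       2 5         0.75
#> 3   G01-I003 2000-01   G01 male       3 5         0.50
#> 4   G01-I004 2000-01   G01 male       4 5         0.25
#> 5   G01-I005 2000-01   G01 male       5 5         0.00
#> 6   G01-I001 2000-02   G01 male       1 5         1.00

dat <- merge(sim$latent[c("individual", "period", "group", "sex", "trait")],
             ranks$records, by = c("individual", "period", "group", "sex"))
compare_rank_metrics(dat, model_spec("trait", "gaussian",
                                     trait = "consortship index",
                                     sex = "male"))
#> Trait 'consortship index' (male): ORDINAL
#>   AIC ordinal 491.44 | proportional 563.87 | null 757.13 (n = 163)
#>   dAIC(ordinal - proportional) = -72.43; dAIC(best - null) = -265.68
```

The ordinal-rank model beats the proportional-rank model by 72 AIC units
and the null by 266 — the procedure correctly identifies the
density-dependent generator. Ranks here are *inferred* (upset rate 0.1), so
the comparison includes realistic rank-measurement error. With
`regime = "density_independent"` the same pipeline classifies the trait
PROPORTIONAL, and `regime_recovery_experiment()` repeats the loop over many
replicates and reports the recovery rate. `tally_and_test()` aggregates
classifications across traits: e.g. 7 of 7 male traits ordinal gives a
two-tailed binomial p = 0.015625, and a 7/0 vs 3/4 male/female split gives
a Fisher p = 0.0699.

A command-line interface wrapping the same functions ships at
`inst/cli/domrank.R` (`build-ranks`, `compare`, `simulate`, `recover`),
reading CSV bout/trait/rank tables and a JSON config.

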