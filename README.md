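# qmimic

Do people copy what the person ahead of them in the checkout queue just
bought? `qmimic` is an R package for answering that question from
timestamped point-of-sale logs, built for researchers studying social
influence on food choice (behavioural epidemiology, computational social
science, campus-nutrition studies).

Raw co-purchasing similarity confounds three things: imitation, similar
tastes among people who queue together (homophily), and the shared
day-and-shop context everyone faces (menus, weather, promotions). The
package implements a matched observational design that isolates the
first:

1. **Dyads.** Two different badge holders paying consecutively at the
   same register, same day and meal period, within 5 minutes, nobody in
   between; both must buy the period anchor (a meal at lunch, coffee or
   tea otherwise). Only user pairs observed together ≥ 10 times are
   kept.
2. **Matched pairs.** For each focus item, a treated dyad (partner
   bought it) is matched to a control dyad (partner did not) with the
   same partner, shop and period, the item on sale in both strata, and
   stratum popularity equal within a 10% caliper. Balance is reported as
   the standardized mean difference (balanced when SMD < 0.2).
3. **Paired estimation.** With `n11/n10/n01/n00` the matched-pair
   contingency cells,

       RD = (n10 − n01) / n        RR = (n11 + n10) / (n11 + n01)

   with percentile-bootstrap 95% CIs, and the McNemar statistic
   `(n10 − n01)² / (n10 + n01)` for the null of no treatment effect.
4. **Robustness.** A randomized-partner baseline (shared-context
   similarity only), a lag-binned dose–response fit of RD on queue lag,
   and Rosenbaum sensitivity bounds `Γ*` with the amplification
   `Γ = (ΛΔ + 1)/(Λ + Δ)`.
5. **Synthetic ground truth.** A seeded generator produces campus-like
   logs with eating profiles, homophilous co-queueing ties, day×shop
   context shocks and a planted additive mimicry effect `δ·e^(−lag/τ)`,
   recording every decision's counterfactual probabilities so the whole
   pipeline is testable without private data.

## Worked example

```r
library(qmimic)

sim <- simulate_purchase_log(sim_config(seed = 42))  # 200 users, 60 days
an  <- analyze_log(sim$log, sim$catalog, seed = 42)

unlist(an$funnel)
#>   transactions          dyads frequent_dyads eligible_dyads  matched_pairs
#>          13826           5755           5266           4710           2242

an$pooled_counts
#> paired 2x2 counts (n = 2242)
#>   both bought      n11 = 235
#>   treated only     n10 = 619
#>   control only     n01 = 238
#>   neither          n00 = 1150

an$pooled_estimate
#> RD = 0.1699 [0.1445, 0.1949]   RR = 1.805 [1.646, 1.983]   (n = 2242 pairs)

ground_truth_rd(sim$truth)      # the planted target rd*
#> [1] 0.15

rosenbaum_gamma(an$pooled_counts)
#> Rosenbaum sensitivity: gamma* = 2.289 at alpha = 0.05 (discordant 619 vs 238)
```

Reading: out of 13,826 simulated transactions, 5,266 dyads of frequent
queue pairs survive the filters and yield 2,242 matched pairs across the
13 item analyses. A partner's purchase raises the focal person's
purchase probability by about 17 percentage points (RR ≈ 1.8) against a
planted effect of 15 points — the small excess is residual
shared-context confounding, quantified and discussed in the methods
vignette (`vignettes/queue-mimicry.Rmd`). An unobserved within-pair bias
would need to more than double the odds of treatment (Γ* ≈ 2.3) to
explain the effect away.

The whole study — per-item estimates, subgroups, randomized baseline,
dose–response, sensitivity, JSON report — runs from one call:

```r
report <- run_study(list(sim = list(n_users = 200, n_days = 60),
                         seed = 42, out_dir = "out"))
```

A thin command-line wrapper ships in `inst/cli/qmim`
(`qmim simulate|validate|dyads|run`).

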