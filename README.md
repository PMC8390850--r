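# pansoc

Do male chimpanzees with strong social bonds sire more offspring — and if
so, through which routes? `pansoc` is an R package for analysts of
long-term primate (or other fission–fusion) behavioral data who want to go
from raw event logs — party arrivals, grooming bouts, pant-grunt
submission signals, coalitionary aggression, paternities, genetic
relatedness — to the full inference chain linking male sociality to
reproductive success.

## What it computes

**Sociality measures per one-year siring window** (the 365 days before a
conception, back-dated 226 days from birth). Dyadic association is a
Simple Ratio Index over first-of-day arrivals in parties of ≤ 4
individuals arriving ≤ 5 min apart:

```
SRI_ab = J_ab / (N_a + N_b − J_ab)
```

Grooming rates divide dyadic grooming minutes by focal co-presence
minutes, and the Composite Sociality Index averages mean-scaled SRI and
grooming rate (window mean CSI = 1). From these come 15 individual
measures — counts and sums of *strong* ties (strictly above the window
mean), top-3 CSI strength, grooming effort — each Z-standardized within
window, with the study's sampling filters (≥ 1800 min observed together,
> 20 qualifying arrivals, ≥ 600 focal minutes for rates).

**Dominance** via Elo scores on pant-grunts (recipient wins), with the
update constant `k` *and* per-male entry scores fitted by maximum
likelihood, queryable at any date; the top-scoring eligible male at
conception is the alpha.

**Inference**: binomial random-intercept GLMMs (adaptive Gauss–Hermite
quadrature via lme4) compared by small-sample-corrected AIC
(`AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1)`) with Akaike weights, an all-subsets
non-social null-model search with a nesting rule (models equal to a
better-supported model plus one term are pruned), variance-inflation
checks, an alpha-bond model set on events sired by subordinates, yearly
coalition networks (triads → three dyads, ≥ 8 dyads per year) with
betweenness regressed on strong-tie counts, and a symmetric binary-probit
social relations model of dyadic coalition formation (Gibbs sampler with
additive actor effects and Gelman–Rubin diagnostics).

**A synthetic community generator** with planted bond, rank and siring
effects closes the loop: every stage is validated by parameter recovery
on data whose truth is known.

## Worked example

```r
library(pansoc)

cfg <- sim_config(seed = 2026,
  siring_coefs = list(beta_rank = 0.5, beta_strong_ties = 0.5,
                      beta_alpha_csi = 0.8, beta_relatedness = -2))
report <- run_pipeline(config = cfg, select_null = FALSE,
                       model_sets = c("table1", "table2"),
                       quadrature_points = 1, seed = 2026)
print(report)
#> <pansoc_report>
#>   31 siring events, 403 design rows, null: relatedness + elo_z + age_z
#>   table1: best model 'Count of high CSI ties' (dAICc = -4.05)
#>   table2: best model 'CSI with alpha' (dAICc = -4.43)
#>   betweenness ~ strong ties: slope 2.862, F = 16.27
```

The Table-2-style comparison (alpha-bond models, non-alpha siring events)
and the odds ratios of its best model:

```r
report$comparisons$table2[1:4, ]
#>                                               model df  AICc  dAICc weight
#> 1                                    CSI with alpha  6 180.9 -4.432 0.3148
#> 2 CSI with alpha + count of strong association ties  7 182.1 -3.268 0.1760
#> 3                       Association rate with alpha  6 182.4 -2.924 0.1481
#> 4                          Grooming rate with alpha  6 182.8 -2.492 0.1193

tidy(attr(report$comparisons$table2, "fits")[[report$comparisons$table2$model[1]]])
#>               term odds.ratio or.conf.low or.conf.high
#> 1      (Intercept)     0.0689     0.03845        0.123
#> 2      relatedness     0.0731     0.00164        3.265
#> 3            elo_z     1.3083     0.71712        2.387
#> 4            age_z     0.6767     0.40290        1.137
#> 5 z_csi_with_alpha     1.8052     1.14708        2.841
```

Read: in this simulated community a one-SD stronger composite bond with
the alpha male raises a subordinate's per-event siring odds by ×1.8
(planted truth: ×2.2), after rank, age and relatedness. Negative `dAICc`
means the model outfits the non-social null. A single 31-event community
is noisy — which measure lands on top varies by seed; the systematic
recovery rates over 20 communities are what `recovery_experiment()` and
the acceptance script report. The coalition side of the same bonds shows
up as a strongly positive betweenness–strong-ties slope (F = 16.3 here).

`autoplot()` methods exist for comparison tables, Elo trajectories and
SRM posteriors; `tidy()`/`glance()` for every fitted object.

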