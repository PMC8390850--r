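---
title: "Measuring male social bonds and their reproductive payoff: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring male social bonds and their reproductive payoff: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pansoc` implements an analysis pipeline for a long-standing question in
behavioral ecology: do male chimpanzees that maintain strong social bonds
with other males sire more offspring, and if so through which mechanisms —
alpha concessions, coalitionary leverage, or both? This vignette documents
the statistical machinery, the choices that were genuinely open, and what
the simulation-based validation does and does not establish.

## The measurement layer

**Siring windows.** Each paternity defines an analysis window: conception
is back-dated from birth by the 226-day mean gestation of this population,
and the window spans the 365 days before conception (`start <= d <
conception`). Candidate sires are males alive, non-sterile, genotyped and
at least 11.0 years old at conception (ages use days/365.25). Events
missing four or more mother-by-candidate relatedness values are excluded;
with one to three missing values the event is retained and missing dyads
take the event-wise mean of the available candidate values (the exclusion
rule only states when to drop an event; the imputation is this package's
documented choice, and imputed values are flagged).

**Association.** Dyadic association is a Simple Ratio Index over
qualifying arrivals: first arrival of the day, in a party of at most four
individuals, with two males scored as arriving jointly when their flagged
arrivals are at most five minutes apart (shared presence at a follow start
is encoded as a zero-gap arrival pair). `SRI = J / (N_a + N_b - J)`. The
first-of-day restriction controls autocorrelation; the small-party
restriction makes co-arrival informative about partner choice. Dyads
observed together under 1800 minutes in a window, or with a member at 20
or fewer qualifying arrivals, are dropped from individual measures;
rate-based (grooming-rate and CSI) measures additionally require 600 focal
co-presence minutes.

**Strong ties.** A tie is strong when its value is strictly above the mean
over all same-window filter-passing dyads, zeros included. "Strictly
above" is the plain reading of "above the mean"; including zero-valued
dyads in the mean is the conservative variant (the alternative, means over
co-observed dyads only, can be obtained by pre-filtering the dyad table).

**Grooming and CSI.** Dyadic grooming rate divides dyadic grooming
minutes by focal co-presence minutes (grooming is only recorded on
focals). The individual grooming-rate denominator is the union — not the
sum — of each male's focal co-presence intervals with other males, so
overlapping party time is not double-counted. The composite sociality
index averages mean-scaled SRI and mean-scaled grooming rate, so the mean
CSI among included dyads is 1 by construction; when one component has a
zero window mean the CSI reduces to the other component, with a warning.
All individual measures are Z-standardized within window (sample SD,
`n - 1`), since community size varies between windows.

**Dominance.** Elo scores are computed from pant-grunts (the actor of
this formal submission signal loses; the recipient wins) with the
classical base-10 logistic expectation at scale 400, and the update
constant `k` plus per-individual entry scores fitted by maximum
likelihood (L-BFGS-B, three deterministic starts at k = 20, 100, 300;
entry scores centered at 1000 because the likelihood only sees score
differences). Scores at a date are the last post-update values strictly
before it; the alpha is the top-scoring eligible male at conception.

## Inference layer

**Model comparison.** Siring success is a binomial logit GLMM: one row
per candidate male per event, outcome 1 for the sire, random intercepts
for male identity, fitted by adaptive Gauss–Hermite quadrature (15 points
by default; 1 point = Laplace; on well-behaved data the two agree to well
under 0.1 log-likelihood unit). The information criterion is
`AICc = -2l + 2k + 2k(k+1)/(n - k - 1)` with `n` the number of design
rows and `k` the fixed effects (intercept included) plus one
random-intercept variance — both conventions documented rather than
asserted, since software differs. The non-social null is chosen by an
all-subsets search over relatedness, Elo score, age, age², and the count
of reproductive-age males, with a pruning rule: a model equal to a
better-supported model plus exactly one term is removed before the top
set (within 6 AICc points) is formed, because a pure-noise addition costs
about 2 AICc points and would otherwise linger in the top set. Sociality
measures are then added one at a time (15 measures; Table-1-style), and
the alpha-bond set (three bond-with-alpha measures, the strong-tie count,
and their combinations; 8 models, Table-2-style) is fitted on the events
sired by non-alpha males. Akaike weights are normalized within each
compared set.

**Coalitions.** Triadic coalitions count as three dyadic coalitions.
Calendar-year networks (binary edges; unweighted, unnormalized
betweenness — the original igraph call's weighting is not documented, so
a weighted variant sits behind a flag) are kept only when at least 8
distinct dyads formed coalitions. Betweenness is regressed by OLS on
within-year Z-scaled strong-tie counts.

**Dyadic probit SRM.** Coalition formation per dyad-year is modeled as
`z = x'b + a_i + a_j + e`, `y = 1{z > 0}`, with equal row and column
effects as appropriate for an undirected outcome — the additive part of
the AME framework; multiplicative latent factors are deliberately out of
scope. The Gibbs sampler uses truncated-normal latent draws, a conjugate
normal update for `b` (prior `N(0, 100 I)`), sequential updates for actor
effects with an inverse-gamma (2, 1) variance, and recenters actor
effects into the intercept each sweep for identifiability. Repeated dyads
across years are pooled with year-wise covariate standardization and one
actor effect per male — a documented stand-in for an unstated
repeated-observations likelihood. Individual covariates enter
symmetrically (dyad sums of scaled cardinal Elo; counts of prime 20–30 y
and old >30 y members). Convergence uses the potential scale reduction
factor `sqrt(((n-1)/n W + B/n)/W)`; identical chains give values within
5e-4 of 1 at the chain lengths used. Production chains of 90,000
iterations are supported, while tests and the acceptance harness run
reduced chains (1,500–3,000 iterations) that the convergence diagnostics
justify on these small, well-behaved problems.

## The synthetic community

Because the deposited field data are not required, every downstream stage
is validated against a generator that emulates the statistical structure
of the study population and records its latent truth. Defaults are 13
males, 20 females, 10 years, 300 follow-days per year. Conceptions arrive
at one per female per 5.5 years — the chimpanzee interbirth interval —
giving roughly 30–40 siring events per community.

Two weakly overlapping latent bond channels drive behavior: association
bonds shape arrival clusters (a daily random graph whose components
arrive together minutes apart, party size growing with each arrival) and
coalition rates; grooming affinities (15% shared with association bonds)
shape grooming hazards. The split is deliberate: in the real system
dyadic association and grooming correlate only weakly (R² below 0.1),
and a single shared bond variable would make the composite index nearly
collinear with its grooming component, rendering the alpha-bond model
comparison unidentifiable. Grooming is a Poisson process over focal
co-presence minutes with 8-minute exponential bouts, calibrated to the
observed regime of dyadic rates near half a percent of focal time.
Pant-grunt direction follows `P(i submits to j) = pnorm(a_j - a_i)` on
latent abilities. Coalitions are drawn per dyad-year at a base rate of
0.07 with a log-linear bonded boost of 2.5, yielding roughly 15–19 events
per year — inside the observed range — and a third actor joins 20% of
events.

Generation is two-pass: behavioral logs first, then the package's own
measurement pipeline computes each window's Elo standings (at the
generating `k`), strong-tie counts and CSI-with-alpha, and the sire is
drawn from a multinomial whose log-odds combine those measured statistics
with relatedness. Planting effects on measured statistics — not on
latent shortcuts — guarantees the signal lives in exactly the quantities
the analysis estimates. Default planted effects mirror the reported
effect-size regime (odds ratios near 1.6 per SD of strong-tie count and
1.4 per SD of alpha-CSI, a positive rank effect, inbreeding avoidance);
recovery experiments use round planted values (0.5; 0.8 for the
alpha-CSI term) chosen before any validation run and frozen.

What the generator does *not* emulate: demographic turnover (fixed
roster), female social structure, seasonality, observation-effort
heterogeneity between males, and rank dynamics (abilities are static, so
the maximum-likelihood `k` on community pant-grunt streams is correctly
driven toward its lower bound — entry scores absorb a static hierarchy;
`k`-recovery is therefore validated on self-consistent Elo streams, where
scores genuinely diffuse). Passing recovery tests shows the pipeline
detects effects of the planted kind at realistic sample sizes; it cannot
show robustness to the field complications listed above.

## Numerical and procedural choices

- Dates are ISO-8601 `Date`s; window membership is `start <= d < end`.
- Party size at arrival counts the party after the arriver joins (a lone
  pair counts as size 2).
- Grooming direction is ignored for duration and rate measures; dyads are
  unordered throughout.
- Z-standardization of a constant (or singleton) vector returns zeros
  with a warning rather than NaN.
- Missing standardized sociality values in the design table (dyads
  removed by the sampling filters, or the alpha's own bond-with-alpha)
  are imputed at 0 — the within-window mean — and counted in a message.
- Age² is the square of Z-scaled age (not the Z of the square); a toggle
  is unnecessary because the design table carries the raw age column.
- Replicate experiments fit the fixed non-social null (relatedness + Elo
  + age) rather than re-running the 32-model search per replicate, and
  default to Laplace fits; the search itself is validated separately.
  They may also reuse the generator's second-pass window metrics — the
  same package functions on the same logs — rather than recomputing
  them with a freshly fitted Elo.
- Problem sizes in tests and the acceptance harness: 20 simulated
  communities per recovery experiment, 2,000-event Elo streams, 2,000+
  dyad-year SRM recovery sets with reduced chains, 1,500-observation
  logistic fits for the one-extra-term AICc pattern (whose per-fit
  difference is distributed as `2 - chi-square(1)`; the pattern is
  checked on batch medians, which concentrate near 1.55).

## Known limitations

- The betweenness analysis inherits the sparse-network noise of yearly
  coalition graphs; slope signs are stable across communities, individual
  F statistics are not.
- The SRM omits multiplicative latent factors, so residual triadic
  structure in coalition formation is absorbed into actor effects.
- The strong-tie mean's scope (include or exclude never-co-observed
  dyads) changes tie counts in sparse data; the conservative default is
  documented above and the alternative is a one-line pre-filter.
- ML-Elo entry scores for males with few interactions are weakly
  identified; the entry bound (±1500) is a pragmatic guard, not a prior.
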