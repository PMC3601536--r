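---
title: "Measuring network integration from perceived and expected involvement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring network integration from perceived and expected involvement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netintegr)
```

## The measurement model

An integrated service network is a set of autonomous agencies that plan
and deliver services together. netintegr quantifies how integrated such a
network is by the *agreement* between two ordinal ratings every agency
gives about every other agency: the involvement it currently perceives,
and the involvement it believes should exist. Unlike measures that equate
more involvement with better integration, agreement is symmetric: an
agency that is far more involved than the group thinks necessary is as
poorly integrated as one that is far less involved.

The responses live in two square matrices, perceived `P` and expected
`E`, with the convention that cell `[i, j]` is agency *j*'s rating about
its involvement with agency *i*. A column is therefore one agency's
*self-ratings* and a row is the *group's ratings* about one agency.
Diagonal cells do not exist. For agency *X*, each partner *j* contributes
one rating pair per perspective:

* **P1** — `(P[X, j], E[X, j])`: does the group's perception of X match
  the group's expectation?
* **P2** — `(P[j, X], E[X, j])`: does X's own perception match the
  group's expectation?
* **P3** — `(P[X, j], E[j, X])`: does the group's perception match X's
  own expectation?
* **P4** — `(P[j, X], E[j, X])`: does X's perception match its own
  expectation?

The perspective score is the fraction of complete pairs that agree
**exactly** on the ordinal scale; `agency_scores()` also reports the
numerator and denominator. The four scores read together diagnose *who*
holds the misperception: a low P2 with a high P4, for instance, means X's
self-image is internally consistent but not shared by the group.

### Assumptions and conventions

* *Exact agreement.* Adjacent categories earn no credit. This is the
  natural reading of "agreed ratings" on a 5-point scale; a `tolerance`
  argument (`|difference| <= k`) exists for sensitivity analysis but
  defaults to 0.
* *Pairwise deletion.* A pair with either member missing enters neither
  count. No imputation is attempted: a non-respondent simply has no P2–P4,
  while P1 survives on the group's row of ratings — the asymmetry one
  observes in real surveys.
* *Representative averaging.* When an agency fields several
  representatives, their ratings per directed pair are averaged and
  rounded to the nearest integer before any scoring
  (`collapse_representatives()`). "Nearest integer" leaves .5 ties
  unspecified; we round half away from zero (3.5 → 4) because it treats
  the scale ends symmetrically, and expose `ties = "even"` for the
  alternative.
* *Scale bounds.* The instrument is a 5-point scale coded 1–5 here;
  `bounds` is configurable (e.g. `c(0, 4)`) since variants of the
  instrument differ in coding, and validation uses the configured bounds.

## Global scores and their uncertainty

The global integration score for one perspective is the mean of the
defined agency scores. For P1 that includes every agency; for P2–P4 it is
respondents-only by construction (complete-case, not a modelling choice).
Geometrically the mean is the filled fraction of the integration-area
diagram: sort the agencies by score, give each an equal width on the unit
axis, and fill under the profile (`integration_area_plot()`; the filled
fraction equals the mean exactly, which the tests verify against a
polygon-area computation). The blank remainder is the integration gap.

Because the paper trail behind the original interval formulas is not part
of this package's sources, the interval choices are our own and are stated
here once:

* **mean**: normal approximation `mean ± z·sd/√n`, clipped to `[0, 1]`;
  degenerate (zero-width) when all scores coincide; undefined for a
  single score.
* **weighted**: inverse-variance weights `w_i = 1/var_i` with
  `var_i = p̃_i(1−p̃_i)/valid_i` and the shrunken proportion
  `p̃_i = (agreed_i + ½)/(valid_i + 1)`. The shrinkage (a Jeffreys-style
  half-count) only enters the *weight*, never the reported score; without
  it an agency scoring exactly 0 or 1 would get infinite weight and
  swallow the network. Interval `estimate ± z·√(1/Σw)`, clipped.
* **bootstrap** (three schemes, all resampling the *agency scores* — the
  unit of analysis throughout — never the underlying rating pairs):
  * *standard*: B i.i.d. resamples of size n; bias-corrected point
    estimate `2·mean − mean(replicates)`; BCa interval.
  * *balanced*: B copies of the score vector concatenated, permuted once,
    cut into B consecutive blocks. Every score appears exactly B times
    across the resamples, so the grand replicate mean equals the sample
    mean exactly — a variance-reduction device; point and interval as for
    standard.
  * *Bayesian*: per replicate, flat-Dirichlet weights drawn as
    sorted-uniform spacings; the replicate is the weighted mean. The point
    estimate is the posterior mean and the interval the central
    percentile credibility interval.

### BCa details

The BCa interval adjusts the percentile interval for bias and skewness.
Numerical choices, all covered by a frozen-value test against an
independent implementation:

* the bias correction uses the *strictly-less* proportion of replicate
  means below the sample mean, clamped to `[1/(B+1), B/(B+1)]` before the
  normal quantile so ties can never produce an infinite z0;
* if every replicate mean falls on one side of the sample mean the
  correction is unusable, and the plain percentile interval is returned
  with a warning;
* the acceleration is the jackknife skewness of the leave-one-out means
  of the original scores (not of the replicates);
* empirical quantiles use R's default type-7 interpolation;
* if all replicate means equal the sample mean the interval collapses to
  that point.

The point estimate reported for the standard and balanced schemes is the
classical bias-corrected `2·θ̂ − mean(θ*)`, not a median-adjusted value —
a deliberate, flagged choice.

Defaults: `B = 40000` and `confidence = 0.95`. At `B = 40000` the three
bootstrap points and the plain mean agree to well under one percentage
point, and dropping to `B = 500` moves the estimate only in the third
decimal place — the suite asserts both on a 30-agency simulated network.
`B < 100` is rejected outright: percentile-type endpoints from fewer
replicates are noise. Bootstrap seeds are explicit arguments; the same
seed and inputs reproduce replicate means bit-identically, and
`global_table()` derives one deterministic seed per perspective-method
cell from its base seed.

## What the synthetic generator does and does not emulate

`simulate_network()` exists so every estimator can be validated against
known truth; no survey data ship with the package.

* **independent** model: each off-diagonal cell draws its expected rating
  from `rating_distribution` (default uniform over the 5 categories);
  with probability `agreement_prob` the perceived rating copies it,
  otherwise it is uniform over the other four categories. Same-cell
  agreement — hence the expected P1 and P4 — is `agreement_prob` by
  construction; P2/P3 pair ratings from two independent cells, so their
  expected agreement is the cross-product of the perceived and expected
  marginals. `expected_scores()` computes all four by enumerating the
  5×5 category lattice rather than by simulation.
* **consensus** model: one latent true rating per dyad; each of the four
  reports touching the dyad deviates from it with probability
  `consensus_noise` (uniform over the other categories). All four
  perspectives then share the expected agreement
  `(1−ν)² + ν²/4` for uniform deviations.
* Non-response is independent Bernoulli per agency (`response_rate`,
  default 1; the rates observed in the two motivating surveys, 0.89 and
  0.64, are natural presets) and blanks the agency's column in both
  matrices.

Deliberately **not** modelled: dyadic reciprocity correlation (real
partners' views of each other correlate), sector structure, informative
non-response (poorly integrated agencies are plausibly likelier to skip
the survey), item non-response within a respondent (supported by the data
model and the scoring, just not generated), halo and end-aversion
response styles, and distance-weighted disagreement (disagreeing ratings
land uniformly, not preferentially on adjacent categories — an ordinal-
proximity variant would be easy but has nothing to be validated against).
Passing tests therefore show that the estimators recover the parameters
of *these* generative models, not that the instrument itself is unbiased
on real networks.

## Validation strategy and problem sizes

The test suite works at desk scale, chosen so the whole suite runs in
about a minute: scoring is verified pair-for-pair against a brute-force
enumeration oracle on 200 random 3–6 agency networks with random
missingness; the worked 4-agency example and the 80%-of-raters scenario
are asserted exactly; estimator concordance uses one 30-agency network at
`B = 40000`; interval calibration uses 100 simulated 30-agency networks
(the 95% CI for the P1 global mean must cover the generator's agreement
probability in at least 90 of them); and the BCa endpoints are checked to
10 digits against values frozen from an independent implementation of the
same formulas.

## Degenerate inputs and edge rules

* Networks need at least 2 agencies; bootstrap needs at least 2 defined
  scores.
* All-equal scores: every estimator returns the common value with a
  zero-width interval.
* A score of exactly 0 or 1 is reported as such everywhere; only the
  weighted estimator's variance sees the shrunken proportion.
* Estimates and interval endpoints are clipped to `[0, 1]` after
  computation (relevant for the bias-corrected point and normal
  intervals near the boundary).
* `rating_pair` equality note: when perceived and expected matrices are
  cell-for-cell identical, P1 and P4 are exactly 100%; P2 and P3 compare
  cell `[j, X]` with cell `[X, j]` and reach 100% only if the shared
  matrix is also symmetric.

## Known limitations

The scores are proportions of small denominators (n−1 pairs at best), so
individual agency scores are coarse — the weighted global estimator
exists precisely because their precisions differ. The normal-approximation
intervals can be anti-conservative for extreme scores at small n; the BCa
interval is preferred there. Agreement is chance-uncorrected by design
(a kappa-style correction answers a different question and is out of
scope), and the method measures integration among the planning group that
fills in the instrument, not necessarily integration in frontline
practice.
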