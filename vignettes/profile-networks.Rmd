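---
title: "Profile enumeration and within-profile symptom networks: methods"
author: "symptomnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile enumeration and within-profile symptom networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The problem

Polythetic diagnostic rules admit many symptom combinations under one
label. For a nine-item instrument scored 0–3 with a clinical cutoff of 10
(the PHQ-9 convention), any profile with at least four present symptoms
*can* reach the cutoff, giving $\sum_{r=4}^{9} \binom{9}{r} = 382$
theoretically possible dichotomized profiles; a DSM-style rule (at least
five of nine symptoms, at least one of them a core symptom) admits 227.
`symptomnet` implements the full analysis cycle around this combinatorial
fact: enumerate the catalog, match respondents to profiles, and model the
interplay of symptoms *within* each prevalent profile as a
partial-correlation network.

## Profile catalog

A symptom is coded present when its item scores 1 or more. Under the
threshold rule a profile is eligible when its maximum achievable total
(present items at the maximum score, absent at zero) reaches the cutoff —
the only reading that reproduces the 382 count. Enumeration is exhaustive
over all $2^k$ patterns (supported to $k = 24$) and is cross-checkable
against the closed-form binomial sum; both routes are exposed
(`enumerate_profiles()`, `count_profiles()`).

Catalog IDs follow a canonical, fully deterministic order — descending
symptom count, then ascending lexicographic pattern with item 1 most
significant — so ID 1 is the all-present profile and IDs are stable
across runs and cohorts. The sample-dependent *frequency rank* produced by
`profile_frequencies()` is deliberately a separate number: theoretical
identity and empirical prevalence should not be conflated.

## Cohorts

`load_responses()` performs listwise exclusion of respondents with any
missing or out-of-range item (imputation would inject modelling choices
into a descriptive step; exclusion counts are logged and reported).
Inclusion uses the raw total score (PHQ-9 ≥ 10), not the dichotomized
count. Frequency-rank ties break by ascending catalog ID. Covariates are
pass-through descriptives only, never inputs to estimation. A convenience
severity banding follows the instrument's published labels (moderate up
to 14, moderately severe 15–19, severe 20+); some of the literature splits
the lower edge differently, which is why the band is a reporting column
and never a filter.

## Network estimation

Within a profile, every member shares the same presence pattern, so absent
items are constant zero; they are removed (a Gaussian graphical model is
undefined for constant variables) and recorded, and each profile network
spans exactly its present symptoms. Input associations are Pearson
correlations on the raw 0–3 scores; a polychoric option is deliberately
omitted to keep the estimator aligned with the continuous-input
convention of the within-profile analysis.

The regularized estimator solves the L1-penalized Gaussian likelihood by
block coordinate descent (compiled via RcppArmadillo) along 100
log-spaced penalties from $\lambda_{\max}$ (the largest absolute
off-diagonal correlation, where the network is empty) down to
$0.01\,\lambda_{\max}$; the reference convention of interpreting the
published "$\lambda = 0.01$" as the path's minimum ratio is adopted, since
a fixed penalty of 0.01 would make EBIC model selection vacuous. The
penalty is not applied to the precision diagonal.

**Model selection.** Each distinct sparsity pattern appearing along the
path is scored by
$\mathrm{EBIC} = -2\ell + E\log n + 4\gamma E\log p$ ($\gamma = 0.5$)
evaluated at the pattern's *unpenalized constrained maximum-likelihood
refit* (a relaxed graphical lasso). Scoring the penalized estimates
directly makes the criterion pay for shrinkage on strong true edges and
drags selection toward dense models; with refit scoring, the selected
support agrees with an exhaustive search over all sparsity patterns
(each refit by constrained ML) on small problems — a property the test
suite asserts with an independent pure-R implementation of that
exhaustive oracle. Exact EBIC ties resolve toward the sparser support,
then the larger penalty: conservative selection. Reported edge weights
are the refit partial correlations. Path points that fail to converge or
produce a non-positive-definite precision are flagged and skipped with a
warning; if none survives, estimation errors out (and the pipeline falls
back, below).

**Non-regularized fallback.** For subsamples where the path fails, the
fallback inverts the correlation matrix and keeps each edge whose
partial correlation rejects under a Fisher-z test of order $p - 2$
(effective sample size $n - (p - 2)$, i.e.
$z = \operatorname{atanh}(r)\sqrt{n - p - 1}$) at a two-sided 0.05
level, with no multiplicity correction — intentionally matching the
"0.05 null threshold" convention rather than a corrected test. With
$\alpha = 1$ this reproduces the full inversion partial correlations to
numerical precision, which the tests check at $10^{-10}$.

Estimation refuses subsamples below 10 members and warns below 100, where
small-sample instability is expected. Strength centrality sums absolute
incident edge weights; standardization is a z-score across items (flagged
as undefined when all strengths are equal); rank ties break by item
order. Layouts are weighted Fruchterman–Reingold (igraph), rescaled to
the unit square, and deterministic given their seed.

## Stability

Edge accuracy uses a nonparametric bootstrap: resamples of the original
size drawn with replacement, the network re-estimated with the identical
configuration, and per-edge means with 2.5/97.5 percentile intervals.
Centrality stability uses the case-dropping subset bootstrap over the
grid 0.05–0.75 in steps of 0.05 (the CS coefficient is conventionally
reported up to 75% dropped); for each proportion, subsamples without
replacement of size $\mathrm{round}((1 - q)\,n)$ are re-estimated and the
Pearson correlation of their strength vector with the full-sample
strengths recorded. CS is the largest proportion keeping at least 95% of
that distribution at or above 0.7; it is 0 when no proportion qualifies
and undefined (with diagnostics) when no proportion yields any usable
resample. Correlations are computed on raw strengths — standardization is
an affine map per vector and leaves Pearson unchanged, while raw values
avoid zero-variance corner cases. Failed re-estimations are excluded from
the distribution rather than scored as failures, and their counts are
reported so the choice is auditable. The default of 1,000 resamples
matches common practice; analyses in the test suite scale it to 200.

## Synthetic cohorts and what they show

The generator plants a mixture of subpopulations, each with a fixed
profile, a mixing weight, and a ground-truth partial-correlation network
over its present items (validated positive definite after conversion to a
unit-diagonal precision; latent variances are fixed at one so all
association structure lives in the precision matrix, making ground truth
directly comparable with estimates). Latent multivariate-normal draws are
discretized through per-item thresholds into scores 1..3 — **never 0** —
so a generated respondent's dichotomized pattern equals its planted
profile exactly. This is deliberate: profile identification and network
estimation are tested separately, and a noisy-membership mode is out of
scope. Default thresholds are standard-normal tertiles (equal mass on
scores 1, 2, 3), configurable per item to emulate skewed marginals such
as rare suicidal ideation. `inclusion_rate()` gives the exact pass
probability of the threshold filter under latent independence (convolution
of the per-item score distributions); under a correlated ground truth the
item marginals remain exact and the rate is a close approximation.

What the generator does *not* emulate: empirical item marginals of any
real survey (no public accession exists for the motivating cohorts),
measurement error in symptom presence, per-item score ranges other than a
common maximum, and longitudinal dependence. Passing tests therefore
demonstrate that the pipeline recovers known structure from data shaped
like ordinal questionnaire responses — not that any particular empirical
cohort's profile frequencies or edge weights are reproduced. Quantities
such as "167 of 382 profiles observed" or specific CS values are sample
statistics of unavailable survey data and are intentionally absent from
the test expectations.

## Validation conditions

The test suite fixes its study conditions as follows: oracle-equivalence
checks run at $p \in \{3, 4\}$, $n = 1000$, planted edges of 0.3–0.4;
ground-truth recovery at $k = 9$, $n = 2000$, eight planted edges of
0.25–0.35 (tertile thresholds); the stability/sample-size study compares
$n = 2000$ against $n = 150$ over ten seed pairs with 200 resamples per
drop proportion; and the structural end-to-end run plants the three
headline profiles (all nine symptoms; all but item 9; all but items 8–9)
in a 1,500-respondent cohort. Every stochastic step takes an explicit
seed; the pipeline derives per-stage seeds from its global seed by a
Lehmer sequence modulo $2^{31}-1$, so stages can be rerun in isolation
with identical results, and full runs are bit-reproducible.

## Known limitations

Pearson correlations on 3-level ordinal scores attenuate latent
associations, so recovered edge weights are biased toward zero even when
the support is recovered exactly; comparisons across profiles of equal
scale are unaffected, but absolute weights should be read with this in
mind. The non-regularized fallback inherits the usual caveats of
unpenalized inversion near singularity. Directed, temporal, and
cross-profile comparison tests are out of scope, as are centrality
indices other than strength.
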