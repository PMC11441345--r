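# symptomnet

Depression — like most questionnaire-defined syndromes — is diagnosed by a
rule that many different symptom combinations can satisfy. On the PHQ-9
(nine items, each scored 0–3, clinical cutoff at a total of 10), **382**
distinct presence/absence symptom profiles can reach the cutoff, yet
empirical cohorts concentrate on a handful of them, and the symptoms inside
each profile interact differently. `symptomnet` is an R package for
studying exactly this heterogeneity: it enumerates the theoretical profile
catalog, matches respondents to profiles, and estimates a within-profile
**partial-correlation symptom network** for each prevalent profile, with
bootstrap diagnostics for how stable those networks are.

It is aimed at researchers in network psychometrics and psychiatric
epidemiology who have item-level questionnaire data (or want to simulate
it) and need a reproducible profile-then-network pipeline.

## The model

Within a profile's subsample, item scores are modelled with a Gaussian
graphical model (a pairwise Markov random field): nodes are symptoms,
and an edge carries the partial correlation

$$pr_{ij} = -\kappa_{ij} / \sqrt{\kappa_{ii}\,\kappa_{jj}},$$

where $\kappa$ is the precision (inverse covariance) matrix. Sparse
networks are estimated by the graphical lasso over a 100-point log-spaced
penalty path (smallest penalty = 0.01 of the largest), with the model
selected by the extended Bayesian information criterion

$$\mathrm{EBIC} = -2\ell + E\log n + 4\gamma E \log p, \qquad \gamma = 0.5,$$

where $E$ is the number of edges. Candidate sparsity patterns proposed by
the path are scored by the EBIC of their unpenalized constrained
maximum-likelihood refits, so selection is not biased by shrinkage on
strong edges. For small subsamples where the regularized path fails,
a non-regularized fallback keeps every partial correlation whose Fisher-z
test rejects at a 0.05 level. Node importance is summarized by strength
centrality (sum of absolute incident edge weights), and its robustness by
nonparametric bootstrap edge intervals and the case-dropping
correlation-stability (CS) coefficient: the largest share of cases that
can be dropped while the subsample centralities keep a correlation of at
least 0.7 with the full-sample centralities with 95% probability
(interpretable above 0.25).

## Worked example

A synthetic cohort with three planted profiles (all nine symptoms; all but
suicidal ideation; all but suicidal ideation and psychomotor changes),
mixed 0.5/0.3/0.2, run end to end:

```r
library(symptomnet)

chain <- function(p, w) {
  m <- matrix(0, p, p)
  for (i in seq_len(p - 1)) m[i, i + 1] <- m[i + 1, i] <- w
  m
}
spec <- synthetic_spec(1500, list(
  subpopulation(rep(1, 9), weight = 0.5,
                pcor = random_sparse_pcor(9, 8, c(0.2, 0.35), seed = 1)),
  subpopulation(c(rep(1, 8), 0), weight = 0.3, pcor = chain(8, 0.25)),
  subpopulation(c(rep(1, 7), 0, 0), weight = 0.2, pcor = chain(7, 0.25))),
  seed = 2024)
cohort <- sample_cohort(spec)
report <- run_pipeline(pipeline_config(cohort, selectors = 1:3, seed = 7,
                                       verbose = FALSE))
print(report)
```

```
# Symptom profile network analysis

- Theoretical catalog size: 382
- Respondents read: 1500 (invalid rows excluded: 0)
- Included respondents: 1482
- Distinct observed profiles: 3
- Coverage: top 3 profiles account for 100.0% of included cases

## Profile rank 1 (catalog ID 1, pattern 111111111)
- n = 749; estimator: ebic_glasso
- Items in network: 9; strongest symptoms: phq6, phq1, phq8

## Profile rank 2 (catalog ID 10, pattern 111111110)
- n = 458; estimator: ebic_glasso
- Items in network: 8; strongest symptoms: phq5, phq4, phq7

## Profile rank 3 (catalog ID 46, pattern 111111100)
- n = 275; estimator: ebic_glasso
- Items in network: 7; strongest symptoms: phq4, phq5, phq1
```

Reading the output: 382 is the size of the theoretical catalog of
dichotomized profiles that can reach PHQ-9 ≥ 10; 1,482 of 1,500 simulated
respondents pass the cutoff; the three planted profiles surface as
frequency ranks 1–3 with percents near their mixing weights; and each
profile's network spans exactly its present symptoms (9, 8, and 7 nodes —
absent symptoms are constant zero in the subsample and are dropped).
`summary(report$profiles[[1]]$network)` prints the edge list and strength
centrality table; adding `boot = boot_config()` to the configuration
appends edge-accuracy intervals and the CS coefficient per profile.

Real data enters through `load_responses("cohort.csv")` (item columns
`phq1..phq9` by default), and every stage is also callable on its own:
`enumerate_profiles()`, `match_profiles()`, `profile_frequencies()`,
`symptom_network()`, `network_stability()`.

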