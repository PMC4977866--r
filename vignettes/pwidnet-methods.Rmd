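---
title: "Methods: combined regression and correlation-network analysis of needle-sharing risk factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined regression and correlation-network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis in one paragraph

`pwidnet` reanalyses a categorical risk-factor survey of people who inject
drugs (PWID) in which roughly 37.5% of 1,049 participants reported ever
sharing needles. Two complementary machines are combined. The *regression*
machine asks which factors predict sharing: a univariate odds-ratio screen
per factor, candidate selection at p < 0.05, and a multivariate logistic
model whose adjusted odds ratios identify independent predictors. The
*network* machine asks how factors co-vary within each behavioural subgroup:
participants are split into a never-sharing group (NSNG) and a sharing group
(SNG), factor-by-factor correlations are computed within each subgroup, and
pairs with |r| > 0.1 and p < 0.05 become edges of a correlation network whose
global topology, node centralities, and dense modules are then examined. The
final rule intersects the two: a *key factor* is one that is prominent
(above-average betweenness and closeness centrality) only in the sharing
group's network *and* independently associated with sharing in the
regression. On the published tables this nominates HIV serostatus.

## Survey data model

A dataset is a subject-by-factor table of category labels plus a binary
outcome, validated against a codebook that fixes each factor's ordered
categories, reference category, and thematic role (sociodemographic, drug
use, sexual/infectious). Records with missing or illegal values are rejected
outright — the study population was defined by complete questionnaires, and
imputation would manufacture data the model then treats as observed. Labels
are matched case-sensitively after whitespace trimming so validation is
deterministic. The "Unknown" level of the other-infectious-diseases factor is
an ordinary first-class category: the published analysis models it as its own
level rather than as missingness.

## Regression machinery

For category *k* against the reference, the odds ratio is the cross-product
ratio `(a_k d_ref) / (b_k c_ref)` of the 2x2 sub-table, with the Woolf
interval `exp(ln OR ± 1.959964 * sqrt(1/a + 1/b + 1/c + 1/d))` and a Wald
p-value from the normal deviate of `ln OR / SE`. The z quantile is fixed at
1.959964 so printed intervals reproduce exactly rather than drifting with a
runtime `qnorm()` call.

The factor-level omnibus p-value is a likelihood-ratio (G) test of the
K-level factor against the intercept-only binomial model. For a single
categorical predictor this equals the logistic-regression LRT and has a
closed form from the contingency table, which also makes the 500-replicate
null simulations in the tests cheap. The LRT was chosen over a Wald or score
omnibus because it is invariant to category coding; on the published counts
it selects exactly the 15 printed candidate factors at alpha = 0.05, although
its extreme tail p-values differ from the printed ones in magnitude (both are
far beyond any decision threshold).

Zero cells flag a contrast as unestimable instead of triggering a continuity
correction: none occur in the published table, and a silent +0.5 would change
printed values elsewhere. The multivariate model enters every selected factor
as a full treatment-coded indicator set with no stepwise pruning; the
published table reports adjusted odds ratios for only the six factors that
survive, which emerges here from fitting all candidates and flagging
factor-level significance (any non-reference category with adjusted Wald
p < 0.05). Perfect separation raises an error naming the offending factor;
non-convergence is reported and estimates withheld.

## Correlation networks

Factors are encoded as 0-based ordinal codes in printed category order.
Nominal factors (residence, ethnicity, occupation, marital status, drug of
choice, source of syringe) have no natural order; coding them in printed
order is an explicit, documented convention — any rank coding of a nominal
factor is arbitrary, and conclusions about individual nominal-factor edges
should be read with that in mind.

The default correlation is Spearman's rank coefficient (the factors are
mostly ordered categories); Pearson is available by flag. P-values use the t
approximation on n - 2 degrees of freedom. Edges require *strictly*
|r| > 0.1 and p < 0.05; no multiple-testing correction is applied, matching
the source analysis. Factors with no surviving edge are excluded from the
node set — this is what removes occupation from the never-sharing network —
but remain in the network's "universe" so downstream tables can mark them
*not included* rather than zero.

Global statistics follow the conventions of the network-analyzer tooling the
source analysis used:

* density `2E/(N(N-1))` and average neighbours `2E/N` (closed-form
  identities on the printed node/edge counts);
* diameter and characteristic path length over *connected* pairs only;
* clustering coefficient as the mean local clustering over nodes of degree
  >= 2;
* heterogeneity as the coefficient of variation of the degree sequence;
* Freeman degree centralization `(N/(N-2)) (max_deg/(N-1) - density)`.

The degree >= 2 restriction matters numerically: on sparse random graphs it
excludes nodes whose local clustering is undefined instead of counting them
as zero, which is why a random-ensemble clustering mean can sit at (or even
above) the edge-density baseline.

## The Erdős–Rényi null model

The null ensemble draws uniform simple graphs with *exactly* the empirical
node and edge counts — the G(n, m) variant, since G(n, p) matches the edge
count only in expectation. Each of 1,000 replicates is summarised with the
same global-statistic conventions as the empirical network, disconnected
replicates included (path length over connected pairs). Empirical one-sided
p-values use the add-one formulation `(1 + #{replicates >= observed}) /
(reps + 1)` so a value beyond every replicate reports 1/1001 rather than 0,
and the non-randomness verdict uses p < 0.01.

The "±" quoted alongside published ensemble means is treated as the standard
error of the ensemble mean: at n ≈ 19 the per-replicate standard deviation
of the clustering coefficient is ~0.07, thirty-five times the quoted ±0.002,
while the SEM over 1,000 replicates reproduces it. Both are reported. For the
matched G(19, 38) ensemble this package computes a mean clustering
coefficient of ~0.222 (SEM ~0.002), consistent with the published random-
network value; for the denser G(20, 65) ensemble the computed mean (~0.340)
sits close to the edge density, and the published 0.364 suggests the original
toolchain used a slightly different local-clustering average for that case —
the exact convention is not stated in the source, so only the sparser
ensemble is used as a quantitative anchor.

## Centralities, above-average flags, and MCODE

Centralities are computed on the unweighted skeleton: the published values
are classic normalized betweenness/closeness, and correlation magnitudes are
not distances. Betweenness is normalized by `(N-1)(N-2)/2`; closeness on a
disconnected graph is within-component closeness scaled by
`(component size - 1)/(N - 1)`, degrading gracefully instead of collapsing
to zero. Ranks share tied values (min convention), reproducing the printed
ties. "Above average" means strictly greater than the arithmetic mean over
included nodes; excluded nodes enter neither the mean nor the flag sets.

Module detection reimplements the MCODE algorithm: each vertex is weighted
by the density of the highest k-core of its closed neighbourhood times that
core's k (vertices under the degree cutoff score 0); complexes grow greedily
from the highest-weight unused seed, admitting neighbours whose weight is at
least `seed weight * (1 - node_score_cutoff)`; complexes without a 2-core
are discarded. Defaults are node score cutoff 0.2, degree cutoff 2, k-core
2, max depth 100, with the haircut and fluff post-processing steps exposed
but off. Ties are broken lexicographically by node name, making the output
deterministic. One behavioural consequence worth knowing: two equally dense
cliques joined by a single bridge merge into one complex, because both
bridge endpoints carry full clique weight and pass any admission threshold
below 1 — the greedy expansion has no penalty for crossing a sparse cut.

## The synthetic-survey generator

No subject-level data are distributed with the study, so the pipeline is
exercised on a generator that emulates its statistical structure. Each
subject's factor categories are drawn by thresholding a correlated latent
Gaussian vector at the cumulative-marginal quantiles (a Gaussian copula over
the ordinal codes) — a dependence mechanism chosen because it preserves the
marginals exactly while exposing a single correlation matrix, which is
precisely the quantity the network stage measures. The outcome is Bernoulli
with logit equal to an intercept plus per-category log-odds increments, the
same functional form the regression stage fits, so parameter recovery is a
meaningful test.

The default parameters (`default_yunnan_params()`) set:

* marginals to the published per-category totals divided by 1,049;
* outcome increments to the log of the published multivariate odds ratios
  for the six independently associated factors (zero elsewhere, zero for
  reference categories);
* the intercept by a one-dimensional root find so the expected prevalence
  equals 393/1,049, solved against a fixed-seed Monte-Carlo draw (100,000
  samples) of the summed increments under the copula — the joint law of the
  six effect-bearing factors has no convenient closed form once they are
  correlated;
* a latent correlation of 0.2 between factors sharing a thematic role and 0
  across roles. This block structure is an explicitly labelled fabrication:
  the source reports only thresholded edges, never correlation magnitudes,
  so the default is chosen to give the network stage recoverable structure
  at realistic survey sizes, not to estimate the real dependence.

A non-positive-semidefinite latent correlation is refused loudly rather than
repaired: silently projecting to the nearest PSD matrix would invalidate the
correlation-recovery tests that treat the matrix as ground truth. All
sampling is threaded through one seeded generator; identical seeds give
byte-identical datasets.

What passing tests show — and do not show. The generator reproduces
marginals, a logistic outcome, and copula dependence. Real questionnaire
data have features it deliberately lacks: cluster effects by recruitment
site, response biases correlated with the outcome, logically entangled
categories (duration of abuse vs duration of injection), and dependence that
is not well described by a single Gaussian copula. Pipeline correctness and
operating characteristics (coverage, type-I error) transfer to real data;
the specific edge sets and centrality orderings of the synthetic networks do
not.

## Problem sizes and numerical choices

The test suite runs marginal checks at n = 50,000, prevalence calibration
checks at n = 200,000, multivariate parameter recovery on 20 replicates of
n = 20,000 (pooled 95% Wald coverage required >= 90%), null-size simulations
at 500 replicates of n = 300, and ensemble checks at 1,000 replicates —
sizes at which binomial standard errors make the assertions sharp without
making the suite slow. Brute-force oracles (Floyd–Warshall distances,
explicit shortest-path enumeration, naive tally loops, hand-written
likelihood maximization) are kept to <= 10-node graphs and <= 5,000-row
fits, where exhaustive computation is trivially fast and shares no code with
the implementation it checks.

Tolerances: printed odds ratios and intervals are matched to ±0.1 (one unit
in the last printed digit); closed-form identities to 5e-4; the stochastic
ensemble mean to ±0.02; oracle equivalences to 1e-12 (pure arithmetic) or
1e-6 (independent optimizer).

## Known limitations

* The real correlation matrices are unpublished, so the synthetic networks
  are structurally plausible but not reproductions; only printed-table
  quantities and analytic identities are verified against the study.
* Rank-coding nominal factors makes their edge signs convention-dependent.
* The multivariate refit of all 15 candidates need not match a fit of only
  the six surviving factors, and the source does not state which was done.
* No survey weights, clustering, or longitudinal structure; the source
  analysis used none.
* The "acts faster in the sharing group" interpretation of shorter path
  lengths is reported as the computed statistics plus a threshold verdict;
  no intervention dynamics are modelled.
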