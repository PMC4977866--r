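# pwidnet

Combined regression and correlation-network analysis of needle-sharing risk
factors among people who inject drugs (PWID).

## The problem

Needle and syringe sharing is the main route by which blood-borne infections
(HIV, viral hepatitis) spread among PWID. Classical logistic regression
identifies which factors *predict* sharing, but says nothing about how risk
factors *co-vary* within behavioural subgroups — information that matters
when a harm-reduction programme must pick a small, reachable target group.
`pwidnet` implements a combined analysis for categorical risk-factor surveys:

1. **Regression.** For each factor, a univariate odds-ratio screen: per
   category *k* vs the reference, `OR = (a_k d_ref)/(b_k c_ref)` with the
   Woolf 95% interval `exp(ln OR ± 1.96 √(1/a + 1/b + 1/c + 1/d))`, plus a
   likelihood-ratio omnibus p per factor. Factors with p < 0.05 enter a
   multivariate logistic model (treatment coding, full indicator sets);
   adjusted odds ratios flag independent predictors.
2. **Networks.** Subjects are split into never-sharing (NSNG) and sharing
   (SNG) groups. Within each group, Spearman correlations between
   ordinal-coded factors define a network: edges where |r| > 0.1 and
   p < 0.05. Global topology (density, diameter, clustering, characteristic
   path length, heterogeneity, centralization) is compared against 1,000
   Erdős–Rényi G(n, m) random graphs with matched node and edge counts;
   node importance is measured by normalized betweenness (BC) and closeness
   (CC) centralities, and dense modules are found with an implementation of
   the MCODE algorithm.
3. **Combination.** A *key factor* is prominent (above-average BC **and**
   CC) only in the sharing group's network and independently associated
   with sharing in the multivariate model:
   `key = (above_both_SNG \ above_both_NSNG) ∩ regression_significant`.

Because the underlying subject-level survey is not public, the package ships
(a) the published summary tables as plain-text inputs, from which every
printed odds ratio and centrality flag is recomputable, and (b) a
Gaussian-copula synthetic-survey generator calibrated to the published
marginals, so the entire pipeline is exercisable and testable end to end.

## Worked example

Univariate screen on the published counts — HIV serostatus:

```r
library(pwidnet)
ct <- yunnan_contingency_tables("HIV serostatus")[[1]]
univariate_factor_test(ct)[, c("category", "total", "shared",
                               "odds_ratio", "ci_low", "ci_high")]
#>   category total shared odds_ratio   ci_low ci_high
#> 1 Negative   853    254   1.000000       NA      NA
#> 2 Positive   196    139   5.750863 4.087487 8.09114
```

HIV-seropositive participants shared needles at 5.8 times the odds of
seronegative participants (95% CI 4.1–8.1), matching the published 5.8
(4.1–8.1).

Null-model comparison for the never-sharing network's size (19 nodes, 38
edges):

```r
er_ensemble_stats(19, 38, reps = 1000, seed = 1)
#> Erdos-Renyi G(19, 38) ensemble, 1000 replicates (seed 1)
#>   clustering: 0.222 (sd 0.071, sem 0.0022)
#>   path length: 2.127 (sd 0.072, sem 0.0023)
```

The ensemble mean clustering 0.222 (SEM 0.002) reproduces the published
random-network value 0.221 (±0.002); the empirical network's 0.273 exceeds
it, and `compare_to_null()` turns that into an add-one empirical p-value.

Key-factor nomination from the published centrality and regression tables:

```r
t1 <- yunnan_table1(); t3 <- yunnan_table3()
mv <- t1[!is.na(t1$multi_p), c("factor", "multi_p")]; names(mv)[2] <- "wald_p"
nsng <- flag_above_average(centrality_table_from_values(
  t3$factor, t3$bc_nsng, t3$cc_nsng, "NSNG"))
sng <- flag_above_average(centrality_table_from_values(
  t3$factor, t3$bc_sng, t3$cc_sng, "SNG"))
identify_key_factors(mv, nsng, sng, prevalence = 393/1049)
#> Key-factor report
#>   - Sharing prevalence: 37.5% of subjects reported needle sharing.
#>   - Regression: 6 factor(s) independently associated with sharing: Residence,
#>     Other drug use, Duration of drug injection, Times reusing needle,
#>     HIV serostatus, Other infectious diseases.
#>   - Network contrast: above-average BC and CC for 8 factor(s) in the NSNG and 7 in the SNG.
#>   - Prominent only in the sharing group: HIV serostatus, Marital status.
#>   - Key harm-reduction target factor(s): HIV serostatus.
```

Eight factors are prominent in both centralities in the never-sharing
network, seven in the sharing network; HIV serostatus and marital status are
prominent *only* among sharers, and of those only HIV serostatus is also an
independent regression predictor — so HIV-seropositive PWID are the
nominated harm-reduction target group.

## The analysis workflow

Numbered drivers under `analysis/` run the full study pipeline and write
their tables under `results/`:

| script | what it does |
|---|---|
| `01_published_tables.R` | prevalences, univariate screen, candidate selection from printed counts |
| `02_simulate.R` | synthetic survey (n = 1,049) from the calibrated generator |
| `03_regression.R` | multivariate logistic fit on the synthetic survey |
| `04_networks.R` | subgroup correlation networks, global statistics, GraphML/SIF export |
| `05_null_model.R` | matched Erdős–Rényi ensembles and non-randomness verdicts |
| `06_centrality_modules.R` | BC/CC tables, above-average flags, MCODE modules |
| `07_key_factors.R` | the intersection rule, printed-table and synthetic routes |

Run them in order: `Rscript analysis/01_published_tables.R`, etc.

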