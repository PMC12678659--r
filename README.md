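# panelnet

Network psychometrics for two-wave binary symptom panels: cross-sectional
Ising networks, cross-lagged panel networks (CLPN), bridge and centrality
analysis, community detection, and bootstrap stability — built for studies
of depressive symptoms and health-risk behaviours in large two-group
cohorts (for example, people with and without diabetes in European ageing
surveys), and for methodologists who need every estimator in that workflow
testable against known ground truth.

## The models

A panel holds subjects × items × 2 waves of 0/1 indicators — here, the 12
binary EURO-D depressive symptoms (Dep1–Dep12) plus four behaviours:
current smoking (S), physical inactivity (P), less-than-daily fruit/veg
consumption (F), and heavy episodic drinking (D).

**Ising network (cross-sectional).** One wave is modelled as a binary
Markov random field

P(x) ∝ exp( Σᵢ τᵢ xᵢ + Σ_{i<j} θᵢⱼ xᵢ xⱼ ),  x ∈ {0,1}^p,

estimated by eLasso: nodewise L1-penalized logistic regression with
extended-BIC model selection (EBIC = −2ℓ + k log n + 2γ k log(p−1),
γ = 0.25) and AND-rule symmetrization.

**CLPN (longitudinal).** Each wave-2 item is LASSO-regressed on all wave-1
items: logit P(x⁽²⁾ⱼ = 1 | x⁽¹⁾) = β₀ⱼ + Σᵢ Bᵢⱼ x⁽¹⁾ᵢ. B is a directed
network — diagonal entries are autoregressive effects, off-diagonal entries
cross-lagged effects — with the penalty chosen by seeded 10-fold
cross-validation (one-standard-error rule) or EBIC.

Around these sit the supporting stages of the full workflow: participant
inclusion filtering, Table-style group descriptives (Pearson χ², Cronbach's
α, EURO-D caseness), the goldbricker redundancy screen (Hittner–May–Silver
test for overlapping dependent correlations), strength / expected-influence
/ bridge centrality, walktrap communities, case-dropping bootstrap
CS-coefficients and edge CIs — plus a calibrated two-group synthetic panel
generator (Gibbs-sampled wave 1, logistic cross-lagged wave 2) so that
every estimator is validated by parameter recovery.

## Worked example

```r
library(panelnet)

panel <- generate_default_panel(n_total = 10000, seed = 42)
panel
#> Binary panel: 10000 subjects x 16 items x 2 waves
#>   groups: diabetes=791, no_diabetes=9209

ifit <- ising_fit(panel, group = "no_diabetes")
ifit
#> Ising network: 16 nodes, n = 9209 (eLasso, gamma = 0.25, AND rule)
#>   edge density: 62.5% (75 of 120 possible edges)

bt <- bridge_metrics(coef(ifit), panel$codebook$item_group)
bt[order(-bt$bridge_strength), ][1:3, ]
#>  node      group bridge_strength bridge_expected_influence
#>     P  behaviour       2.7999899                 2.7999899
#> Dep12 depression       0.4072864                 0.4072864
#>  Dep6 depression       0.3822400                 0.3822400

walktrap_communities(coef(ifit))
#> Walktrap partition (t = 4): 4 communities, Q = 0.000
#>   [1] Dep1, Dep2, ..., Dep12, P
#>   [2] S
#>   [3] F
#>   [4] D

cfit <- clpn_fit(panel, group = "no_diabetes", seed = 1)
cfit
#> Cross-lagged panel network: 16 nodes, n = 9209 (lasso, cv selection)
#>   edge density: 6.6% of 256 directed edges (diagonal included)
#>   strongest autoregressive effects: S (2.21), D (1.37), Dep1 (1.36)

head(summary(cfit)$cross_lagged, 1)
#> from   to    weight
#>    P Dep6 0.2151601
```

Reading the numbers: in the generated cohort physical inactivity (P) is the
dominant bridge node — its bridge strength (2.80, the absolute edge weight
it shares with the symptom side) is seven times the next node's — and the
walktrap partition accordingly places P inside the depressive-symptom
community while the other behaviours stay separate. The longitudinal
network recovers the strongest autoregressive effects on the behaviours
(smoking 2.21 log-odds) and its top cross-lagged edge is inactivity →
interest (Dep6), the effect planted in the generator. These are exactly the
qualitative findings this machinery is designed to surface; the quantities
themselves are properties of the synthetic scenario, not of any real
cohort.

The whole workflow per group — filter, descriptives, redundancy screen, six
cross-sectional and four longitudinal networks, metrics, communities,
stability — runs as one call:

```r
bundle <- run_full_analysis(panel, default_config(seed = 7))
write_bundle(bundle, "results/")
```

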