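---
title: "Joint disease mapping of preventable hospitalizations with a Shared Component Model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint disease mapping of preventable hospitalizations with a Shared Component Model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Potentially preventable hospitalizations (PPH) — admissions for chronic
conditions such as COPD, congestive heart failure, diabetes complications,
dehydration, angina and adult asthma that timely outpatient care should
largely avoid — are a standard signal of how well a territory's ambulatory
care performs. When several such conditions are mapped over small health
areas, two kinds of geographic structure can coexist: a *common* pattern
affecting all conditions alike (plausibly the performance of the local
providers) and *condition-specific* departures from it (plausibly
idiosyncratic organizational factors). `pphmap` implements the joint
Bayesian analysis that separates the two: descriptive small-area
statistics, a Shared Component Model (SCM) over all conditions at once,
single-condition comparators, model comparison by DIC, a posterior
variance decomposition, and exceedance-probability map surfaces — plus a
calibrated synthetic-data generator so the whole pipeline is testable with
known ground truth.

## Data model

The areal unit is a small administrative health zone. Raw input is a
stratified count table: person-years and admission counts per (area,
condition, 5-year age band x sex). The default stratification spans ages
15–19 through 100+ (18 bands x 2 sexes = 36 strata); it is configurable.
`assemble()` collapses strata by *indirect standardization*: the
region-wide stratum rate \(r_{sj} = \sum_i c_{isj} / \sum_i n_{is}\) is
applied to each area's stratum person-years, giving expected counts
\(e_{ij} = \sum_s n_{is} r_{sj}\). Two consequences are load-bearing and
tested: \(\sum_i e_{ij} = \sum_i O_{ij}\) holds exactly per condition, and
the standardized hospitalization ratio \(\mathrm{SHR}_{ij} =
O_{ij}/e_{ij}\) aggregates to 1 over the region. A stratum with zero
regional person-years has an undefined rate; it is defined as 0 with a
warning (it cannot occur in a valid table, where zero person-years forces
a zero count).

Adjacency comes from a GAL neighbor-list file. Validation enforces
symmetry and rejects self-loops rather than repairing silently; isolated
areas are legal but flagged, because the spatial prior must treat them
specially (below). Area order in the GAL file fixes matrix row order
everywhere downstream.

## Descriptive statistics

* **Crude and directly standardized rates**, per 100,000 person-years.
* **EQ5–95**: the ratio of the 95th to the 5th percentile of area rates,
  with linear-interpolation (type 7) quantiles. It is reported as
  undefined when fewer than 20 areas are available or when the 5th
  percentile is zero — the latter is our reading of why published tables
  show "–" for the rarest conditions, not something the source of the
  convention states.
* **EB variance**: the between-area variance \(\tau^2\) of relative risks
  beyond Poisson noise. The name is used in the applied literature without
  a formula; we implement the simple moment estimator derived from
  \(\mathrm{Var}(O_i/e_i) = \tau^2 + 1/e_i\):
  \(\hat\tau^2 = \max\{0, \mathrm{mean}_i[(O_i/e_i - 1)^2 - 1/e_i]\}\),
  with an expected-count-weighted variant as an option. It is
  oracle-testable and recovers \(\tau^2\) on Poisson-gamma simulation
  (500 areas, \(e_i = 200\), \(\tau^2 = 0.3\) recovered within 0.05).
* **Moran's I** with binary symmetric (non-row-standardized) weights and a
  permutation test; the two-sided p-value is
  \((1 + \#\{|I^*| \ge |I|\})/(B+1)\) with \(B = 999\) by default, so the
  smallest attainable p is 0.001. Isolated areas carry no weight and are
  excluded with a warning. For the fitted model we compute I on the
  posterior mean of the shared field \(\varphi_i\) (log scale), not on
  \(\exp(\varphi_i)\); the source analyses do not state their choice, and
  on the log scale the statistic is invariant to the intercept.

## The Shared Component Model

First level: \(O_{ij} \sim \mathrm{Poisson}(\mu_{ij})\),
\(\log \mu_{ij} = \log e_{ij} + \alpha_j + \delta_j \varphi_i +
\epsilon_{ij}\). The loading \(\delta_j\) measures how strongly condition
\(j\) expresses the common field \(\varphi\); \(\epsilon_{ij}\) is the
condition-specific (discrepant) effect.

Priors:

* \(\alpha_j\): improper flat. Posterior propriety requires at least one
  admission per condition; this is validated at input.
* \(\log \delta_j \sim N(0, 1/5.9)\). The "5.9" is read in the WinBUGS
  convention as a *precision* (variance ≈ 0.17), the standard choice in
  the two-disease SCM literature; a variance reading is available as a
  sensitivity option.
* \(\varphi\): exchangeable \(N(0, \sigma^2_{shared})\) or intrinsic CAR
  (pairwise-difference prior on graph edges). Both are offered because the
  model choice between them is part of the analysis (by DIC).
* \(\epsilon_{\cdot j}\): exchangeable \(N(0, \sigma^2_{specific,j})\).
* Precisions: Gamma(0.5, 0.0005), the convention of the SCM literature;
  configurable. This prior is vague on the scale of typical disease-
  mapping standard deviations but does pull weakly identified
  \(\sigma_{specific,j}\) downward when the data cannot distinguish
  specific effects from Poisson noise — visible for the condition with the
  smallest specific scale in our recovery experiments.

**Identifiability.** The likelihood only sees \(\alpha_j + \delta_j
\varphi_i + \epsilon_{ij}\), so three transforms are applied after every
sweep, all leaving every \(\mu_{ij}\) unchanged: \(\varphi\) is centered
(shift absorbed into the intercepts via \(\delta_j\)); each
\(\epsilon_{\cdot j}\) column is centered (shift absorbed into
\(\alpha_j\)); and the loadings are rescaled to unit geometric mean with
the inverse scale applied to \(\varphi\) (generalizing the
\(\delta, 1/\delta\) convention of the two-disease model; `"none"` is
available to mimic prior-only identification). For an intrinsic CAR field
the centering is exact (the prior is flat along the constant direction).
For an exchangeable field it amounts to conditioning the prior on a zero
mean; because the iid Gaussian mean is independent of the deviations and
is absorbed by the flat intercepts, the posterior of every identified
quantity is unchanged — which the dense-grid validation below confirms
empirically.

**Isolated areas under the CAR prior** have no neighbors to condition on;
they are given an exchangeable conditional with the shared precision, and
a warning is emitted. The Gibbs update for the shared precision uses the
matching degrees of freedom: \(n\) for the exchangeable family, and
\((n - n_{iso} - \#\text{components among connected areas}) + n_{iso}\)
for the CAR family.

## The sampler

A Metropolis-within-Gibbs scheme, written in C++:

* conjugate Gamma draws for all precisions;
* adaptive random-walk Metropolis for \(\alpha_j\), \(\log\delta_j\), each
  \(\varphi_i\) and each \(\epsilon_{ij}\). Step sizes adapt by
  Robbins–Monro on the log scale toward 0.44 acceptance, **during burn-in
  only**, so the post-burn-in chain is a fixed Markov kernel. Post-burn-in
  acceptance rates are recorded per block and sit in [0.15, 0.6] on
  default synthetic data;
* two *likelihood-invariant swap moves* that repair the slow mixing that
  single-site walks exhibit between the shared and specific components:
  (a) \(\log\delta_j \to \log\delta_j + d\) with
  \(\epsilon_{ij} \to \epsilon_{ij} - (e^{d}-1)\delta_j\varphi_i\), and
  (b) \(\varphi_i \to \varphi_i + d\) with \(\epsilon_{ij} \to
  \epsilon_{ij} - \delta_j d\). Both keep every \(\mu_{ij}\) fixed, have
  unit Jacobian, and accept on the prior ratio alone. Without them the
  variance decomposition for the conditions with the smallest specific
  scales mixes an order of magnitude more slowly.

Initialization: \(\alpha_j = \log(\sum_i O_{ij} / \sum_i e_{ij})\) with
per-chain jitter, \(\varphi, \epsilon \sim N(0, 0.1^2)\) per chain,
\(\log\delta = 0\). One master seed derives per-chain seeds, recorded in
the returned metadata; identical seeds reproduce retained draws
bit-for-bit. A non-finite log-posterior aborts with the iteration index.

The same engine serves the comparators: with one condition, \(\delta\)
fixed at 1, a CAR \(\varphi\) (as the structured effect \(u\)) and
exchangeable \(\epsilon\) (as \(v\)) it is the BYM model; dropping
\(\varphi\) gives the non-spatial exchangeable baseline used for the
joint-vs-independent comparison.

**Validation.** On a 2-area, single-condition toy model with fixed
\(\sigma\), the sampler's posterior for the mean log-risk level is
compared against a \(601^2\) dense-grid numerical posterior; total
variation over a 0.05-wide binning is below 0.05 with 10,000 retained
draws. Split-chain \(\hat R\) on that fit sits in [0.99, 1.02].

## Posterior summaries

* **DIC**: \(\bar D + p_D\) with \(p_D = \bar D - D(\bar\theta)\), the
  plug-in deviance evaluated at posterior means of all parameters on their
  sampled (log) scales. The identity \(DIC = \bar D + p_D\) is asserted on
  every fit; a negative \(p_D\) is flagged, not hidden.
* **Variance decomposition**: per retained draw and condition,
  \(f_j = \mathrm{Var}_i(\delta_j\varphi_i) / [\mathrm{Var}_i(\delta_j
  \varphi_i) + \mathrm{Var}_i(\epsilon_{ij})]\) with empirical variances
  across areas, summarized by the posterior mean and central 95% interval.
  Computing the fraction from posterior-mean summaries instead was
  considered and rejected: it does not preserve the relationship between
  the scale columns and the percentage column that the per-draw definition
  guarantees. Scale parameters are summarized by posterior medians with
  95% intervals. Draws with zero total variance contribute 0 with a
  counted warning.
* **Exceedance surfaces**: per area, the fraction of retained draws with a
  relative-risk term above 1, categorized high (> 0.8) / low (< 0.2) /
  indeterminate. Three terms are mapped: the shared pattern
  \(\exp(\varphi_i)\); the per-condition relative risk about its regional
  level, \(\exp(\delta_j\varphi_i + \epsilon_{ij})\); and the discrepant
  component \(\exp(\epsilon_{ij})\). Excluding \(\alpha_j\) from the
  condition-level term is a deliberate choice: with conserved expected
  counts the intercept is a regional level, and the mapped quantity should
  be centered on 1 in the region by construction.
* **Diagnostics**: plain split-chain Gelman–Rubin \(\hat R\) (constant
  chains report 1 with a zero-variance flag) and per-chain
  autocorrelation averaged across chains.

## The synthetic-data generator

The generator draws data exactly from the model above, at defaults that
emulate a three-year regional admission registry: 240 areas (a 15 x 16
rook lattice unless a graph is supplied), annual person-years log-uniform
between 4,065 and 250,616 (the log-uniform choice reproduces the heavy
right skew of real small-area population sizes), six conditions with
regional rates 11.3, 155.0, 88.9, 3.9, 23.9 and 21.2 per 100,000
person-years, shared scale 0.121, loadings (0.92, 1.12, 0.74, 1.42, 1.11,
1.09) and specific scales (0.243, 0.112, 0.079, 0.673, 0.489, 0.353).
Intercepts are set to \(-[(\delta_j\sigma_{sh})^2 + \sigma_{sp,j}^2]/2\)
so each condition's expected regional rate equals its configured baseline.
Counts are pure Poisson at stratum level, with a fixed exponential
age-rate gradient (0.3 per 5-year band) whose existence — not its value —
is what the standardization tests need. The returned ground truth records
the realized \(\alpha, \delta, \varphi, \epsilon\) and the per-condition
true shared-variance fraction (empirical across areas).

What it deliberately does **not** emulate: readmission clustering
(overdispersion beyond Poisson), real geography or administrative
adjacency, private-hospital leakage, or insurance-coverage biases. Passing
recovery tests therefore demonstrate correctness of the machinery under
the model's own assumptions, not robustness to the ways real discharge
data violate them.

## What the recovery experiments show — and their limits

At the default conditions (240 areas, fast schedule of 3 chains x 5,000
iterations, 1,000 burn-in, thin 5) the 95% credible intervals for the
loadings cover the generating values for effectively all conditions
across seeds, and the recovered shared-variance percentages track the
truth with aggregate (across-seed mean) errors within a few points. Two
caveats are worth stating plainly. First, the shared-vs-specific split
for the pair of conditions with the smallest specific scales is weakly
identified: in individual replicates their estimated percentages can
trade 20–30 points in opposite directions, and this persists at six times
the chain length with \(\hat R \approx 1.03\) — it is a property of the
posterior, not of the sampler, and matches the very wide credible
intervals such analyses report. Second, raw-SHR correlations are a noisy
mirror of sharing: at the default (small) shared scale, Poisson noise
dominates \(\mathrm{Var}(\mathrm{SHR}) = \tau^2 + 1/e\), so even a single
common pattern with no specific noise yields modest raw correlations;
only when the shared scale dominates sampling noise do they approach 1.

## Numerical choices and degenerate inputs

* Quantiles: type 7 everywhere (R's default), stated because EQ5–95
  depends on it.
* Conservation checks use relative tolerance 1e-9; the sum-to-zero
  invariant of the CAR field is asserted at 1e-10 absolute per draw.
* MCMC schedules: defaults mirror a production schedule (3 x 49,500,
  burn-in 12,000, thin 75); the package's tests and the analysis scripts
  use the fast desk schedule (3 x 5,000 / 1,000 / 5) and 48–100-area
  problems for the cheaper checks, sizes chosen so the full suite runs in
  about a minute while leaving the recovery claims at the full 240-area
  size.
* Ties and empty cases: empty rate vectors are errors; constant vectors
  are errors for Moran's I (no variance to permute) and flagged for
  \(\hat R\); a zero-variance SHR column yields NA correlations for its
  pairs rather than an error.
* The comparison of exchangeable vs CAR shared fields by DIC, and of the
  joint model vs summed independent fits, is asserted as a majority vote
  over seeds — the direction, not the magnitude, is the reproducible
  claim at desk scale.

## Known limitations

The sampler is single-threaded and updates one scalar at a time; for
problems an order of magnitude larger than 240 areas a block or marginal
sampler would be preferable. The exchangeable-field centering makes the
reported \(\alpha_j\) the regional mean level by construction, which is
the natural reporting convention but differs from an unconstrained
parameterization by a (posterior-irrelevant) relabeling. GeoJSON export
attaches probabilities and categories to features by a configurable id
property; it does no geometry processing and is not a cartography tool.
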