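---
title: "Evaluating genetic risk prediction with the liability threshold model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating genetic risk prediction with the liability threshold model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liabilityMetrics)
```

## The model

liabilityMetrics evaluates how well a set of measured risk factors —
typically a panel of susceptibility variants — can predict a binary disease
outcome, using only two quantities: the overall disease probability $K$
(lifetime risk, or the risk over any stated period) and the proportion
$V_m$ of liability variance the measured factors explain.

The framework is the classical liability threshold model. Each individual
carries a latent *liability* $L \sim N(0, 1)$; disease occurs when $L$
exceeds the threshold $T = \Phi^{-1}(1 - K)$. The liability splits into a
*measurable* component $Z \sim N(0, V_m)$, determined by the known factors,
and an independent residual, so that $L \mid Z = z \sim N(z, 1 - V_m)$.
When the measured factors are genetic variants, $V_m$ is the heritability
they capture on the liability scale.

For an individual at lower-tail percentile $p$ of the measurable liability,
the predicted absolute risk is

$$R(p) = \bar\Phi\!\left(\frac{T - \sqrt{V_m}\,\Phi^{-1}(p)}
{\sqrt{1 - V_m}}\right),$$

a strictly increasing map from percentile to risk (`risk_at_percentile()`,
inverted exactly by `percentile_at_risk()`). Everything else in the package
is a functional of this one curve, or of the Pearson–Aitken (PA) moments of
$Z$ after selecting on disease status:

* **Classification and ROC.** A "positive test" at percentile cutoff $c$
  captures true-positive mass $TP(c) = \int_c^1 R(p)\,dp$; the other three
  cells follow from the margins (`classification_table()`). The ROC curve
  is traced over 5000 cutoffs (`roc_curve()`), and the exact area is also
  available in closed integral form,
  $\mathrm{AUC} = \frac{1}{K(1-K)} \int_0^1 TP(c)\,(1 - R(c))\,dc$
  (`auc_exact()`). Two binormal approximations (`auc_binormal()`) use the
  PA moments of $Z$ in cases and controls: the accurate form with both
  conditional variances, and a spreadsheet-friendly form that replaces both
  by the unselected variance $V_m$ — the latter reproduces the "equal
  variance" approximation of the reference tables.
* **Risk distribution.** The predicted risks have closed-form cdf and
  density in the population, in cases and in non-cases (`risk_density()`),
  the predictiveness curve (`predictiveness_curve()`), the proportion of
  cases found in the top risk fraction (`proportion_cases_explained()`),
  the Lorenz-type cases-explained curve whose area is *close to but not
  equal to* the AUC (`cases_explained_curve()`), and dispersion summaries
  (`risk_summary()`), including the identity
  $\mathrm{var}(R)/[K(1-K)] = \bar R_{\text{cases}} -
  \bar R_{\text{non-cases}}$ (the discrimination slope).
* **Model improvement.** For nested models explaining $V_{old}$ and
  $V_{new}$, reclassification across pre-set risk categories is computed
  analytically by bivariate-normal rectangle probabilities over the PA
  conditional law of the two measurable liabilities
  (`reclassification_table()`, `weighted_nri()`), and the integrated
  discrimination improvement is the difference in discrimination slopes
  (`idi()`).
* **Variant panels.** `variance_explained()` turns allele frequencies and
  per-allele odds ratios into $V_m$; `simulate_cohort()` and
  `empirical_metrics()` provide a Monte-Carlo counterpart of every
  analytic quantity.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `K` | overall disease probability (unitless, in (0,1)) | — | lifetime risk in the bundled applications; any period risk works if the effect sizes refer to the same period |
| `Vm` | liability variance explained (in [0,1)) | — | from `variance_explained()` or external estimates |
| `n_cutoffs`, `grid` | curve resolution | 5000 | halving it moves the AUC by < 1e-4; 5000 matches the reference construction |
| `p_low`, `p_high` | reference percentiles for risk spread | 0.1, 0.9 | the conventional "10th vs 90th percentile" contrast |
| `thresholds` | risk-category boundaries for NRI | `c(0.06, 0.2)` | the ATP-III style 0–6 / 6–20 / >20 % categories |
| `cov_old_new` | covariance of old/new measurable liabilities | `Vold` | an independently added factor; a correlated addition must supply it explicitly |

## Numerical choices

* All expectations over $R$ are integrated in percentile space
  ($E[h(R)] = \int_0^1 h(R(p))\,dp$, adaptive quadrature, absolute
  tolerance $10^{-9}$): the risk density $g(R)$ is unbounded at the edges
  of its support for small $V_m$, while $p$-space integrands are smooth.
* Truncated-normal moments are closed-form (mean $\phi(T)/K$, variance
  $1 + T\,\phi(T)/K - (\phi(T)/K)^2$ in cases), not quadrature.
* Tail-safe forms (`pnorm(..., lower.tail = FALSE)`, `qnorm(1 - K)` via the
  upper tail) keep rare-disease inputs ($K \le 10^{-3}$) accurate.
* The bivariate normal cdf is a pure-R implementation of the Genz (2004)
  rewrite of the Drezner–Wesolowsky method, accurate to ~$10^{-15}$ and
  unit-tested against a one-dimensional quadrature oracle. Rectangles are
  assembled by inclusion–exclusion.
* Risk categories are half-open $[\text{lower}, \text{upper})$: a risk
  exactly at a threshold belongs to the upper category. In the continuous
  model the boundary has measure zero; the convention only matters when
  comparing with empirical tables.
* `Vm < 1e-12` is collapsed to the constant-risk model ($R \equiv K$):
  dispersion indices are exactly zero, the ROC is the diagonal, and
  operations that require a proper risk distribution fail with an
  explicit message rather than dividing by zero.
* The ROC area uses trapezoidal integration with forced (0,0) and (1,1)
  endpoints. At 5000 cutoffs this agrees with the closed-form integral to
  better than $10^{-4}$ and avoids any spline-dialect dependence. Both
  routes slightly exceed (by about $10^{-3}$) some third-party printed
  "accurate AUC" values; a rank-statistic Monte-Carlo oracle at $2\times
  10^7$ draws sides with the values computed here.

## Design choices where the design was open

* **Equal-variance binormal AUC.** The "equal variance" approximation is
  implemented as $\Phi\!\big((\mu_A - \mu_{\bar A})/\sqrt{2 V_m}\big)$,
  i.e. the common variance is the *unselected* variance of the measurable
  liability. Using the case-specific or control-specific PA variance
  instead does not reproduce the reference "AUC approx" values; the
  unselected variance reproduces all of them to printed precision.
* **$V_m$ from a panel.** The per-locus construction maps each genotype's
  absolute risk $r_g$ (obtained from the odds ratios by root-finding the
  baseline risk so the HWE-weighted mean equals $K$ — the cohort
  OR-to-RR correction) to a liability shift $\mu_g = T - \Phi^{-1}(1 -
  r_g)$ against unit residual variance; the locus contributes
  $\mathrm{var}_g(\mu_g)$ and loci add independently. This single-locus
  threshold-shift approximation is accurate for GWAS-scale effects
  (per-allele OR $\lesssim$ 2); it does not iterate on the residual
  variance and is not intended for major loci such as APOE.
* **Intercept calibration of the simulator.** The logistic intercept is
  chosen so the *expected* risk equals $K$ (not the realised prevalence of
  one draw): the distribution of the polygenic score is built by exact
  convolution of the per-locus three-point distributions onto a $10^{-4}$
  grid, making the calibration deterministic.
* **Seeding.** Every stochastic routine takes an explicit `seed` and
  restores the caller's RNG state, so cohorts are reproducible and
  simulation order does not leak between analyses.

## What the synthetic data emulate — and what they do not

The bundled `random_panel()` generator (and the shipped
`synthetic-30-locus-panel.tsv`, produced by `random_panel(30, seed =
2010)`) emulates the *shape* of a GWAS-era susceptibility panel: 30
independent loci in Hardy–Weinberg equilibrium, allele frequencies
0.05–0.95, per-allele odds ratios 1.05–1.6 multiplicative across genotypes
and loci. It does not transcribe any published variant list, and it omits
features of real panels: linkage disequilibrium between loci, effect-size
estimation error and winner's curse, gene–gene interaction, non-collapsed
haplotype effects, and ascertainment. A green simulation test therefore
establishes that the analytic machinery and the multiplicative-OR cohort
model agree *under the stated idealisation* — it does not validate any
particular real panel, nor the behaviour of major-effect loci for which
the normal measurable-liability assumption itself breaks down.

The simulator draws outcomes from a *logistic* model while the analytics
are *probit* (liability). The two agree closely through the body of the
risk distribution — this near-equivalence is itself one of the checked
claims — but they genuinely part in the extreme lower risk tail of rare
diseases, which is why the distribution-matching test compares the
25th–90th percentile range rather than the far tails.

## Known limitations

* Reclassification conditionals are PA normal approximations; the exact
  conditionals of a truncated trivariate normal are skewed. Consequently
  the case/control mixture reproduces the unconditional transition matrix
  to about $10^{-3}$, and analytic NRIs carry a comparable approximation
  scale (the NRI tables are matched at ±0.005).
* Calibration (agreement of predicted with realised risks) is assumed
  perfect and never tested here; goodness-of-fit assessment is out of
  scope.
* Period risks require all inputs (K, odds ratios) to refer to the same
  period; age-conditional and competing-risk handling are out of scope.
* Confidence intervals for any metric are not provided; inputs estimated
  from small samples propagate their uncertainty unchecked.
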