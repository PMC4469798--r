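---
title: "Longitudinal GWAS of growth trajectories: models and methods"
author: "growthgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal GWAS of growth trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Cross-sectional GWAS of childhood body mass index (BMI) throw away the
longitudinal structure of growth: a variant may shift the whole BMI
trajectory up or down, change its *shape*, or both, and these signatures are
invisible to a single-age analysis. `growthgwas` implements a longitudinal
association pipeline for repeated anthropometric measurements between 1 and
17 years of age: a per-SNP semi-parametric linear mixed model on log-BMI,
three cluster-robust Wald tests that separate "level" from "shape" effects,
and a two-stage cross-cohort meta-analysis.

Because the childhood cohorts this design targets are access-controlled,
the package ships a first-class synthetic-cohort generator whose output has
exactly the statistical structure the analysis model assumes. Every stage of
the pipeline is exercised and tested against it.

# The per-SNP model

BMI is right-skewed, so measurements are analysed on the natural-log scale.
For individual $i$ at age $t$ (years):

$$
\log \mathrm{BMI}_{ij} = \beta_0 + s(t_{ij})^\top\beta_s
 + \mathrm{sex}_i\,(\beta_x + s(t_{ij})^\top\beta_{xs})
 + \mathrm{src}_{ij}\,\beta_c
 + d_i\,(\beta_g + s(t_{ij})^\top\gamma)
 + b_{0i} + b_{1i}(t_{ij}-8) + e_{ij}
$$

* $s(t)$ is a 6-dimensional truncated-power piecewise-cubic spline in age
  with knots at 2, 8 and 12 years,
  $s(t) = \big(c,\,c^2,\,c^3,\,(t-2)_+^3 - 216,\,(t-8)_+^3,\,(t-12)_+^3\big)$
  with $c = t-8$. Each component is recentred by its value at age 8, so
  **every basis function vanishes at 8 years**: main effects are effects *at
  age 8*, and the SNP main effect $\beta_g$ is the per-allele shift of the
  whole trajectory ("BMI intercept at 8").
* $d_i \in [0,2]$ is the imputed allele dosage (additive genetic model);
  $\gamma$ captures SNP-by-age interaction (trajectory shape).
* $\mathrm{src}$ is an optional questionnaire-vs-clinic measurement source
  indicator; principal components can be added the same way.
* $(b_{0i}, b_{1i})$ are individual random intercept and linear age slope
  with unstructured covariance $G$.
* $e_{ij}$ has variance $\sigma^2$ (optionally $\sigma^2 m^2$ on
  questionnaire rows) and continuous-time AR(1) correlation
  $\mathrm{cor}(e_{ij}, e_{ik}) = \phi^{|t_{ij}-t_{ik}|}$, $\phi \in [0,1)$,
  so correlation decays with the time gap regardless of visit spacing.

Estimation is by REML. The fixed effects and $\sigma^2$ are profiled out of
the restricted likelihood, and the optimiser (BFGS with numerical
gradients) works on an unconstrained parameterisation: log-Cholesky factors
of $G/\sigma^2$, a logistic transform of $\phi$, and the log of the source
multiplier $m$ when requested. Convergence is declared at a relative
objective change below `1e-8` with a 200-iteration cap; non-convergence is
flagged, not fatal. Per-individual covariance blocks are assembled and
Cholesky-factorised in compiled code, which keeps a full genome scan
practical (roughly half a second per SNP for 400 individuals with ~8
visits, including the robust-covariance step).

Two individuals measured twice at exactly the same age would make the
CAR(1) block singular (correlation $\phi^0 = 1$); duplicate-age rows within
an individual receive a $10^{-8}$ diagonal nugget.

## Why robust standard errors

The random-effects structure (intercept + linear slope) is deliberately
poorer than the fixed-effect age model (full spline). When individual
trajectories vary in shape beyond a linear slope, model-based covariances
of the SNP-by-age coefficients are too small and the multi-df tests
over-reject. All association tests therefore use the individual-level
sandwich covariance $A^{-1} B A^{-1}$, $A = X^\top V^{-1} X$,
$B = \sum_i X_i^\top V_i^{-1} r_i r_i^\top V_i^{-1} X_i$.

With a few hundred clusters the *plain* (CR0) sandwich is itself biased:
residuals from estimated fixed effects underestimate $V_i$ by the cluster's
leverage, and with 21 fixed-effect columns this inflates a 7-df Wald
statistic by several percent. The package therefore defaults to the
Bell--McCaffrey (CR2) adjustment, which replaces $r_i$ by $A_i r_i$ where
$A_i (W_i - X_i M X_i^\top) A_i^\top = W_i$
($M = (X^\top W^{-1} X)^{-1}$, $W = V/\sigma^2$), making $B$ unbiased when
the working covariance is correct and nearly unbiased otherwise. CR0 and
the simple $J/(J-1)$ CR1 inflation remain available
(`cr_adjust` argument). In cohorts of several thousand individuals the
three estimators are indistinguishable.

## The three tests

Writing $(\hat\beta_g, \hat\gamma)$ for the 7 SNP coefficients and $C$ for
their robust covariance block:

1. **SNP (level at 8):** $z = \hat\beta_g / \sqrt{C_{11}}$, two-sided
   normal P-value. A normal rather than $t$ reference is used: cluster
   counts are in the hundreds to thousands.
2. **Global Wald (7 df):** $(\hat\beta_g,\hat\gamma)^\top C^{-1}
   (\hat\beta_g,\hat\gamma)$ — any association with BMI over 1--17 years.
3. **Wald(Change) (6 df):** the same quadratic form over $\hat\gamma$ alone
   — any change in trajectory shape.

A $k$-df quadratic form in a covariance estimated from a finite number of
cluster scores is Hotelling's $T^2$ situation: referred directly to
$\chi^2_k$ it over-rejects, because the inverse of a noisy covariance is
biased upward. The multi-df tests therefore use an approximate Hotelling
reference: the sandwich block is treated as Wishart with an effective
degrees of freedom $\nu$ estimated by Satterthwaite moment matching from
the per-cluster working-model score covariances $Q_i$,
$$\nu = \frac{k(k+1)}{\sum_i \mathrm{tr}(S_i)^2 + \mathrm{tr}(S_i^2)},
\qquad S_i = Q_i \Big(\sum_j Q_j\Big)^{-1},$$
and $W\,(\nu-k+1)/(\nu k)$ is referred to $F(k,\,\nu-k+1)$. For $J$ equal
independent clusters $\nu = J$; unequal cluster sizes and skewed dosage
distributions push $\nu$ well below $J$ (a MAF-0.3 SNP on 250 individuals
gives $\nu \approx 84$). The reported statistic is the $\chi^2$-equivalent
$Q_{\chi^2_k}^{-1}(1-p)$, keeping statistic and P-value mutually
consistent. At cohort scale ($J$ in the thousands, $\nu$ in the hundreds
or more) the calibration changes little; at the 400-individual scale of
the test-suite simulations it is what makes the null genomic-control
factor come out at 1.0. One side effect: because $\nu$ is computed in the
reported allele's parameterisation, recoding the effect allele leaves the
Wald statistics and the level test exactly invariant but can move the
multi-df P-values in their trailing digits.

A non-invertible covariance block is handled by eigenvalue clipping at
$10^{-12}$ with rank-adjusted degrees of freedom. SNPs are excluded before
testing if MAF < 5% or imputation $R^2 < 0.3$ (strict inequalities; a SNP
at exactly 5% stays in). Genome-wide significance is flagged at
$P < 5\times10^{-8}$ on any test.

# Meta-analysis

Per cohort, genomic-control factors are estimated as the median observed
statistic over the median of the central null distribution:
$\chi^2_1$ for the squared level z-scores (median 0.4549), $\chi^2_7$ and
$\chi^2_6$ for the two Wald statistics. Factors are clamped at 1 (genomic
control never deflates).

* The **level effect** is combined by fixed-effect inverse-variance
  weighting, with per-cohort SEs inflated by $\sqrt{\lambda_{1\mathrm{df}}}$,
  plus Cochran's $Q$, $I^2 = \max(0, (Q-(k-1))/Q)\cdot 100$, and a
  heterogeneity P-value.
* The **multi-df P-values** have no sign, so they are combined by
  one-sided $\sqrt{N}$-weighted Stouffer:
  $Z = \sum_i \sqrt{N_i}\,\Phi^{-1}(1-p_i) / \sqrt{\sum_i N_i}$, after
  per-cohort genomic-control adjustment (statistic divided by $\lambda$ on
  the $\chi^2$ scale).

SNPs are matched on id with allele realignment: a swapped effect/other
allele flips $\beta$ and EAF; strand complements are resolved through the
A/T, C/G map; strand-ambiguous SNPs are oriented by allele frequency only
when both cohorts' EAFs are at least 0.1 away from 0.5 and are otherwise
dropped with a reason. The same machinery combines a discovery
meta-analysis with a replication cohort: the discovery stage enters with
its pooled sample size.

# Characterisation

For a locus of interest the package evaluates (i) genotype-specific
population-average BMI curves, $\exp$-transformed back to kg/m²; (ii) the
age-specific per-allele effect $\hat\beta_g + s(t)^\top\hat\gamma$ with
pointwise robust 95% bands; (iii) the earliest detectable age — the
smallest integer age whose CI excludes zero *with all later ages excluding
zero on the same side* (persistence avoids isolated-age false positives;
the rule is this package's choice); and (iv) conversion of a log-scale
effect $\beta$ to kg/m² as $\exp(\mu+\beta) - \exp(\mu)$ with
$\mu = 2.80$ (log-BMI at age 8, about 16.4 kg/m²). The alternative
linearisation $\beta e^{\mu}$ agrees to two decimals at these effect
sizes; the exact-difference form was chosen for interpretability.

# The synthetic-cohort generator

`cohort_config()` + `simulate_dosages()` + `simulate_phenotypes()` generate
data with exactly the model's assumed structure:

* **Dosages.** True genotypes are Binomial(2, MAF) (Hardy--Weinberg).
  Imputation noise uses the posterior-mean moment match
  $d = (1-r^2)\,2p + r^2 g + \varepsilon$,
  $\mathrm{Var}(\varepsilon) = r^2(1-r^2)\,2p(1-p)$, giving
  $E(d) = 2p$, $\mathrm{Var}(d) = r^2\mathrm{Var}(g)$ and
  $\mathrm{cor}^2(d, g) = r^2$ — the defining property of the MACH-style
  dosage quality metric. Dosages are clipped to $[0,2]$.
* **Visit schedule.** Ages are drawn from 17 one-year bins spanning 1--17
  years with per-bin inclusion probabilities taken from the reference
  schedule in `reference_visit_schedule()` (≈8.8 expected visits per child,
  heavier sampling in infancy and adolescence) and jittered ±0.4 years —
  an unbalanced panel like real cohort data. Fixed schedules and uniform
  random schedules are available for controlled experiments.
* **Mean curve.** The female mean log-BMI curve is the least-squares spline
  fit through the log reference bin means (the familiar adiposity-rebound
  shape: BMI falls to a minimum near age 6 and rises through adolescence),
  with the value at age 8 overridden by `intercept_mu` (default 2.80). The
  male curve adds a small sex shift and sex-by-basis coefficients (defaults
  are arbitrary small values; the analysis model estimates them freely).
* **Noise.** Defaults: residual SD 0.057 (log scale) with CAR(1)
  $\phi = 0.5$ at 1 year; random intercept/slope covariance
  $G = \begin{pmatrix} 1.16\times10^{-2} & 3.5\times10^{-4} \\
  3.5\times10^{-4} & 1.0\times10^{-4}\end{pmatrix}$, chosen so that the
  cross-sectional log-BMI SD is ≈0.12 at age 8 growing to ≈0.16 at 16 —
  the between/within split typical of childhood BMI; questionnaire source
  on 25% of rows with residual SD multiplier 1.5 (differential measurement
  error; how real cohorts' error enters the variance is not observable
  from published summaries, so this mechanism is a modelling choice).
* **Misspecification switch.** `random_curve_sd` adds individual random
  coefficients on the spline basis itself — trajectory-shape heterogeneity
  the analysis model does *not* capture. This is the scenario in which
  model-based covariances over-reject and the sandwich earns its keep, and
  it is exercised in the test suite.

What the generator does **not** emulate: linkage disequilibrium between
SNPs (each SNP is drawn independently), population stratification,
secular/cohort effects, missingness mechanisms correlated with phenotype,
and measurement rounding. Passing tests therefore demonstrate correctness
of the statistical machinery under the stated model, not robustness to
every feature of real cohort data.

# Numerical and design choices

* Truncated-power basis rather than B-splines: with knots {2, 8, 12} it
  yields exactly 6 age terms — matching the 7-df global and 6-df change
  tests — and makes "recentre so everything vanishes at 8" a one-line
  operation with an interpretable main effect.
* Basis columns are centred at age 8, not mean-centred: the SNP main effect
  is then the age-8 effect by construction.
* Random effects are intercept + slope only, with the spline terms
  fixed-only, as discussed above.
* The REML objective is minimised to relative tolerance $10^{-8}$;
  successive accepted optimiser steps never increase it. The fitted $V$ is
  kept positive definite by the unconstrained parameterisation plus the
  duplicate-age nugget.
* GWAS scans warm-start each SNP's variance components at the previous
  SNP's optimum; results are unchanged (the objective is the same), only
  iteration counts drop.
* P-values are written in scientific notation with 4 significant digits;
  sex is coded 0 = female, 1 = male; the effect allele is always `Al1` in
  MACH-dialect metadata.

## Problem sizes used in the test suite

Simulation-backed checks use sizes chosen to give adequate Monte-Carlo
resolution while keeping a full test run to minutes on one core: the
calibration scan uses 500 null SNPs on a 400-child cohort (the
genomic-control λ of the 7-df Wald statistics is then determined to ±0.03
Monte-Carlo); parameter recovery uses 50 replicates of a 400-child cohort;
the misspecification type-I study uses 250 replicates; the power contrast
uses 6 replicates of a 5000-child cohort at the reference effect size
0.012. A real genome scan (~2.2M SNPs) parallelises trivially across SNPs.

# Known limitations

* The sandwich protects test *validity* under variance misspecification,
  not the efficiency of $\hat\beta$; strongly misspecified random effects
  cost power.
* With only a few dozen clusters even CR2 multi-df tests are approximate;
  the package targets cohort-scale data (hundreds to thousands of
  individuals).
* Fixed-effect meta-analysis only; heterogeneity is reported, not
  modelled.
* No X-chromosome dosage conventions, no LD-aware locus definition, and no
  genotype-calling/imputation — dosage files are taken as given.
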