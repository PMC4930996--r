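---
title: "Methods: niche decomposition, repeatability and within-individual centering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: niche decomposition, repeatability and within-individual centering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoniche)
```

This vignette is the package's account of its statistical machinery: the
models, the parameters that matter, the numerical choices, and what the
simulation-based validation does and does not establish.

## 1. The niche-width decomposition

For one tissue and one isotope, with individual $j$ measured in years
$i \in Y_j$:

$$\mathrm{WIC} = \frac{1}{J}\sum_j \mathrm{Var}_i\,(x_{ij}), \qquad
  \mathrm{AIC} = \mathrm{Var}_j\,(\bar x_j), \qquad
  \mathrm{TNW} = \mathrm{WIC} + \mathrm{AIC},$$

with the specialization ratio $\mathrm{WIC}/\mathrm{TNW}$. Individuals
contribute *equally* to WIC regardless of how often they were sampled
(an unweighted mean of per-individual variances); sample-size weighting
is available via `weighted = TRUE`.

**Variance convention.** Whether the variances above use the $n$ or the
$n-1$ denominator is a real choice in unbalanced multi-year data, and
reported ratios differ by a few percent between the two. The default is
the *population* convention ($n$), because it is the convention of the
moment-based niche-variation framework and it makes the law of total
variance exact: on any balanced design, WIC + AIC equals the pooled
population variance of all samples (the test suite verifies this to
1e-10). The `convention = "sample"` option gives the $n-1$ forms. Either
way the identity TNW = WIC + AIC holds by construction, and the ratio is
invariant to rescaling the isotope values.

Individuals need at least 2 samples of a tissue to contribute a
within-individual variance; individuals below that threshold are dropped
from that tissue's decomposition only (with a warning, or an error under
`on_few = "error"`).

With 3–6 samples per individual the among component is inflated by the
sampling noise of the per-individual means, so even a population with
*no* among-individual differences has an expected ratio below 1 (about
0.78 under the default design, estimated by Monte Carlo in the test
suite). Ratios should therefore be compared against that design-specific
baseline, not against 1.

Report tables round half-up to 2 decimals (`round_half_up()`), the
convention of published niche tables, rather than R's round-half-even.

## 2. The mixed-model engine

All inferential models are Gaussian linear mixed models

$$y = X\beta + \textstyle\sum_k Z_k b_k + \varepsilon, \qquad
  b_k \sim N(0, \sigma_k^2 I), \quad \varepsilon \sim N(0, \sigma_\varepsilon^2 I),$$

with *crossed* random intercepts for bird identity and year, and
optionally an independent (uncorrelated with the intercept) individual
random slope on a within-individual covariate. An intercept–slope
correlation is deliberately out of scope: with 3–6 observations per
individual it is rarely estimable, and the gating workflow (Section 4)
only asks whether slope *variance* is supported at all.

**Estimation.** Fixed effects and the residual variance are profiled out
analytically; the optimizer works on the standard-deviation ratios
$\theta_k = \sigma_k / \sigma_\varepsilon \ge 0$. The profiled REML
criterion matches the standard one (the test suite confirms agreement
with lme4 to 1e-6 on crossed and random-slope fits, with ANOVA
closed-form components on balanced one-way designs, and with the OLS
log-likelihood when the estimated group variance hits the boundary).
Two optimizer passes are used: L-BFGS-B with a lower bound of zero from
two starting points ($\theta = 1$ and $\theta = 0.1$), then a
Nelder–Mead polish on the folded scale $|\theta|$, because finite-
difference gradients are unreliable exactly where boundary estimates
live. Zero variance estimates are legitimate results and are reported
with a `singular` flag, never as failures. Models with a single random
intercept (the repeatability model) bypass the dense path entirely: the
marginal covariance is block-diagonal, so every likelihood evaluation
reduces to per-group sums and a one-dimensional profile in
$\gamma = \theta^2$ optimized by golden-section search. This makes a
1000-replicate parametric bootstrap of the repeatability SE cost a few
seconds. The dense crossed path builds the $n \times n$ marginal
covariance explicitly and is intended for the design scale it serves
($n \approx 130$); beyond a few thousand observations it is the wrong
tool.

**Inference.** P-values come from likelihood-ratio tests of ML fits.
Testing a single variance component places the null on the boundary of
the parameter space, so the reference distribution is the
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture; a numerically zero LR
(below 1e-8) is assigned to the point mass at zero, p = 1. AIC for
comparing fixed-effect structures is always computed from **ML** fits
($-2\ell + 2k$, $k$ = fixed coefficients + variance components,
including the residual): REML likelihoods of models with different fixed
effects are not comparable, even though variance components themselves
are reported from REML fits. Approximate Wald F statistics with
residual-containment denominator df are available (`wald_f()`) for
descriptive reporting, clearly flagged approximate; they are never the
primary inference path.

**R².** `r2_nakagawa()` reports the marginal and conditional R² on the
total-variance denominator: $\sigma^2_f$ is the variance of the fixed
linear predictor across the observations, each random intercept
contributes its variance, and an independent random slope contributes
its variance times the mean squared covariate.

## 3. Repeatability

`repeatability()` fits the intercept-only model with the individual as
the sole random factor — *agreement* repeatability
$R = \sigma^2_{ind} / (\sigma^2_{ind} + \sigma^2_{res})$, unadjusted,
because the among-year consistency question is asked separately from the
year-effect models. An adjusted variant (e.g. year as a fixed factor) is
available through `adjusted_for`. The standard error comes from a
parametric bootstrap (default 1000 refits, seeded, caller's RNG state
restored); the p-value from the boundary-corrected LRT above.
Validation at the design scale (30 individuals in 3–6 years each, true
R = 0.5, 200 replicates) recovers the mean within 0.05, and the null
rejection rate over 500 replicates stays at the nominal 5% level (the
null simulations set both the individual and the year variance to zero,
since the single-factor model's null distribution is defined without
crossed year effects).

## 4. Centering, standardization and the two model sets

`center_within_individual()` splits a covariate into the individual's
mean over *its own observed years* ($\bar x_j$, the among-individual
part) and the deviation $x_{ij} - \bar x_j$ (the within-individual
part). Both enter as separate fixed effects, so plasticity and stable
individual differences are estimated separately; the test suite verifies
the separation recovers distinct simulated within (+1) and between (−1)
coefficients with |bias| < 0.1 at design scale.

*Environmental set.* Each environmental index (SAM, SOI, SSTA) enters as
a two-month window mean: August–September of the sampling year for red
blood cells (prebreeding), February–March for feathers (premolt). Both
windows are taken from the same calendar year as sampling — the austral
season spans new year, but the tissues' integration periods fall within
the calendar year used — and are configurable rather than hard-coded.
The window value is shared by every bird sampled in a year; $\bar x_j$
still varies among individuals because they are observed in different
year subsets. One index per model, never several: the indices' window
means are strongly correlated over as few as seven study years
(`env_window_correlations()` reports the pairwise correlations), and the
package enforces the one-variable-per-model rule rather than inviting
collinear joint fits. Quadratic models square the *centered* covariates
(within² and between²), matching how quadratic within/between models are
conventionally labelled, not the raw index. With three indices, linear
and quadratic forms, four isotope responses and one null model each,
the full environmental stage is 28 models.

*Trait set.* Breeding traits (body mass in g, clutch initiation date as
day-of-season with day 1 = 1 October so that laying dates compare across
seasons, total clutch mass = A-egg + B-egg in g) are regressed on the
blood isotopes. Both trait and isotope are z-standardized *within year*
(sample SD) first, removing among-year level shifts; the isotope is then
centered within individual. δ¹⁵N and δ¹³C are modelled separately (they
are correlated), giving 3 traits × 2 covariates + 3 nulls = 9 models.
A year stratum with fewer than two distinct values has no z-score and
raises an error naming the year.

*Random-slope gate.* Individual variation in plasticity (random slopes)
is only interpretable once plasticity itself is supported, so the slope
model is fitted **only if** the within-individual fixed effect is
significant (ML LRT, default gate α = 0.05, configurable); otherwise the
result is marked "not evaluated" rather than "not significant". When the
gate opens, slope support is reported as a boundary LRT plus the AIC
difference against the intercepts-only model.

## 5. The synthetic-data generator

`synthetic_config()` defaults describe the study design the package was
built around: 30 females over the 2006–2013 span with no fieldwork in
2011 (7 sampled years), blood in 3–6 years per female with sampling
weights (0.25, 0.35, 0.25, 0.15) giving a mean of 4.3 years
(~130 records), feathers in the same years minus 2009, capped at 5
(mean ≈ 3.7, ~110 records). Isotope values are built additively from
independent Gaussian individual, year and residual effects per
tissue × isotope series. The default component magnitudes were set once
to echo the motivating system — strong among-individual structure in
blood (e.g. δ¹⁵N: σ²ᵢₙd 0.54, σ²ᵧᵣ 0.30, σ²ᵣₑₛ 0.29 ‰², giving
repeatability near 0.45 and WIC/TNW near 0.5) and weak structure in
feathers (σ²ᵢₙd 0.15) — and the default environmental and trait effect
sizes are **zero**, because a null environment is the motivating study's
own finding; simulations that need effects switch them on explicitly.
Environmental indices are monthly AR(1) series (marginal SD 1.2,
month-to-month persistence 0.3; the two-month window means then have
among-year SD near one index unit). Traits are linked on the
standardized scale, so configured β values are directly comparable to
the analysis stage's standardized coefficients, then mapped to natural
units (body mass 2450 ± 250 g, clutch initiation day 35 ± 4, total
clutch mass 190 ± 15 g with a jittered ~42/58 A/B-egg split whose sum is
exact). Generation is byte-reproducible per seed and leaves the caller's
RNG state untouched, and every latent draw is returned for recovery
tests.

What the generator does **not** emulate: isotopic baseline (isoscape)
shifts, non-Gaussian or heavy-tailed effects, correlations between the
four isotope series within a bird beyond what shared design induces, and
the enrollment history that produced the original per-year sample
ledger (the generator matches the marginal design summaries instead).
Passing simulation suites therefore demonstrates correctness of the
estimators under the model's own assumptions — not robustness to baseline
drift or distributional misspecification in real field data.

## 6. Validation sizes and numerical tolerances

The test suite runs, among others: brute-force equivalence of the
decomposition on all designs up to 5 × 5 (1e-12); the balanced law of
total variance (1e-10); ANOVA/OLS equivalences (1e-6); repeatability
recovery (200 replicates) and null level (500 replicates);
within/between coefficient recovery and slope-gate behaviour
(100–200 replicates each); a 5-point specialization sweep (50 seeds per
point); and the full-pipeline cardinality check (28 + 9 models). These
sizes keep the whole suite within a coffee break on one CPU while
leaving Monte-Carlo noise well below the asserted margins. One caveat
recorded here deliberately: per-replicate *relative* error of variance
components estimated from only 7 year levels (median ≈ 40%) or 30
individual levels (≈ 17%) is irreducible sampling spread, not estimator
error — the suite asserts unbiasedness across replicates instead, plus
tight per-replicate error for the residual component, and the exactness
checks against lme4 pin down the estimator itself.

## 7. Known limitations

- Inputs are assumed pre-corrected for capture-date effects; no
  correction model is included.
- The dense crossed-covariance path scales as $O(n^3)$ per likelihood
  evaluation; it is not meant for datasets beyond a few thousand rows.
- LRT p-values are asymptotic; at 7 year levels the year-variance test
  in particular should be read qualitatively.
- No generalized (non-Gaussian) responses, no Satterthwaite/Kenward–Roger
  degrees of freedom, no model averaging, no kernel or ellipse-based
  niche metrics — the decomposition here is the variance-component one.
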