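# isoniche

Quantifying individual foraging specialization and its consequences from
repeated stable-isotope measurements of marked animals.

Long-lived marine predators such as penguins are often "generalists" at
the population level while individual birds may each stick to a narrow
diet or foraging area. Repeated δ¹³C and δ¹⁵N measurements of the same
individuals across years — from tissues that integrate different parts of
the annual cycle, such as red blood cells (prebreeding) and feathers
(premolt) — let us ask three questions this package answers:

1. **How specialized are individuals?** The population's total isotopic
   niche width decomposes as

   *TNW = WIC + AIC*,

   where WIC (within-individual component) is the mean over individuals
   of the variance of each bird's repeated values, and AIC
   (among-individual component) is the variance of the per-individual
   mean values. The ratio **WIC/TNW ∈ (0, 1]** is 1 for a true generalist
   population and approaches 0 with increasing individual
   specialization.

2. **Are individuals consistent across years?** Among-year repeatability
   (intraclass correlation) *R = σ²ᵢₙd / (σ²ᵢₙd + σ²ᵣₑₛ)* from an
   intercept-only REML mixed model, with a parametric-bootstrap standard
   error and a boundary-corrected likelihood-ratio test
   (½χ²₀ + ½χ²₁ mixture).

3. **What drives the variation?** Gaussian linear mixed models with
   *crossed* individual and year random intercepts, where each covariate
   x is split into its among-individual part (the individual mean x̄ⱼ)
   and its within-individual part (xᵢⱼ − x̄ⱼ) so that phenotypic
   plasticity and stable individual differences get separate
   coefficients. Candidate drivers are two-month window means of
   environmental indices (SAM, SOI, local SSTA); breeding traits (body
   mass, clutch initiation date, total clutch mass) are regressed on the
   year-standardized blood isotopes the same way. Models are compared by
   ML AIC with marginal/conditional R² (variance explained by fixed
   effects alone vs fixed plus random), and individual random slopes are
   tested only after the within-individual fixed effect proves
   significant.

The mixed-model engine is implemented in the package itself (profiled
REML/ML over variance ratios, exact closed-form profile for a single
random intercept, dense marginal covariance for crossed designs) and is
validated in the test suite against closed-form balanced-ANOVA results,
OLS limits, and an independent implementation (lme4).

Because multi-year field data of this kind are rarely public, the
package ships a **synthetic-data generator** that emulates the study
design it was built around: 30 females followed over 2006–2013 with no
fieldwork in 2011, blood samples in 3–6 years per female (~130 records),
feathers in 2–5 years (none in 2009), crossed individual/year effects,
AR(1) monthly environmental series, and optional environment and trait
effect sizes with full ground-truth output for recovery tests.

## Worked example

```r
library(isoniche)

x  <- generate_dataset(synthetic_config(seed = 42))
ds <- filter_minimum_years(x$dataset)   # >= 3 blood years with complete
                                        # traits, >= 2 feather years

niche_decomposition(ds)
#> # A tibble: 4 × 9
#>   tissue         isotope   tnw    wic aic_niche ratio n_individuals n_samples
#> 1 red_blood_cell d15N    1.10  0.560      0.542 0.508            30       123
#> 2 red_blood_cell d13C    0.235 0.0998     0.135 0.424            30       123
#> 3 feather        d15N    0.451 0.287      0.164 0.636            30       104
#> 4 feather        d13C    0.656 0.462      0.195 0.703            30       104
```

`ratio` is WIC/TNW: blood δ¹⁵N at 0.51 means an average individual's
niche is about half as wide as the population's (moderate
specialization); feather δ¹³C at 0.70 is closer to a generalist pattern.

```r
blood <- dplyr::filter(ds$samples, tissue == "red_blood_cell")
repeatability(blood, "d15N", n_boot = 500, seed = 42)
#> # A tibble: 1 × 9
#>       r     se  p_value sigma2_group sigma2_residual n_obs n_groups n_boot  seed
#> 1 0.287 0.0986 0.000749        0.325           0.808   123       30    500     42
```

About 29% of the variance not attributable to years lies among
individuals; the boundary-corrected LRT rejects "no individual
consistency".

```r
build_environment_model_set(ds, "red_blood_cell", "d15N")
#> # A tibble: 7 × 11
#>   model                                        akaike_ic delta_aic r2_marginal r2_conditional
#> 1 Null                                              296.      0        0                0.731
#> 2 SOI within + between                              299.      2.64     0.0326           0.752
#> 3 SOI within + between + within^2 + between^2       299.      2.84     0.0696           0.741
#> ...
```

No environmental model beats the null by more than 2 AIC units — as
expected here, since the generator's default environmental effect sizes
are zero. The full sequence (filter → decomposition → repeatability →
28 environmental models → 9 trait models → tissue correlations) runs as
one call:

```r
report <- run_full_analysis(synthetic = synthetic_config(seed = 42))
write_analysis_report(report, "output/")
```

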