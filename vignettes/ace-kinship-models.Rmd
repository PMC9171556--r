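---
title: "Bivariate ACE models for kinship data with a registry survival stage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bivariate ACE models for kinship data with a registry survival stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinace)
```

## The scientific problem

Obsessive-compulsive phenotypes and substance misuse co-occur, and the
central question for aetiology is how much of that co-occurrence is carried
by shared genetic liability versus environmental pathways (for example
self-medication).  Relatives who differ in genetic sharing make the two
sources separable: monozygotic (MZ) twins share all segregating genes,
dizygotic (DZ) twins and full siblings (FS) about half, maternal
half-siblings (MHS) about a quarter, while all pair types are assumed to
share their common rearing environment equally.  `kinace` implements the
full analysis pipeline for this design: a synthetic-cohort generator, the
bivariate quantitative-genetic models, and the phenotypic epidemiological
stage (Cox regression with a time-varying diagnosis exposure, Kaplan-Meier
cumulative incidence, cluster-robust regression).

## The bivariate ACE model

For two traits per person, the model decomposes the within-person
phenotypic covariance matrix `P` (2x2) into additive-genetic, shared- and
nonshared-environment components,

    P = V_A + V_C + V_E,

and the cross-member covariance of a pair of relatives into

    R = r_A V_A + r_C V_C,     r_A in {1, 1/2, 1/4},  r_C = 1.

The stacked 4-vector of a pair is multivariate normal with covariance
`[[P, R], [R, P]]` (`implied_pair_covariance()`).  We use the
*direct-symmetric* parameterization: the entries of `V_A`, `V_C`, `V_E`
are themselves the free parameters, with no Cholesky or path-coefficient
constraint.  This keeps likelihood-ratio tests well calibrated (the null
is not on a boundary of a constrained parameterization) at the price of
occasionally negative variance estimates, which are reported as-is and
flagged; a component correlation is undefined (NA) when its variance
estimate is negative.

Two measurement types share this structure:

* **Continuous traits** enter a full-information ML likelihood: each pair
  contributes the 4-dimensional normal log-density of its observed values
  (marginalized over missing entries), with trait means linear in sex and
  birth year (`continuous_pair_loglik()`).
* **Binary diagnoses** use the liability-threshold model: a diagnosis is
  an underlying standard-normal liability exceeding a cutoff.  Total
  liability variance is fixed to 1 per trait for identification (the
  `V_E` diagonals are derived), and covariates shift the thresholds.
  Pairs are aggregated into 16-cell pattern counts per stratum of pair
  type, sexes and birth-decade bins, and each cell probability is a
  4-dimensional normal rectangle (`binary_pair_loglik()`).

Model selection follows the usual ladder ACE-ACE, AE-AE, CE-CE, E-E: a
reduced model is preferred when its likelihood-ratio test against the full
model is non-significant at 0.05, with AIC reported alongside
(`compare_models()`, `fit_ace_ladder()`).  From a fitted model,
`derived_estimates()` returns standardized variance shares, component
correlations (`rg`, `rc`, `re`), the share of the cross-trait covariance
carried by each component, and the implied phenotypic correlation, with
delta-method confidence intervals from the observed information.

### Numerics of the binary likelihood

The rectangle probabilities are the computational bottleneck.  The pair
covariance has the block structure `[[P, R], [R, P]]`, so conditional on a
shared bivariate factor `s ~ N(0, R)` the two members are independent with
residual covariance `U = P - R`.  The likelihood therefore evaluates each
stratum's 16 cell probabilities with a 2-dimensional Gauss-Hermite
quadrature over `s` (24 nodes per dimension by default) and a closed-form
bivariate normal CDF for the member-level quadrants — roughly three orders
of magnitude faster than generic 4-D integration, and accurate to about
1e-8 against it.  When a direct-symmetric excursion makes `R` or `U`
indefinite while the full 4x4 covariance is still valid, the code falls
back to generic rectangle integration (`mvn_rectangle()`, a deterministic
quasi-Monte-Carlo integrator run under a fixed internal seed so the
objective is noiseless); if the 4x4 covariance itself is invalid the
likelihood returns a large finite penalty so the optimizer can retreat.

Optimization uses `nlminb` on the free parameters with moment-based
starting values: Falconer-style estimates (`2(r_MZ - r_DZ)` and its
sibling-design analogues) for continuous traits, tetrachoric correlations
(`tetrachoric_mle()`) for binary traits, with up to 5 jittered restarts on
failure.  Standard errors come from the numerically differentiated
observed information.

## The synthetic-cohort generator

No individual-level data from the motivating registry and twin studies are
public, so the package generates cohorts whose *population parameters are
the published estimates*; shipped presets (`load_preset()`) transcribe
them:

* **`catss-twin`** — MZ/DZ pairs with two continuous standardized symptom
  scores under the published twin AE solution: heritabilities 36% and 46%,
  genetic correlation 0.31, nonshared-environment correlation 0.10
  (implied phenotypic correlation 0.185).  4000 MZ and 5000 DZ pairs,
  births 1993-2001, 60.1% women.
* **`population-liability`** — FS/MHS pairs with binary diagnoses under
  the published sibling AE solution: liability heritabilities 55% and
  57%, rg 0.28, re 0.27, lifetime prevalences 0.43% (OCD) and 5.79% (any
  substance misuse).  200 000 FS and 20 000 MHS pairs.  Thresholds are
  calibrated at load time so the marginal prevalence matches the target
  given the preset's sex and birth-year shifts (solved by `uniroot` on the
  exact mixture tail probability).
* **`population-registry`** — registry follow-up from 1997 (or the 15th
  birthday) to end of 2013 on the age timescale, with a lognormal
  diagnosis-age distribution matching the published median 28.0 and IQR
  20.3-39.8, piecewise-constant baseline hazards on 5-year age bands, and
  true exposure log hazard ratios log(4.51) and log(6.69) for the
  alcohol- and drug-related outcome categories.
* **`catss-bocs`** — a 12-item binary symptom checklist whose equal probit
  loadings are calibrated analytically (Spearman-Brown) so Cronbach's
  alpha is 0.76 at ~30% item endorsement.

Generation draws explicit shared and member-unique component factors
(`sqrt(r_A) A_shared + sqrt(1 - r_A) A_unique + C_shared + E_unique`), so
MZ pairs with no E variance are identical by construction and the
cross-member covariance is exact by algebra rather than by matrix square
roots of the stacked covariance.

### Deliberate scaled-down choices

Scientific choices where the source material leaves the design open, made
once and kept:

* **Registry exposure prevalence 5%.**  The registry's OCD prevalence is
  0.43%, but at the package's default cohort of 100 000 persons that
  leaves too few exposed events for a stable hazard-ratio estimate
  (the motivating register had 6.3 million people).  Raising the
  lifetime diagnosis probability to 5% preserves the expected number of
  exposed events per outcome (>100) under the 63-fold smaller cohort; all
  hazard ratios are conditional effects and unaffected by exposure
  prevalence under the proportional-hazards model.
* **Figure-track calibration of the combined outcome.**  The published
  cumulative-incidence curves show ~5% of the general population and ~23%
  of people with a lifetime OCD diagnosis experiencing an alcohol- or
  drug-related disorder by age 32.  The 23% marginal track cannot be
  produced by the published *conditional* hazard ratio alone (exposure
  switches on only at diagnosis, median age 28, and the marginal contrast
  also carries comorbidity confounding), so the combined `any_substance`
  category's baseline (0.00376/year) and exposure effect (1.89) are
  calibrated directly to the two curve anchors.  That effect is a
  marginal, curve-matching quantity, deliberately distinct from the
  conditional log hazard ratios used for the alcohol and drug categories.
* **Covariate effects.**  The sources state only that models were
  "adjusted for sex and birth year"; the presets use sex and
  linear-per-decade birth-year effects sized from the published
  sex-specific prevalence tables (e.g. -0.36 liability SD for women on
  substance misuse) with a mild 0.1 SD/decade secular trend.
* **Disjoint pairs.**  Real register data let the same person appear in a
  full-sibling and a half-sibling pair; the generator emits disjoint
  pairs only, and the fitter accordingly assumes independent pairs.
* **Birth-year binning.**  The binary likelihood bins birth years into
  decades (midpoints carry the threshold shift) to keep the cell-count
  likelihood exact and fast; generation uses exact years, a deliberate
  small model mismatch with negligible attenuation.

What passing tests on these cohorts does *not* show: robustness to
ascertainment, diagnostic misclassification, sibling non-independence,
competing risks, or secular changes in register coverage — none of which
the generator emulates.

## The phenotypic stage

`build_counting_process()` converts registry persons into (start, stop]
rows with the diagnosis as a time-varying exposure (a diagnosis before
entry yields a fully exposed record); `cox_fit()` wraps
`survival::coxph` on the age timescale with Efron tie handling and
delayed-entry risk sets; `km_cumulative_incidence()` computes 1 minus the
product-limit estimate per group with log(-log) Greenwood intervals
(assuming no competing risks, as in the published curves);
`ols_cluster_robust()` z-scores outcome and exposure and applies the
cluster sandwich with the `G/(G-1) * (N-1)/(N-k)` small-sample factor.
Sex-stratified estimates are obtained by subsetting rather than
interaction terms.

## Problem sizes and tolerances

The test suite and the acceptance script run the designs at the preset
sizes above (220 000 binary pairs, 9000 twin pairs, 100 000-200 000
registry persons); recovery *property* tests use 20 replicates at reduced
sizes (e.g. 1600 twin pairs, 9000 sibling pairs at raised prevalences,
15 000-person registries) and require every structural parameter within 3
estimated standard errors in at least 18 of 20 replicates.  Integration
accuracy targets: 1e-6 absolute for `mvn_rectangle` (checked against
plain Monte Carlo), ~1e-8 agreement between the quadrature and rectangle
routes of the binary likelihood, 1e-8 agreement of both likelihoods with
per-observation brute-force oracles.  Optimizer convergence is declared
at a gradient norm below `1e-3 * max(1, |loglik|)` with up to five
jittered restarts.

Known limitations: no sex-limitation or gene-environment interaction
models, at most two traits, no ascertainment correction, no polychoric
(>2 category) support, and delta-method (not profile) confidence
intervals.
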