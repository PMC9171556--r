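# Population-cohort preset: full-sibling and maternal half-sibling pairs
# with two binary lifetime diagnoses (OCD; any substance misuse) generated
# by thresholding bivariate-AE liabilities.  Structural values follow the
# best-fitting AE-AE liability decomposition reported for the Swedish
# national-register sibling cohort: A explains 55%/57% of the liability
# variance, E the remainder; genetic correlation 0.28, nonshared-
# environment correlation 0.27.
kind: pairs_binary
traits: [ocd, substance_misuse]
shares:
  a2: [0.55, 0.57]
  e2: [0.45, 0.43]
  rg: 0.28
  re: 0.27
# Lifetime register prevalences: OCD 27342 / 6304188; any substance misuse
# outcome (5444 + 359393) / 6304188.  Thresholds are calibrated at load
# time so the MARGINAL prevalence matches these targets given the
# covariate shifts below.
prevalences: [0.0043371, 0.0578722]
counts:
  FS: 200000
  MHS: 20000
covariates:
  # Liability mean shifts (sex coded 1 = female).  OCD is diagnosed more
  # often in women (+0.114 liability SD, matching a ~1.4x female/male
  # prevalence ratio); substance misuse is more common in men (-0.361,
  # matching ~7.7% male vs ~3.7% female lifetime risk).  A mild secular
  # increase of 0.1 SD/decade reflects growing register coverage.
  sex_effect: [0.114, -0.361]
  birth_year_effect: [0.10, 0.10]
  p_female: 0.489
  birth_window: [1970, 1997]
  ref_year: 1984
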