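# Twin-cohort preset: MZ/DZ pairs with two continuous standardized symptom
# scores (obsessive-compulsive symptoms, alcohol dependence symptoms).
# Structural values follow the best-fitting AE-AE decomposition reported for
# the Swedish CATSS twin cohort at age 18: A explains 36%/46% of the two
# traits' variance, E the remainder; genetic correlation 0.31, nonshared-
# environment correlation 0.10 (implied phenotypic correlation 0.185).
kind: pairs_continuous
traits: [ocs, alcohol_dep]
shares:
  a2: [0.36, 0.46]
  e2: [0.64, 0.54]
  rg: 0.31
  re: 0.10
counts:
  MZ: 4000
  DZ: 5000
covariates:
  # mean shifts in SD units; sex coded 1 = female; birth year per decade.
  # Small effects chosen to exercise the adjustment machinery: women score
  # slightly higher on obsessive-compulsive symptoms and lower on alcohol
  # dependence symptoms; a mild secular trend in both.
  sex_effect: [0.05, -0.15]
  birth_year_effect: [0.02, 0.05]
  p_female: 0.601        # cohort share of women
  birth_window: [1993, 2001]
  ref_year: 1997
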