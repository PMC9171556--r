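fit_small_pair_set <- function(counts = c(MZ = 1200, DZ = 1500), seed = 101,
                               components = cm_twin()) {
  simulate_kin_pairs(components, counts, seed = seed)
}

test_that("a single pair type is rejected as unidentifiable", {
  pairs <- fit_small_pair_set(c(MZ = 200))
  expect_error(fit_ace(pairs, ace_model_spec(c("A", "E"))),
               "distinct genetic relatedness")
  # DZ and FS share r_A = 0.5: still unidentifiable for A vs C
  pairs2 <- fit_small_pair_set(c(DZ = 100, FS = 100))
  expect_s3_class(fit_ace(pairs2, ace_model_spec(c("A", "E"),
                                                 covariates = character(0))),
                  "ace_fit")
})

test_that("null components are recovered near zero", {
  cm0 <- ace_components(V_A = 0, V_C = 0, V_E = c(1, 1, 0.2))
  pairs <- simulate_kin_pairs(cm0, c(MZ = 10000, DZ = 10000), seed = 103)
  fit <- fit_ace(pairs, ace_model_spec(c("A", "C", "E"),
                                       covariates = character(0)))
  expect_true(fit$convergence$converged)
  de <- suppressWarnings(derived_estimates(fit))
  for (q in c("a2_1", "a2_2", "c2_1", "c2_2")) {
    row <- de[de$quantity == q, ]
    # 0.03 band, widened to 3 SEs where Monte-Carlo noise exceeds it
    expect_lt(abs(row$estimate), max(0.03, 3 * row$se), label = q)
  }
})

test_that("AE heritability agrees with the Falconer moment estimate", {
  # sizeable sample: the Falconer moment estimator itself carries
  # sampling noise ~0.02 here, so +/-0.05 is a three-sigma agreement band
  pairs <- fit_small_pair_set(counts = c(MZ = 12000, DZ = 12000), seed = 107)
  fit <- fit_ace(pairs, ace_model_spec(c("A", "E"), covariates = character(0)))
  de <- suppressWarnings(derived_estimates(fit))
  mz <- pairs[pairs$pair_type == "MZ", ]
  dz <- pairs[pairs$pair_type == "DZ", ]
  for (tr in 1:2) {
    rmz <- cor(mz[[paste0("m1_trait", tr)]], mz[[paste0("m2_trait", tr)]])
    rdz <- cor(dz[[paste0("m1_trait", tr)]], dz[[paste0("m2_trait", tr)]])
    falconer <- 2 * (rmz - rdz)
    a2 <- de$estimate[de$quantity == paste0("a2_", tr)]
    expect_lt(abs(a2 - falconer), 0.05)
  }
})

test_that("refitting with traits swapped transposes the solution", {
  pairs <- fit_small_pair_set(counts = c(MZ = 800, DZ = 1000), seed = 109)
  sw <- pairs
  sw[, c("m1_trait1", "m1_trait2", "m2_trait1", "m2_trait2")] <-
    pairs[, c("m1_trait2", "m1_trait1", "m2_trait2", "m2_trait1")]
  f1 <- fit_ace(pairs, ace_model_spec(c("A", "E"), covariates = character(0)))
  f2 <- fit_ace(sw, ace_model_spec(c("A", "E"), covariates = character(0)))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  d1 <- suppressWarnings(derived_estimates(f1))
  d2 <- suppressWarnings(derived_estimates(f2))
  g <- function(d, q) d$estimate[d$quantity == q]
  expect_equal(g(d1, "rg"), g(d2, "rg"), tolerance = 1e-4)
  expect_equal(g(d1, "re"), g(d2, "re"), tolerance = 1e-4)
  expect_equal(g(d1, "a2_1"), g(d2, "a2_2"), tolerance = 1e-4)
})

test_that("model comparisons follow LRT and AIC identities", {
  pairs <- fit_small_pair_set(counts = c(MZ = 600, DZ = 800), seed = 113)
  full <- fit_ace(pairs, ace_model_spec(c("A", "C", "E"),
                                        covariates = character(0)))
  ae <- fit_ace(pairs, ace_model_spec(c("A", "E"), covariates = character(0)))
  cmp <- compare_models(full, ae)
  expect_identical(cmp$df, 3L + 0L)  # dropping the three free V_C entries
  expect_gte(cmp$lrt, 0)
  expect_equal(cmp$delta_aic, -2 * (ae$loglik - full$loglik) +
                 2 * (ae$npar - full$npar), tolerance = 1e-10)
  expect_equal(cmp$p_value,
               pchisq(cmp$lrt, df = 3, lower.tail = FALSE), tolerance = 1e-12)
  # identical fits: LRT 0, p = 1, reduced preferred
  cmp0 <- compare_models(full, full_as_reduced <- local({
    x <- full; x$spec$components <- c("A", "E"); x$npar <- full$npar - 3L
    x$AIC <- -2 * x$loglik + 2 * x$npar; x
  }))
  expect_equal(cmp0$lrt, 0, tolerance = 1e-9)
  expect_equal(cmp0$p_value, 1)
  expect_identical(cmp0$preferred, "AE")
  expect_error(compare_models(ae, full), "nested")
})

test_that("the model ladder selects a parsimonious adequate model", {
  pairs <- fit_small_pair_set(counts = c(MZ = 1500, DZ = 1800), seed = 127)
  lad <- fit_ace_ladder(pairs, covariates = character(0))
  expect_named(lad$fits, c("ACE", "AE", "CE", "E"))
  expect_named(lad$comparisons, c("AE", "CE", "E"))
  # data generated under AE: E-only must be rejected, AE must be adequate
  expect_lt(lad$comparisons$E$p_value, 0.001)
  expect_gt(lad$comparisons$AE$p_value, 0.01)
  expect_identical(lad$best, "AE")
})

test_that("derived estimates reproduce published component identities", {
  de_pop <- derived_estimates(cm_pop())
  g <- function(d, q) d$estimate[d$quantity == q]
  expect_equal(g(de_pop, "rg"), 0.28, tolerance = 1e-10)
  expect_equal(g(de_pop, "re"), 0.27, tolerance = 1e-10)
  expect_equal(g(de_pop, "r_phenotypic"),
               0.28 * sqrt(0.55 * 0.57) + 0.27 * sqrt(0.45 * 0.43),
               tolerance = 1e-12)
  # standardized shares sum to one per trait
  expect_equal(g(de_pop, "a2_1") + g(de_pop, "c2_1") + g(de_pop, "e2_1"), 1,
               tolerance = 1e-10)
  # negative diagonal: correlation undefined with a warning
  neg <- ace_components(V_A = c(-0.1, 0.3, 0.05), V_E = c(1.1, 0.7, 0.1),
                        check = "fitting")
  expect_warning(de_neg <- derived_estimates(neg), "undefined")
  expect_true(is.na(g(de_neg, "rg")))
})
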