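all_pattern_cells <- function(pair_type = "FS", count = 10,
                              sex = 0, byc = 1985) {
  pats <- expand.grid(y22 = 0:1, y21 = 0:1, y12 = 0:1, y11 = 0:1)
  data.frame(pair_type = pair_type, sex1 = sex, sex2 = sex,
             byc1 = byc, byc2 = byc,
             y11 = pats$y11, y12 = pats$y12, y21 = pats$y21, y22 = pats$y22,
             count = count)
}

test_that("independent unit liabilities give uniform 16-cell probabilities", {
  cm <- ace_components(V_A = 0, V_C = 0, V_E = diag(2))
  thr <- rbind(c(0, 0, 0), c(0, 0, 0))
  cells <- all_pattern_cells(count = 10)
  ll <- binary_pair_loglik(cm, thr, cells, ref_year = 1985)
  expect_equal(as.numeric(ll), 160 * log(0.0625), tolerance = 1e-8)
})

test_that("aggregated likelihood equals the per-pair rectangle product", {
  cm <- cm_pop()
  thr <- rbind(c(0.9, -0.11, -0.1), c(0.4, 0.36, -0.1))
  cov_mod <- pair_covariate_model(sex_effect = c(0.11, -0.36),
                                  birth_year_effect = c(0.1, 0.1),
                                  p_female = 0.5,
                                  birth_window = c(1972, 1995),
                                  ref_year = 1984)
  pairs <- simulate_kin_pairs(cm, c(FS = 30, MHS = 20),
                              thresholds = c(0.9, 0.4),
                              covariate_effects = cov_mod, seed = 89)
  cells <- aggregate_binary_pairs(pairs)
  ll <- binary_pair_loglik(cm, thr, cells, ref_year = 1984, gh_points = 40)
  # oracle: per-pair 4-D rectangle probabilities by nested adaptive
  # conditioning (independent of the shared-factor quadrature)
  bin <- function(by) floor(by / 10) * 10 + 5
  oracle <- 0
  for (i in seq_len(nrow(pairs))) {
    S <- implied_pair_covariance(cm, pairs$pair_type[i])
    a1 <- thr[, 1] + thr[, 2] * pairs$m1_sex[i] +
      thr[, 3] * (bin(pairs$m1_by[i]) - 1984) / 10
    a2 <- thr[, 1] + thr[, 2] * pairs$m2_sex[i] +
      thr[, 3] * (bin(pairs$m2_by[i]) - 1984) / 10
    y <- as.numeric(pairs[i, c("m1_trait1", "m1_trait2",
                               "m2_trait1", "m2_trait2")])
    thr4 <- c(a1, a2)
    lo <- ifelse(y == 1, thr4, -Inf)
    hi <- ifelse(y == 1, Inf, thr4)
    oracle <- oracle + log(oracle_rect4(lo, hi, S))
  }
  expect_equal(as.numeric(ll), oracle, tolerance = 1e-8)
})

test_that("splitting a stratum leaves the likelihood unchanged", {
  cm <- cm_pop()
  thr <- rbind(c(1.2, 0, 0), c(0.6, 0, 0))
  cells <- all_pattern_cells(count = 6)
  split_cells <- rbind(transform(cells, count = 2),
                       transform(cells, count = 4))
  expect_equal(as.numeric(binary_pair_loglik(cm, thr, cells)),
               as.numeric(binary_pair_loglik(cm, thr, split_cells)),
               tolerance = 1e-10)
})

test_that("non-PSD cross-covariance falls back to direct integration", {
  # direct-symmetric excursion: V_A indefinite but total pair covariance PD
  cm <- ace_components(V_A = c(0.1, 0.1, 0.25), V_C = 0,
                       V_E = c(0.9, 0.9, -0.05), check = "none")
  thr <- rbind(c(0.8, 0, 0), c(0.8, 0, 0))
  cells <- all_pattern_cells(pair_type = "FS", count = 3)
  ll <- binary_pair_loglik(cm, thr, cells)
  expect_true(is.finite(as.numeric(ll)))
  expect_null(attr(ll, "penalized"))
  # cross-check one cell against the oracle
  S <- implied_pair_covariance(cm, "FS")
  p11 <- oracle_rect4(c(0.8, 0.8, 0.8, 0.8), rep(Inf, 4), S)
  pm <- kinace:::cell_probs_rectangles(S, c(0.8, 0.8), c(0.8, 0.8))
  expect_lt(abs(pm[4, 4] - p11), 2e-6)   # both integrators' absolute error
})

test_that("likelihood is invariant to swapping binary pair members", {
  cm <- cm_pop()
  thr <- rbind(c(1.0, -0.1, 0.1), c(0.5, 0.3, 0.1))
  pairs <- simulate_kin_pairs(cm, c(FS = 200, MHS = 100),
                              thresholds = c(1, 0.5), seed = 97)
  swapped <- pairs
  swapped[, c("m1_trait1", "m1_trait2", "m1_sex", "m1_by")] <-
    pairs[, c("m2_trait1", "m2_trait2", "m2_sex", "m2_by")]
  swapped[, c("m2_trait1", "m2_trait2", "m2_sex", "m2_by")] <-
    pairs[, c("m1_trait1", "m1_trait2", "m1_sex", "m1_by")]
  expect_equal(as.numeric(binary_pair_loglik(cm, thr,
                                             aggregate_binary_pairs(pairs))),
               as.numeric(binary_pair_loglik(cm, thr,
                                             aggregate_binary_pairs(swapped))),
               tolerance = 1e-8)
})

test_that("unit-variance identification is enforced", {
  cm <- ace_components(V_A = c(0.5, 0.5, 0.1), V_E = c(0.4, 0.4, 0.1),
                       check = "none")
  expect_error(binary_pair_loglik(cm, matrix(0, 2, 3),
                                  all_pattern_cells()),
               "unit total variance")
})
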