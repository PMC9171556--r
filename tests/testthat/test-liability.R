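test_that("threshold and prevalence are exact inverses", {
  expect_identical(threshold_from_prevalence(0.5), 0)
  # registry-scale prevalence: 27342 cases among 6304188 persons
  expect_equal(threshold_from_prevalence(27342 / 6304188), 2.624633,
               tolerance = 1e-6)
  p <- c(1e-5, 0.004337, 0.057872, 0.3, 0.9)
  expect_equal(prevalence_from_threshold(threshold_from_prevalence(p)), p,
               tolerance = 1e-12)
  expect_error(threshold_from_prevalence(0), "inside")
  expect_error(threshold_from_prevalence(1.2), "inside")
})

test_that("rectangle probabilities match closed forms", {
  # 4-D independence: positive orthant has probability 1/16
  p4 <- mvn_rectangle(rep(0, 4), rep(Inf, 4), diag(4))
  expect_equal(as.numeric(p4), 1 / 16, tolerance = 2e-6)
  # bivariate orthant: 1/4 + asin(rho)/(2 pi) = 1/3 at rho = 0.5
  p2 <- mvn_rectangle(c(0, 0), c(Inf, Inf),
                      matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(as.numeric(p2), 1 / 3, tolerance = 1e-10)
})

test_that("orthant probabilities of any 4-D correlation sum to one", {
  set.seed(43)
  corr <- random_corr4()
  total <- 0
  for (i in 0:15) {
    signs <- as.integer(intToBits(i))[1:4]
    lo <- ifelse(signs == 1, 0, -Inf)
    hi <- ifelse(signs == 1, Inf, 0)
    total <- total + as.numeric(mvn_rectangle(lo, hi, corr))
  }
  expect_equal(total, 1, tolerance = 4e-6)
})

test_that("rectangle probability is deterministic and validated", {
  corr <- random_corr4()
  a <- mvn_rectangle(rep(-1, 4), c(0.5, 1, 2, Inf), corr)
  b <- mvn_rectangle(rep(-1, 4), c(0.5, 1, 2, Inf), corr)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_lt(attr(a, "error"), 1e-6)
  expect_error(mvn_rectangle(rep(0, 3), rep(1, 3), diag(3)), "dimensions")
  bad <- matrix(1, 4, 4)
  expect_error(mvn_rectangle(rep(0, 4), rep(1, 4), bad), "positive definite")
  expect_error(mvn_rectangle(c(0, 0), c(-1, 1), diag(2)), "strictly below")
})

test_that("rectangle probabilities agree with plain Monte Carlo", {
  set.seed(47)
  for (rep in 1:3) {
    corr <- random_corr4()
    lo <- sort(rnorm(4))[c(1, 3, 2, 4)] - 0.5
    hi <- lo + runif(4, 0.8, 3)
    p <- as.numeric(mvn_rectangle(lo, hi, corr))
    mc <- mc_rect4(lo, hi, corr, n = 1e6, seed = 100 + rep)
    expect_lt(abs(p - mc$p), 3 * mc$se + 1e-6)
  }
})

test_that("bivariate orthant probability increases monotonically in rho", {
  rhos <- seq(-0.9, 0.9, by = 0.15)
  ps <- vapply(rhos, function(r) {
    as.numeric(mvn_rectangle(c(0, 0), c(Inf, Inf),
                             matrix(c(1, r, r, 1), 2)))
  }, numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("tetrachoric MLE recovers independence and closed-form cases", {
  # counts proportional to products of margins: independence
  tab <- outer(c(700, 300), c(600, 400)) / 1000
  est <- tetrachoric_mle(tab)
  expect_lt(abs(est$rho), 1e-4)
  # thresholds fixed at zero with orthant probabilities of rho = 0.5
  tab2 <- matrix(c(1 / 3, 1 / 6, 1 / 6, 1 / 3), 2) * 1200
  est2 <- tetrachoric_mle(tab2, thresholds = c(0, 0))
  expect_equal(est2$rho, 0.5, tolerance = 1e-4)
  expect_true(is.finite(est2$se))
})

test_that("tetrachoric MLE flags boundary and degenerate tables", {
  expect_warning(out <- tetrachoric_mle(matrix(c(50, 0, 0, 50), 2)),
                 "clamped")
  expect_equal(out$rho, 1 - 1e-6)
  expect_true(out$clamped)
  expect_warning(out2 <- tetrachoric_mle(matrix(c(0, 30, 70, 0), 2)),
                 "clamped")
  expect_equal(out2$rho, -(1 - 1e-6))
  expect_error(tetrachoric_mle(matrix(c(0, 0, 30, 70), 2)), "margins")
})

test_that("tetrachoric MLE matches a brute-force grid search", {
  set.seed(53)
  for (rep in 1:4) {
    rho <- runif(1, -0.8, 0.8)
    tau <- c(runif(1, -0.8, 0.8), runif(1, -0.8, 0.8))
    n <- 2000
    z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    tab <- table(factor(z1 >= tau[1], c(FALSE, TRUE)),
                 factor(z2 >= tau[2], c(FALSE, TRUE)))
    est <- tetrachoric_mle(tab)
    # grid search over rho at the margin-implied thresholds
    grid <- seq(-0.999, 0.999, by = 1e-3)
    p1 <- sum(tab[2, ]) / n; p2 <- sum(tab[, 2]) / n
    t1 <- qnorm(p1, lower.tail = FALSE); t2 <- qnorm(p2, lower.tail = FALSE)
    ll <- vapply(grid, function(r) {
      p11 <- mvtnorm::pmvnorm(lower = c(t1, t2), upper = c(Inf, Inf),
                              corr = matrix(c(1, r, r, 1), 2),
                              algorithm = mvtnorm::Miwa(steps = 128))[1]
      pr <- c(1 - p1 - p2 + p11, p2 - p11, p1 - p11, p11)
      ns <- c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
      if (any(pr[ns > 0] <= 0)) return(-Inf)
      sum(ns[ns > 0] * log(pr[ns > 0]))
    }, numeric(1))
    expect_lt(abs(est$rho - grid[which.max(ll)]), 2e-3)
  }
})
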