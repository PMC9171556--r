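# Independent oracles used across test files.

# 4-D normal rectangle probability by sequential conditioning with nested
# adaptive quadrature: integrate over x1 and x2 the conditional bivariate
# normal rectangle of (x3, x4), which has a closed form.  Independent of
# both in-package integration routes (shared-factor quadrature and QMC).
oracle_rect4 <- function(lower, upper, Sigma) {
  stopifnot(length(lower) == 4L, length(upper) == 4L)
  phi2_rect <- function(lo, hi, mu, S) {
    sd <- sqrt(diag(S)); rho <- S[1, 2] / prod(sd)
    l <- (lo - mu) / sd; h <- (hi - mu) / sd
    p2 <- function(a, b) {
      if (a <= -8 || b <= -8) return(0)
      if (a >= 8 && b >= 8) return(1)
      if (a >= 8) return(stats::pnorm(b))
      if (b >= 8) return(stats::pnorm(a))
      mvtnorm::pmvnorm(lower = c(-Inf, -Inf), upper = c(a, b),
                       corr = matrix(c(1, rho, rho, 1), 2),
                       algorithm = mvtnorm::Miwa(steps = 128))[1]
    }
    p2(h[1], h[2]) - p2(l[1], h[2]) - p2(h[1], l[2]) + p2(l[1], l[2])
  }
  S11 <- Sigma[1:2, 1:2]; S12 <- Sigma[1:2, 3:4]
  S22 <- Sigma[3:4, 3:4]
  B <- t(solve(S11, S12))            # regression of (x3,x4) on (x1,x2)
  Scond <- S22 - B %*% S12
  sd1 <- sqrt(S11[1, 1])
  inner <- function(x1) {
    # conditional law of x2 | x1
    mu2 <- S11[1, 2] / S11[1, 1] * x1
    s2 <- sqrt(S11[2, 2] - S11[1, 2]^2 / S11[1, 1])
    f2 <- function(x2) {
      vapply(x2, function(z) {
        mu34 <- as.numeric(B %*% c(x1, z))
        phi2_rect(lower[3:4], upper[3:4], mu34, Scond)
      }, numeric(1)) * stats::dnorm(x2, mu2, s2)
    }
    stats::integrate(f2, max(lower[2], mu2 - 9 * s2), min(upper[2], mu2 + 9 * s2),
                     rel.tol = 1e-9, abs.tol = 1e-13)$value
  }
  f1 <- function(x1) vapply(x1, inner, numeric(1)) * stats::dnorm(x1, 0, sd1)
  stats::integrate(f1, max(lower[1], -9 * sd1), min(upper[1], 9 * sd1),
                   rel.tol = 1e-9, abs.tol = 1e-13)$value
}

# Plain Monte-Carlo estimate of a 4-D rectangle probability with its
# standard error, drawn in chunks to bound memory.
mc_rect4 <- function(lower, upper, corr, n = 1e6, seed = 42, chunk = 5e5) {
  set.seed(seed)
  L <- t(chol(corr))
  hits <- 0; total <- 0
  while (total < n) {
    m <- min(chunk, n - total)
    z <- matrix(stats::rnorm(m * 4), 4, m)
    x <- L %*% z
    ok <- colSums(x >= lower & x <= upper) == 4L
    hits <- hits + sum(ok); total <- total + m
  }
  p <- hits / total
  list(p = p, se = sqrt(p * (1 - p) / total))
}

# Random positive-definite 4x4 correlation matrix.
random_corr4 <- function() {
  A <- matrix(stats::rnorm(16), 4)
  S <- crossprod(A) + diag(4) * 0.5
  d <- sqrt(diag(S))
  S / tcrossprod(d)
}

# Brute-force one-parameter Cox partial likelihood (Breslow-free: data
# must have untied event times), with delayed-entry risk sets.
oracle_cox_loglik <- function(beta, rows) {
  ev <- rows[rows$event == 1, ]
  ll <- 0
  for (i in seq_len(nrow(ev))) {
    t_i <- ev$stop_age[i]
    at_risk <- rows$start_age < t_i & rows$stop_age >= t_i
    ll <- ll + beta * ev$exposed[i] -
      log(sum(exp(beta * rows$exposed[at_risk])))
  }
  ll
}

# small helpers for building component sets quickly
cm_pop <- function() components_from_shares(a2 = c(0.55, 0.57),
                                            e2 = c(0.45, 0.43),
                                            rg = 0.28, re = 0.27)
cm_twin <- function() components_from_shares(a2 = c(0.36, 0.46),
                                             e2 = c(0.64, 0.54),
                                             rg = 0.31, re = 0.10)
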