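#' Liability threshold for a given prevalence
#'
#' Under the liability-threshold model a binary diagnosis corresponds to a
#' standard-normal liability exceeding a cutoff; the cutoff is the upper-tail
#' normal quantile of the prevalence.
#'
#' @param p Prevalence, in (0, 1).
#' @return The liability cutoff \code{z} with \code{P(Z >= z) = p}.
#' @examples
#' threshold_from_prevalence(0.5)        # 0
#' threshold_from_prevalence(0.004337)   # approx 2.62
#' @export
threshold_from_prevalence <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("prevalence must lie strictly inside (0, 1)")
  }
  stats::qnorm(p, lower.tail = FALSE)
}

#' Prevalence implied by a liability threshold
#'
#' Inverse of \code{\link{threshold_from_prevalence}}.
#'
#' @param z Liability cutoff.
#' @return Upper-tail probability \code{P(Z >= z)}.
#' @export
prevalence_from_threshold <- function(z) {
  stats::pnorm(z, lower.tail = FALSE)
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
# state afterwards.  Used so that quasi-Monte-Carlo rectangle probabilities
# are deterministic (noiseless objectives for the optimizer).
with_fixed_seed <- function(expr, seed = 20260928L) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Vectorized bivariate standard normal CDF P(X <= h, Y <= k) with common
# correlation rho.  Gauss-Legendre quadrature on the Drezner-Wesolowsky
# arcsine identity; accurate to ~1e-14 for |rho| <= 0.925.  Larger |rho|
# falls back to deterministic per-element integration via mvtnorm.
pbvnorm <- function(h, k, rho) {
  stopifnot(length(rho) == 1L, is.finite(rho), abs(rho) <= 1)
  n <- max(length(h), length(k))
  h <- rep_len(as.numeric(h), n)
  k <- rep_len(as.numeric(k), n)
  # clamp: beyond |8| the remaining normal mass is < 1e-15
  h <- pmin(pmax(h, -8), 8)
  k <- pmin(pmax(k, -8), 8)
  if (rho == 0) return(stats::pnorm(h) * stats::pnorm(k))
  if (abs(rho) <= 0.925) {
    # 20-point Gauss-Legendre on [0, asin(rho)]
    gl_x <- c(0.0765265211334973, 0.2277858511416451, 0.3737060887154196,
              0.5108670019508271, 0.6360536807265150, 0.7463319064601508,
              0.8391169718222188, 0.9122344282513259, 0.9639719272779138,
              0.9931285991850949)
    gl_w <- c(0.1527533871307259, 0.1491729864726037, 0.1420961093183821,
              0.1316886384491766, 0.1181945319615184, 0.1019301198172404,
              0.0832767415767048, 0.0626720483341091, 0.0406014298003869,
              0.0176140071391521)
    asr <- asin(rho)
    sn <- sin(asr / 2 * c(1 - gl_x, 1 + gl_x))   # length 20 nodes
    w  <- c(gl_w, gl_w)
    hk <- h * k
    hs <- (h * h + k * k) / 2
    # integrand matrix: nodes x n, summed with weights
    acc <- numeric(n)
    for (j in seq_along(sn)) {
      acc <- acc + w[j] * exp((sn[j] * hk - hs) / (1 - sn[j]^2))
    }
    p <- acc * asr / (4 * pi) + stats::pnorm(h) * stats::pnorm(k)
    return(pmin(pmax(p, 0), 1))
  }
  # extreme correlation: exact-algorithm fallback, element by element
  corr <- matrix(c(1, rho, rho, 1), 2, 2)
  vapply(seq_len(n), function(i) {
    if (!is.finite(h[i]) && h[i] < 0) return(0)
    if (!is.finite(k[i]) && k[i] < 0) return(0)
    if (!is.finite(h[i]) && !is.finite(k[i])) return(1)
    if (!is.finite(h[i])) return(stats::pnorm(k[i]))
    if (!is.finite(k[i])) return(stats::pnorm(h[i]))
    as.numeric(mvtnorm::pmvnorm(lower = c(-Inf, -Inf), upper = c(h[i], k[i]),
                                corr = corr, algorithm = mvtnorm::Miwa(steps = 512)))
  }, numeric(1))
}

# Upper-orthant bivariate probability P(X >= h, Y >= k); vectorized.
pbvnorm_upper <- function(h, k, rho) pbvnorm(-h, -k, rho)

#' Multivariate normal rectangle probability
#'
#' Probability that a zero-mean multivariate normal vector with unit
#' variances and the given correlation matrix falls inside an axis-aligned
#' rectangle.  Dimension 2 uses a deterministic Gauss-Legendre scheme;
#' dimension 4 uses a quasi-Monte-Carlo integrator run under a fixed
#' internal seed so repeated evaluations are identical (a noiseless
#' objective for likelihood optimization).
#'
#' @param lower,upper Numeric bound vectors (\code{-Inf}/\code{Inf}
#'   allowed), \code{lower < upper} elementwise.
#' @param corr Correlation matrix (2x2 or 4x4), symmetric positive definite
#'   with unit diagonal.
#' @param accuracy Absolute error target (default \code{1e-6}).
#' @return The rectangle probability, with attribute \code{"error"} giving
#'   the integrator's estimated absolute error.
#' @examples
#' mvn_rectangle(rep(0, 4), rep(Inf, 4), diag(4))  # 1/16
#' @export
mvn_rectangle <- function(lower, upper, corr, accuracy = 1e-6) {
  d <- length(lower)
  if (!(d %in% c(2L, 4L))) stop("only dimensions 2 and 4 are supported")
  if (length(upper) != d) stop("lower and upper must have equal length")
  corr <- as.matrix(corr)
  if (!all(dim(corr) == d)) stop("corr must be ", d, "x", d)
  if (max(abs(corr - t(corr))) > 1e-10 || max(abs(diag(corr) - 1)) > 1e-10) {
    stop("corr must be symmetric with unit diagonal")
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) stop("corr must be positive definite")
  if (any(lower >= upper)) stop("lower must be strictly below upper elementwise")

  if (d == 2L) {
    rho <- corr[1, 2]
    p <- pbvnorm(upper[1], upper[2], rho) - pbvnorm(lower[1], upper[2], rho) -
      pbvnorm(upper[1], lower[2], rho) + pbvnorm(lower[1], lower[2], rho)
    p <- min(max(p, 0), 1)
    attr(p, "error") <- 1e-14
    return(p)
  }

  res <- with_fixed_seed(mvtnorm::pmvnorm(
    lower = lower, upper = upper, corr = corr,
    algorithm = mvtnorm::GenzBretz(abseps = accuracy / 2, maxpts = 100000L)
  ))
  err <- attr(res, "error")
  if (is.null(err) || err > accuracy) {
    res <- with_fixed_seed(mvtnorm::pmvnorm(
      lower = lower, upper = upper, corr = corr,
      algorithm = mvtnorm::GenzBretz(abseps = accuracy / 2, maxpts = 1000000L)
    ))
    err <- attr(res, "error")
  }
  p <- min(max(as.numeric(res), 0), 1)
  attr(p, "error") <- err
  p
}

#' Tetrachoric correlation by maximum likelihood
#'
#' Estimates the correlation of two latent standard-normal liabilities from
#' a 2x2 table of their dichotomized indicators, by maximizing the
#' multinomial likelihood whose cell probabilities are bivariate normal
#' rectangle probabilities.  Thresholds are estimated from the margins
#' (their joint MLE) unless supplied.
#'
#' @param table 2x2 matrix of nonnegative counts; rows index trait 1
#'   (absent, present), columns trait 2.
#' @param thresholds Optional length-2 vector of fixed liability cutoffs
#'   (trait 1, trait 2).  Default \code{NULL} estimates them from margins.
#' @return A list with \code{rho} (estimate), \code{se}, \code{thresholds},
#'   \code{loglik}, and \code{clamped} (TRUE if the estimate hit the
#'   boundary because an interior cell was empty).
#' @examples
#' tab <- matrix(c(40, 10, 10, 40), 2, 2)
#' tetrachoric_mle(tab)$rho
#' @export
tetrachoric_mle <- function(table, thresholds = NULL) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0)) {
    stop("table must be a 2x2 matrix of nonnegative counts")
  }
  n <- sum(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all margins of the 2x2 table must be positive")
  }
  free_tau <- is.null(thresholds)
  if (free_tau) {
    p1 <- (tab[2, 1] + tab[2, 2]) / n  # trait 1 present
    p2 <- (tab[1, 2] + tab[2, 2]) / n
    thresholds <- c(threshold_from_prevalence(p1), threshold_from_prevalence(p2))
  } else if (length(thresholds) != 2L || any(!is.finite(thresholds))) {
    stop("thresholds must be a finite length-2 vector")
  }

  cell_probs <- function(rho, tau) {
    p11 <- pbvnorm_upper(tau[1], tau[2], rho)        # both present
    p1p <- prevalence_from_threshold(tau[1])
    pp1 <- prevalence_from_threshold(tau[2])
    p10 <- p1p - p11
    p01 <- pp1 - p11
    p00 <- 1 - p1p - pp1 + p11
    matrix(c(p00, p10, p01, p11), 2, 2)
  }
  negll <- function(rho, tau = thresholds) {
    pr <- cell_probs(rho, tau)
    if (any(pr[tab > 0] <= 0)) return(1e10)
    -sum(tab[tab > 0] * log(pr[tab > 0]))
  }

  bound <- 1 - 1e-6
  clamped <- FALSE
  if (tab[1, 2] == 0 && tab[2, 1] == 0) {
    rho_hat <- bound; clamped <- TRUE
    warning("empty discordant cells: tetrachoric estimate clamped to ", bound)
  } else if (tab[1, 1] == 0 && tab[2, 2] == 0) {
    rho_hat <- -bound; clamped <- TRUE
    warning("empty concordant cells: tetrachoric estimate clamped to ", -bound)
  } else {
    opt <- stats::optimize(negll, interval = c(-bound, bound), tol = 1e-9)
    rho_hat <- opt$minimum
  }

  se <- NA_real_
  if (!clamped) {
    if (free_tau) {
      H <- numDeriv::hessian(function(par) negll(par[1], par[2:3]),
                             c(rho_hat, thresholds))
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V) && V[1, 1] > 0) se <- sqrt(V[1, 1])
    } else {
      h <- numDeriv::hessian(function(r) negll(r), rho_hat)
      if (is.finite(h) && h > 0) se <- sqrt(1 / as.numeric(h))
    }
  }
  list(rho = rho_hat, se = se, thresholds = thresholds,
       loglik = -negll(rho_hat), clamped = clamped)
}

# Probabilists' Gauss-Hermite rule: nodes/weights integrating exactly
# against the standard normal density (weights sum to 1).  Golub-Welsch.
gauss_hermite_normal <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 1))
  off <- sqrt(seq_len(n - 1))
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (e$vectors[1, ord])^2)
}
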