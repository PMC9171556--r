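# Binary bivariate ACE likelihood under the liability-threshold model.
# Pairs are aggregated into 16-cell contingency tables per (pair type,
# sex pair, birth-decade pair) stratum; each cell probability is a 4-D
# normal rectangle under the implied pair correlation with stratum-shifted
# thresholds.  Identification fixes the total liability variance of each
# trait to 1 (V_E diagonals derived).

#' Aggregate binary pair data into stratum cell counts
#'
#' Collapses a pair data frame with 0/1 traits into counts of the 16
#' response patterns per stratum, where a stratum is a combination of pair
#' type, both members' sexes, and both members' birth-year decade bins
#' (decade midpoints carry the birth-year threshold shift).
#'
#' @param pairs Pair data frame from \code{\link{simulate_kin_pairs}} with
#'   binary traits.
#' @param decade_width Width of the birth-year bins in years (default 10).
#' @param use_sex,use_birth_year Stratify by these covariates?  Collapsing
#'   a covariate out (FALSE) is exact when its threshold coefficient is
#'   fixed at zero and keeps the number of strata small.
#' @return A data frame with one row per (stratum, pattern) with positive
#'   count: \code{pair_type}, \code{sex1}, \code{sex2}, \code{byc1},
#'   \code{byc2} (bin midpoints), \code{y11}, \code{y12}, \code{y21},
#'   \code{y22}, \code{count}.
#' @export
aggregate_binary_pairs <- function(pairs, decade_width = 10,
                                   use_sex = TRUE, use_birth_year = TRUE) {
  vals <- unlist(pairs[, c("m1_trait1", "m1_trait2", "m2_trait1", "m2_trait2")])
  if (anyNA(vals)) {
    n0 <- nrow(pairs)
    pairs <- pairs[stats::complete.cases(
      pairs[, c("m1_trait1", "m1_trait2", "m2_trait1", "m2_trait2")]), ]
    warning("dropped ", n0 - nrow(pairs), " pairs with missing binary traits")
    vals <- unlist(pairs[, c("m1_trait1", "m1_trait2", "m2_trait1", "m2_trait2")])
  }
  if (!all(vals %in% c(0, 1))) stop("traits must be binary 0/1")
  bin <- function(by) floor(by / decade_width) * decade_width + decade_width / 2
  mid <- bin(mean(pairs$m1_by))
  key <- data.frame(
    pair_type = pairs$pair_type,
    sex1 = if (use_sex) pairs$m1_sex else 0L,
    sex2 = if (use_sex) pairs$m2_sex else 0L,
    byc1 = if (use_birth_year) bin(pairs$m1_by) else mid,
    byc2 = if (use_birth_year) bin(pairs$m2_by) else mid,
    y11 = pairs$m1_trait1, y12 = pairs$m1_trait2,
    y21 = pairs$m2_trait1, y22 = pairs$m2_trait2
  )
  agg <- stats::aggregate(list(count = rep(1L, nrow(key))), by = key, FUN = sum)
  agg[order(agg$pair_type, agg$sex1, agg$sex2, agg$byc1, agg$byc2,
            agg$y11, agg$y12, agg$y21, agg$y22), , drop = FALSE]
}

# 4x4 matrix of joint pattern probabilities for one stratum, by 2-D
# Gauss-Hermite integration over the shared liability factor s ~ N(0, R):
# conditional on s, the two members' liabilities are independent bivariate
# normals with covariance U = P - R.  Rows index member 1's pattern
# (1 = 00, 2 = 01, 3 = 10, 4 = 11), columns member 2's.  Returns NULL when
# the decomposition is invalid (R or U not PSD), so callers can penalize
# or fall back to direct rectangle integration.
cell_probs_quadrature <- function(R, U, a1, a2, gh) {
  eR <- eigen(R, symmetric = TRUE)
  if (min(eR$values) < -1e-9) return(NULL)
  if (U[1, 1] <= 1e-10 || U[2, 2] <= 1e-10) return(NULL)
  su <- sqrt(diag(U))
  rho_u <- U[1, 2] / prod(su)
  if (abs(rho_u) >= 1) return(NULL)
  Lr <- eR$vectors %*% (sqrt(pmax(eR$values, 0)) * t(eR$vectors))
  m <- length(gh$nodes)
  z <- cbind(rep(gh$nodes, each = m), rep(gh$nodes, times = m))
  w <- rep(gh$weights, each = m) * rep(gh$weights, times = m)
  s <- z %*% t(Lr)

  member_q <- function(a) {
    b1 <- (a[1] - s[, 1]) / su[1]
    b2 <- (a[2] - s[, 2]) / su[2]
    p11 <- pbvnorm(-b1, -b2, rho_u)          # both above threshold
    p1 <- stats::pnorm(b1, lower.tail = FALSE)
    p2 <- stats::pnorm(b2, lower.tail = FALSE)
    cbind(`00` = 1 - p1 - p2 + p11, `01` = p2 - p11,
          `10` = p1 - p11, `11` = p11)
  }
  Q1 <- member_q(a1)
  Q2 <- member_q(a2)
  crossprod(Q1 * w, Q2)   # 4x4: sum_s w(s) q1(pattern1|s) q2(pattern2|s)
}

# Same 4x4 pattern-probability matrix via direct 4-D rectangle integration
# (slow, used as fallback and as the in-package oracle path).
cell_probs_rectangles <- function(Sigma4, a1, a2, accuracy = 1e-6) {
  sd4 <- sqrt(diag(Sigma4))
  corr <- Sigma4 / tcrossprod(sd4)
  thr <- c(a1, a2) / sd4
  out <- matrix(NA_real_, 4, 4)
  # pattern order must match pattern_index(): (00, 01, 10, 11)
  pats <- expand.grid(y2 = 0:1, y1 = 0:1)[, c("y1", "y2")]
  for (i in 1:4) {
    for (j in 1:4) {
      yy <- c(pats$y1[i], pats$y2[i], pats$y1[j], pats$y2[j])
      lo <- ifelse(yy == 1, thr, -Inf)
      hi <- ifelse(yy == 1, Inf, thr)
      out[i, j] <- as.numeric(mvn_rectangle(lo, hi, corr, accuracy))
    }
  }
  out
}

# row index (1..4) of a member pattern in the 4x4 probability matrix
pattern_index <- function(t1, t2) 1L + 2L * t1 + t2

#' Binary-pair log-likelihood (liability-threshold model)
#'
#' Multinomial log-likelihood of aggregated 16-cell pattern counts:
#' \code{sum count * log P(pattern)}, with pattern probabilities given by
#' 4-dimensional normal rectangles under the pair type's implied liability
#' correlation and stratum-specific thresholds (intercept plus sex and
#' birth-decade shifts per trait).  Equals the per-pair product likelihood.
#'
#' @param components An \code{\link{ace_components}} object; the total
#'   \code{V_A + V_C + V_E} must have unit diagonal (liability scale).
#' @param threshold_coefs 2x3 matrix per trait: intercept, sex shift,
#'   birth-year shift per decade.
#' @param cells Aggregated counts from \code{\link{aggregate_binary_pairs}}.
#' @param ref_year Centering year for the birth-year term.
#' @param gh_points Number of Gauss-Hermite nodes per factor dimension.
#' @return Log-likelihood; impossible cells (probability 0 with positive
#'   count) or invalid covariance structure yield a large finite penalty
#'   with attribute \code{"penalized"}.
#' @export
binary_pair_loglik <- function(components, threshold_coefs, cells,
                               ref_year = 1985, gh_points = 24) {
  P <- total_covariance(components)
  if (max(abs(diag(P) - 1)) > 1e-6) {
    stop("binary liability model requires unit total variance per trait")
  }
  gh <- gauss_hermite_normal(gh_points)
  strat_key <- interaction(cells$pair_type, cells$sex1, cells$sex2,
                           cells$byc1, cells$byc2, drop = TRUE)
  ll <- 0
  penalized <- FALSE
  for (sk in levels(strat_key)) {
    rows <- which(strat_key == sk)
    r1 <- rows[1]
    rel <- pair_relatedness(cells$pair_type[r1])
    R <- rel$r_A * components$V_A + rel$r_C * components$V_C
    U <- P - R
    thr_member <- function(sex, byc) {
      threshold_coefs[, 1] + threshold_coefs[, 2] * sex +
        threshold_coefs[, 3] * (byc - ref_year) / 10
    }
    a1 <- thr_member(cells$sex1[r1], cells$byc1[r1])
    a2 <- thr_member(cells$sex2[r1], cells$byc2[r1])
    pm <- cell_probs_quadrature(R, U, a1, a2, gh)
    if (is.null(pm)) {
      Sigma4 <- rbind(cbind(P, R), cbind(R, P))
      ev <- eigen(Sigma4, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 1e-8) {
        ll <- ll - 1e8 * (1 + abs(min(ev)))
        penalized <- TRUE
        next
      }
      pm <- cell_probs_rectangles(Sigma4, a1, a2)
    }
    i1 <- pattern_index(cells$y11[rows], cells$y12[rows])
    i2 <- pattern_index(cells$y21[rows], cells$y22[rows])
    pr <- pm[cbind(i1, i2)]
    bad <- pr <= 0 & cells$count[rows] > 0
    if (any(bad)) {
      ll <- ll - 1e8
      penalized <- TRUE
      next
    }
    ok <- cells$count[rows] > 0
    ll <- ll + sum(cells$count[rows][ok] * log(pr[ok]))
  }
  if (penalized) attr(ll, "penalized") <- TRUE
  ll
}
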