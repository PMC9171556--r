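# Continuous bivariate ACE likelihood: full-information ML over pairs.
# Each pair contributes the log-density of its observed trait values under
# a 4-dimensional normal whose covariance is implied_pair_covariance() for
# its pair type and whose means come from the covariate regression.

log2pi <- log(2 * pi)

# Design matrix rows for one member: intercept, sex, (birth year - ref)/10.
member_design <- function(sex, by, ref_year) {
  cbind(1, sex, (by - ref_year) / 10)
}

#' Continuous-pair log-likelihood (FIML)
#'
#' Sum over pairs of the multivariate-normal log-density of the stacked
#' vector (member 1 trait 1, member 1 trait 2, member 2 trait 1, member 2
#' trait 2), marginalizing over any missing entries (full-information
#' maximum likelihood).  Means are linear in sex and birth year per trait;
#' the covariance is \code{\link{implied_pair_covariance}} for the pair's
#' type.
#'
#' @param components An \code{\link{ace_components}} object.
#' @param mean_coefs 2x3 matrix of mean coefficients per trait: intercept,
#'   sex, birth year (per decade).
#' @param pairs Pair data frame as produced by
#'   \code{\link{simulate_kin_pairs}}.
#' @param ref_year Centering year for the birth-year term.
#' @return The log-likelihood.  A non-positive-definite implied covariance
#'   yields a large finite penalty (attribute \code{"penalized"} set) rather
#'   than an error, so optimizers can recover.
#' @export
continuous_pair_loglik <- function(components, mean_coefs, pairs,
                                   ref_year = 1985) {
  y <- as.matrix(pairs[, c("m1_trait1", "m1_trait2", "m2_trait1", "m2_trait2")])
  X1 <- member_design(pairs$m1_sex, pairs$m1_by, ref_year)
  X2 <- member_design(pairs$m2_sex, pairs$m2_by, ref_year)
  mu <- cbind(X1 %*% mean_coefs[1, ], X1 %*% mean_coefs[2, ],
              X2 %*% mean_coefs[1, ], X2 %*% mean_coefs[2, ])
  r <- y - mu

  ll <- 0
  penalized <- FALSE
  for (type in unique(pairs$pair_type)) {
    idx <- which(pairs$pair_type == type)
    S <- implied_pair_covariance(components, type)
    obs <- !is.na(r[idx, , drop = FALSE])
    pat_key <- obs %*% c(1, 2, 4, 8)
    for (key in unique(pat_key)) {
      rows <- idx[pat_key == key]
      keep <- which(obs[match(rows[1], idx), ])
      if (length(keep) == 0L) next
      Ssub <- S[keep, keep, drop = FALSE]
      ev <- eigen(Ssub, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 1e-10) {
        # distance-scaled penalty keeps the surface finite and sloped
        ll <- ll - 1e8 * (1 + abs(min(ev)))
        penalized <- TRUE
        next
      }
      U <- chol(Ssub)
      z <- backsolve(U, t(r[rows, keep, drop = FALSE]), transpose = TRUE)
      quad <- colSums(z^2)
      logdet <- 2 * sum(log(diag(U)))
      ll <- ll - 0.5 * sum(length(keep) * log2pi + logdet + quad)
    }
  }
  if (penalized) attr(ll, "penalized") <- TRUE
  ll
}
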