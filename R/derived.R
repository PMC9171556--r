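# Derived quantities of a bivariate ACE solution: standardized variance
# shares, component correlations, covariance decomposition and the implied
# phenotypic correlation, with delta-method confidence intervals when a
# fitted parameter covariance is available.

derived_vector <- function(components) {
  P <- total_covariance(components)
  shares <- sapply(c("V_A", "V_C", "V_E"), function(nm) {
    diag(components[[nm]]) / diag(P)
  })  # 2 x 3
  comp_cor <- sapply(c("V_A", "V_C", "V_E"), function(nm) {
    V <- components[[nm]]
    d <- V[1, 1] * V[2, 2]
    if (d <= 0) NA_real_ else V[1, 2] / sqrt(d)
  })
  covs <- sapply(c("V_A", "V_C", "V_E"), function(nm) components[[nm]][1, 2])
  cov_share <- if (abs(sum(covs)) < 1e-300) rep(NA_real_, 3) else covs / sum(covs)
  r_phen <- P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  out <- c(shares[1, 1], shares[2, 1], shares[1, 2], shares[2, 2],
           shares[1, 3], shares[2, 3],
           comp_cor[[1]], comp_cor[[2]], comp_cor[[3]],
           cov_share[[1]], cov_share[[2]], cov_share[[3]], r_phen)
  names(out) <- c("a2_1", "a2_2", "c2_1", "c2_2", "e2_1", "e2_2",
                  "rg", "rc", "re",
                  "cov_share_A", "cov_share_C", "cov_share_E",
                  "r_phenotypic")
  out
}

#' Standardized shares, component correlations and covariance decomposition
#'
#' From a fitted ACE model (or raw component matrices) computes, per trait,
#' the standardized variance shares a2/c2/e2; the genetic, shared- and
#' nonshared-environment correlations \code{rg}, \code{rc}, \code{re}
#' (\code{V[1,2]/sqrt(V[1,1] V[2,2])} per component); the fraction of the
#' cross-trait covariance carried by each component; and the implied
#' phenotypic correlation (total cross-trait covariance over the product of
#' total SDs).  For an \code{\link{ace_fit}} with a valid parameter
#' covariance, 95\% confidence intervals are attached by the delta method.
#'
#' A component with a negative estimated variance (a direct-symmetric
#' artifact) has an undefined correlation; it is reported as \code{NA} with
#' a warning.
#'
#' @param fit An \code{\link{ace_fit}} or \code{\link{ace_components}}
#'   object.
#' @return A data frame with columns \code{quantity}, \code{estimate} and,
#'   when available, \code{se}, \code{lower}, \code{upper}.
#' @examples
#' cm <- components_from_shares(a2 = c(0.55, 0.57), e2 = c(0.45, 0.43),
#'                              rg = 0.28, re = 0.27)
#' derived_estimates(cm)
#' @export
derived_estimates <- function(fit) {
  if (inherits(fit, "ace_components")) {
    est <- derived_vector(fit)
    if (any(c(diag(fit$V_A), diag(fit$V_C), diag(fit$V_E)) < 0)) {
      warning("negative component variance: its correlation is undefined (NA)")
    }
    return(data.frame(quantity = names(est), estimate = unname(est),
                      stringsAsFactors = FALSE))
  }
  if (!inherits(fit, "ace_fit")) {
    stop("fit must be an ace_fit or ace_components object")
  }
  if (!fit$convergence$converged) {
    warning("derived estimates from a fit flagged as non-converged")
  }
  est <- derived_vector(fit$components)
  if (fit$negative_variance) {
    warning("negative component variance: its correlation is undefined (NA)")
  }
  out <- data.frame(quantity = names(est), estimate = unname(est),
                    se = NA_real_, lower = NA_real_, upper = NA_real_,
                    stringsAsFactors = FALSE)
  if (!anyNA(fit$vcov)) {
    fun <- function(par) {
      up <- unpack_par(par, fit$spec, fit$measurement)
      v <- derived_vector(up$components)
      v[!is.finite(v)] <- 0    # jacobian rows for undefined entries unused
      v
    }
    J <- tryCatch(numDeriv::jacobian(fun, unname(fit$par)),
                  error = function(e) NULL)
    if (!is.null(J)) {
      V <- J %*% fit$vcov %*% t(J)
      se <- sqrt(pmax(diag(V), 0))
      out$se <- se
      out$lower <- out$estimate - stats::qnorm(0.975) * se
      out$upper <- out$estimate + stats::qnorm(0.975) * se
      und <- !is.finite(est)
      out$se[und] <- out$lower[und] <- out$upper[und] <- NA_real_
    }
  }
  out
}
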