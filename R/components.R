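#' Construct bivariate ACE component matrices
#'
#' Bundles the three symmetric 2x2 matrices \code{V_A}, \code{V_C},
#' \code{V_E} that define a bivariate ACE variance decomposition.  For data
#' generation each matrix must be positive semidefinite and the total
#' \code{V_A + V_C + V_E} should have unit diagonal when the traits are
#' standardized; during direct-symmetric fitting individual diagonals may go
#' negative, but the total must remain positive definite.
#'
#' @param V_A,V_C,V_E Symmetric 2x2 matrices (scalars are recycled to
#'   \code{diag(x, 2)}; a length-3 vector \code{c(v11, v22, v12)} is also
#'   accepted).
#' @param traits Character vector of length 2 naming the traits.
#' @param check One of \code{"generation"} (each component PSD, unit total
#'   diagonal), \code{"fitting"} (total PD only) or \code{"none"}.
#' @return An object of class \code{"ace_components"}: a list with elements
#'   \code{V_A}, \code{V_C}, \code{V_E}, \code{traits}.
#' @examples
#' cm <- ace_components(V_A = c(0.55, 0.57, 0.157),
#'                      V_E = c(0.45, 0.43, 0.119))
#' total_covariance(cm)
#' @export
ace_components <- function(V_A = matrix(0, 2, 2), V_C = matrix(0, 2, 2),
                           V_E = diag(2), traits = c("trait1", "trait2"),
                           check = c("generation", "fitting", "none")) {
  check <- match.arg(check)
  V_A <- as_cov2(V_A, "V_A")
  V_C <- as_cov2(V_C, "V_C")
  V_E <- as_cov2(V_E, "V_E")
  obj <- structure(list(V_A = V_A, V_C = V_C, V_E = V_E,
                        traits = as.character(traits)),
                   class = "ace_components")
  if (check == "generation") {
    for (nm in c("V_A", "V_C", "V_E")) {
      if (min(eigen(obj[[nm]], symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
        stop(nm, " is not positive semidefinite (generation components must be)")
      }
    }
  } else if (check == "fitting") {
    tot <- total_covariance(obj)
    if (min(eigen(tot, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("total covariance V_A + V_C + V_E is not positive definite")
    }
  }
  obj
}

as_cov2 <- function(x, name) {
  if (length(x) == 1L) x <- diag(as.numeric(x), 2)
  if (is.numeric(x) && length(x) == 3L) {
    x <- matrix(c(x[1], x[3], x[3], x[2]), 2, 2)
  }
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L))) stop(name, " must be a 2x2 matrix")
  if (abs(x[1, 2] - x[2, 1]) > 1e-12) stop(name, " must be symmetric")
  x[2, 1] <- x[1, 2]
  storage.mode(x) <- "double"
  x
}

#' Total phenotypic covariance implied by ACE components
#'
#' @param components An \code{\link{ace_components}} object.
#' @return The 2x2 matrix \code{V_A + V_C + V_E}.
#' @export
total_covariance <- function(components) {
  components$V_A + components$V_C + components$V_E
}

#' Build ACE components from standardized shares and component correlations
#'
#' Reconstructs the raw component matrices from the quantities quantitative
#' genetic studies usually report: per-trait standardized variance shares
#' (\code{a2}, \code{c2}, \code{e2}, summing to 1 per trait) and the
#' component correlations \code{rg}, \code{rc}, \code{re}.  Off-diagonals
#' are \code{r * sqrt(share1 * share2)}.
#'
#' @param a2,c2,e2 Length-2 vectors of per-trait variance shares.
#' @param rg,rc,re Component correlations (A, C and E respectively).
#' @param traits Trait labels.
#' @return An \code{\link{ace_components}} object with unit total diagonal.
#' @examples
#' components_from_shares(a2 = c(0.55, 0.57), e2 = c(0.45, 0.43),
#'                        rg = 0.28, re = 0.27)
#' @export
components_from_shares <- function(a2, c2 = c(0, 0), e2, rg = 0, rc = 0, re = 0,
                                   traits = c("trait1", "trait2")) {
  stopifnot(length(a2) == 2L, length(c2) == 2L, length(e2) == 2L)
  tot <- a2 + c2 + e2
  if (any(abs(tot - 1) > 1e-8)) {
    stop("variance shares must sum to 1 per trait (got ",
         paste(signif(tot, 6), collapse = ", "), ")")
  }
  off <- function(sh, r) r * sqrt(sh[1] * sh[2])
  ace_components(
    V_A = c(a2, off(a2, rg)),
    V_C = c(c2, off(c2, rc)),
    V_E = c(e2, off(e2, re)),
    traits = traits
  )
}

#' Covariance of the stacked pair phenotype vector
#'
#' For a relative pair, the 4-vector (member 1 trait 1, member 1 trait 2,
#' member 2 trait 1, member 2 trait 2) has block covariance
#' \code{[[P, R], [R, P]]} with within-person block
#' \code{P = V_A + V_C + V_E} and cross-member block
#' \code{R = r_A * V_A + r_C * V_C}, where \code{r_A} is the pair type's
#' genetic relatedness and \code{r_C = 1}.
#'
#' @param components An \code{\link{ace_components}} object.
#' @param pair_type Pair type label (see \code{\link{kin_pair_types}}).
#' @return A symmetric 4x4 covariance matrix.
#' @examples
#' cm <- components_from_shares(a2 = c(0.55, 0.57), e2 = c(0.45, 0.43),
#'                              rg = 0.28, re = 0.27)
#' implied_pair_covariance(cm, "MHS")
#' @export
implied_pair_covariance <- function(components, pair_type) {
  rel <- pair_relatedness(pair_type)
  P <- total_covariance(components)
  R <- rel$r_A * components$V_A + rel$r_C * components$V_C
  rbind(cbind(P, R), cbind(R, P))
}

#' @export
print.ace_components <- function(x, ...) {
  cat("Bivariate ACE components (traits: ",
      paste(x$traits, collapse = ", "), ")\n", sep = "")
  for (nm in c("V_A", "V_C", "V_E")) {
    cat(nm, ":\n", sep = "")
    print(round(x[[nm]], 4))
  }
  invisible(x)
}
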