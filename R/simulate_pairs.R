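#' Default covariate model for pair simulation
#'
#' Covariates enter the liability/score mean: sex (coded 1 = female) adds
#' \code{sex_effect} per trait, birth year adds \code{birth_year_effect} per
#' decade relative to \code{ref_year}.  Twins share a birth year; sibling
#' pairs are first- and second-born with a gap of at most 5 years.
#'
#' @param sex_effect,birth_year_effect Length-2 numeric vectors (one entry
#'   per trait); birth-year effects are per decade.
#' @param p_female Probability that a member is female.
#' @param birth_window Integer range of birth years.
#' @param ref_year Centering year for the birth-year term.
#' @return A list suitable for the \code{covariate_effects} argument of
#'   \code{\link{simulate_kin_pairs}}.
#' @export
pair_covariate_model <- function(sex_effect = c(0, 0),
                                 birth_year_effect = c(0, 0),
                                 p_female = 0.5,
                                 birth_window = c(1970, 1997),
                                 ref_year = round(mean(birth_window))) {
  stopifnot(length(sex_effect) == 2L, length(birth_year_effect) == 2L,
            p_female >= 0, p_female <= 1, length(birth_window) == 2L,
            birth_window[1] <= birth_window[2])
  list(sex_effect = as.numeric(sex_effect),
       birth_year_effect = as.numeric(birth_year_effect),
       p_female = p_female,
       birth_window = as.integer(birth_window),
       ref_year = as.numeric(ref_year))
}

# Symmetric PSD square root (handles the rank-deficient MZ case where
# V_C = V_E = 0 makes the pair covariance singular).
psd_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1)) {
    stop("generation covariance is not positive semidefinite")
  }
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# Deterministic child seed for a named stream under a root seed.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) %% 65011 + 1) * 32503 + h * 271) %% 2147483629L
}

#' Simulate kinship pairs under a bivariate ACE structure
#'
#' For each pair the stacked 4-vector (member 1 trait 1, member 1 trait 2,
#' member 2 trait 1, member 2 trait 2) is drawn from a zero-mean
#' multivariate normal with covariance \code{\link{implied_pair_covariance}},
#' mean-shifted by the covariate model, and (for binary traits) dichotomized
#' as \code{value >= threshold}.
#'
#' @param components An \code{\link{ace_components}} object; every component
#'   must be positive semidefinite.
#' @param counts Named integer vector of pair counts, names among
#'   \code{MZ, DZ, FS, MHS}.
#' @param thresholds Optional length-2 vector of liability cutoffs; if
#'   given, both traits are returned as 0/1 indicators of
#'   \code{liability >= threshold}.
#' @param covariate_effects A \code{\link{pair_covariate_model}} list, or
#'   \code{NULL} for no covariate shifts (sexes Bernoulli(1/2), default
#'   birth window).
#' @param seed Integer root seed; per-pair-type child streams are derived
#'   deterministically from it.
#' @return A data frame with one row per pair: \code{pair_id},
#'   \code{pair_type}, \code{m1_trait1}, \code{m1_trait2}, \code{m2_trait1},
#'   \code{m2_trait2}, \code{m1_sex}, \code{m2_sex}, \code{m1_by},
#'   \code{m2_by}.
#' @examples
#' cm <- components_from_shares(a2 = c(0.36, 0.46), e2 = c(0.64, 0.54),
#'                              rg = 0.31, re = 0.10)
#' pairs <- simulate_kin_pairs(cm, counts = c(MZ = 100, DZ = 100), seed = 1)
#' @export
simulate_kin_pairs <- function(components, counts, thresholds = NULL,
                               covariate_effects = NULL, seed = 1L) {
  if (!inherits(components, "ace_components")) {
    stop("components must be an ace_components object")
  }
  for (nm in c("V_A", "V_C", "V_E")) {
    ev <- eigen(components[[nm]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("generation component ", nm, " is not positive semidefinite ",
           "(min eigenvalue ", signif(min(ev), 3), ")")
    }
  }
  if (is.null(names(counts)) || any(!names(counts) %in% kin_pair_types()$label)) {
    stop("counts must be named with pair types among ",
         paste(kin_pair_types()$label, collapse = ", "))
  }
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (!is.null(thresholds) && length(thresholds) != 2L) {
    stop("thresholds must be NULL or a length-2 vector")
  }
  cov_mod <- if (is.null(covariate_effects)) pair_covariate_model()
             else covariate_effects

  out <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    type <- names(counts)[i]
    n <- as.integer(counts[i])
    if (n == 0L) { out[[i]] <- NULL; next }
    set.seed(derive_seed(seed, paste0("pairs-", type)))
    rel <- pair_relatedness(type)
    LA <- psd_sqrt(components$V_A)
    LC <- psd_sqrt(components$V_C)
    LE <- psd_sqrt(components$V_E)
    draw2 <- function(L) matrix(stats::rnorm(n * 2L), n, 2L) %*% t(L)
    # shared vs member-unique component draws: cov(member1, member2) =
    # r_A V_A + r_C V_C, with MZ pairs identical by construction when
    # V_C = V_E = 0
    A_sh <- draw2(LA); A_u1 <- draw2(LA); A_u2 <- draw2(LA)
    C_sh <- draw2(LC)
    E_u1 <- draw2(LE); E_u2 <- draw2(LE)
    wa_sh <- sqrt(rel$r_A); wa_u <- sqrt(1 - rel$r_A)
    m1 <- wa_sh * A_sh + wa_u * A_u1 + C_sh + E_u1
    m2 <- wa_sh * A_sh + wa_u * A_u2 + C_sh + E_u2
    liab <- cbind(m1, m2)

    sex1 <- stats::rbinom(n, 1L, cov_mod$p_female)
    sex2 <- if (type == "MZ") sex1 else stats::rbinom(n, 1L, cov_mod$p_female)
    bw <- cov_mod$birth_window
    years <- seq(bw[1], bw[2])
    if (type %in% c("MZ", "DZ")) {
      by1 <- by2 <- years[sample.int(length(years), n, replace = TRUE)]
    } else {
      by1 <- years[sample.int(length(years), n, replace = TRUE)]
      gap <- sample(1:5, n, replace = TRUE)
      by2 <- pmin(by1 + gap, bw[2])
    }
    shift <- function(sex, by, trait) {
      cov_mod$sex_effect[trait] * sex +
        cov_mod$birth_year_effect[trait] * (by - cov_mod$ref_year) / 10
    }
    liab[, 1] <- liab[, 1] + shift(sex1, by1, 1)
    liab[, 2] <- liab[, 2] + shift(sex1, by1, 2)
    liab[, 3] <- liab[, 3] + shift(sex2, by2, 1)
    liab[, 4] <- liab[, 4] + shift(sex2, by2, 2)

    if (!is.null(thresholds)) {
      liab[, c(1, 3)] <- (liab[, c(1, 3)] >= thresholds[1]) + 0
      liab[, c(2, 4)] <- (liab[, c(2, 4)] >= thresholds[2]) + 0
    }
    out[[i]] <- data.frame(
      pair_id = paste0(type, "-", seq_len(n)),
      pair_type = type,
      m1_trait1 = liab[, 1], m1_trait2 = liab[, 2],
      m2_trait1 = liab[, 3], m2_trait2 = liab[, 4],
      m1_sex = sex1, m2_sex = sex2,
      m1_by = by1, m2_by = by2,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
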