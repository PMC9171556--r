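#' Specify a bivariate ACE model
#'
#' @param components Character vector of included variance components
#'   (subset of \code{c("A", "C", "E")}); \code{E} is always included.
#'   Both traits share the same component set (the model ladder ACE-ACE,
#'   AE-AE, CE-CE, E-E).
#' @param measurement \code{"auto"} (default), \code{"continuous"} or
#'   \code{"binary"}.
#' @param covariates Covariates in the mean/threshold model; any subset of
#'   \code{c("sex", "birth_year")}.
#' @return An object of class \code{"ace_model_spec"}.
#' @export
ace_model_spec <- function(components = c("A", "C", "E"),
                           measurement = c("auto", "continuous", "binary"),
                           covariates = c("sex", "birth_year")) {
  measurement <- match.arg(measurement)
  components <- unique(toupper(components))
  if (!all(components %in% c("A", "C", "E"))) {
    stop("components must be a subset of A, C, E")
  }
  if (!"E" %in% components) components <- c(components, "E")
  components <- intersect(c("A", "C", "E"), components)
  if (!all(covariates %in% c("sex", "birth_year"))) {
    stop("covariates must be among 'sex', 'birth_year'")
  }
  structure(list(components = components, measurement = measurement,
                 covariates = covariates),
            class = "ace_model_spec")
}

# Names of the free parameters for a resolved spec (measurement known).
par_names_for <- function(spec, measurement) {
  nm <- character(0)
  for (comp in intersect(c("A", "C"), spec$components)) {
    nm <- c(nm, paste0(comp, c("11", "22", "12")))
  }
  nm <- c(nm, if (measurement == "binary") "E12" else c("E11", "E22", "E12"))
  pre <- if (measurement == "binary") "tau" else "mu"
  nm <- c(nm, paste0(pre, 1:2))
  if ("sex" %in% spec$covariates) nm <- c(nm, paste0("sex", 1:2))
  if ("birth_year" %in% spec$covariates) nm <- c(nm, paste0("by", 1:2))
  nm
}

# Rebuild component matrices and coefficient matrix from a free-parameter
# vector.  For binary measurement the V_E diagonals are derived from the
# unit-total-liability-variance identification.
unpack_par <- function(par, spec, measurement) {
  names(par) <- par_names_for(spec, measurement)
  g <- function(nm) if (nm %in% names(par)) par[[nm]] else 0
  V_A <- matrix(c(g("A11"), g("A12"), g("A12"), g("A22")), 2, 2)
  V_C <- matrix(c(g("C11"), g("C12"), g("C12"), g("C22")), 2, 2)
  if (measurement == "binary") {
    e11 <- 1 - V_A[1, 1] - V_C[1, 1]
    e22 <- 1 - V_A[2, 2] - V_C[2, 2]
    V_E <- matrix(c(e11, g("E12"), g("E12"), e22), 2, 2)
  } else {
    V_E <- matrix(c(g("E11"), g("E12"), g("E12"), g("E22")), 2, 2)
  }
  comps <- structure(list(V_A = V_A, V_C = V_C, V_E = V_E,
                          traits = c("trait1", "trait2")),
                     class = "ace_components")
  pre <- if (measurement == "binary") "tau" else "mu"
  coefs <- rbind(
    c(g(paste0(pre, 1)), g("sex1"), g("by1")),
    c(g(paste0(pre, 2)), g("sex2"), g("by2"))
  )
  list(components = comps, coefs = coefs)
}

# Moment-based starting values: per-type cross-member correlations
# regressed on r_A (Falconer-style), tetrachoric for binary traits.
starting_values <- function(pairs, spec, measurement, ref_year) {
  types <- unique(pairs$pair_type)
  rA <- vapply(types, function(tp) pair_relatedness(tp)$r_A, numeric(1))
  nt <- vapply(types, function(tp) sum(pairs$pair_type == tp), numeric(1))

  corr_of <- function(x, y) {
    ok <- stats::complete.cases(x, y)
    if (measurement == "binary") {
      tab <- table(factor(x[ok], 0:1), factor(y[ok], 0:1))
      est <- tryCatch(suppressWarnings(tetrachoric_mle(tab)$rho),
                      error = function(e) 0)
      est
    } else {
      suppressWarnings(stats::cor(x[ok], y[ok]))
    }
  }
  r_cross1 <- vapply(types, function(tp) {
    d <- pairs[pairs$pair_type == tp, ]
    corr_of(d$m1_trait1, d$m2_trait1)
  }, numeric(1))
  r_cross2 <- vapply(types, function(tp) {
    d <- pairs[pairs$pair_type == tp, ]
    corr_of(d$m1_trait2, d$m2_trait2)
  }, numeric(1))
  r_cross12 <- vapply(types, function(tp) {
    d <- pairs[pairs$pair_type == tp, ]
    (corr_of(d$m1_trait1, d$m2_trait2) + corr_of(d$m1_trait2, d$m2_trait1)) / 2
  }, numeric(1))
  rp <- corr_of(c(pairs$m1_trait1, pairs$m2_trait1),
                c(pairs$m1_trait2, pairs$m2_trait2))

  has_A <- "A" %in% spec$components
  has_C <- "C" %in% spec$components
  moment_split <- function(rc) {
    # weighted fit of rc ~ c2 + rA * a2 across pair types
    w <- nt / sum(nt)
    if (has_A && has_C && length(types) >= 2) {
      fit <- stats::lm(rc ~ rA, weights = w)
      c(a = unname(stats::coef(fit)[2]), c = unname(stats::coef(fit)[1]))
    } else if (has_A) {
      c(a = sum(w * rA * rc) / sum(w * rA^2), c = 0)
    } else if (has_C) {
      c(a = 0, c = sum(w * rc) / sum(w))
    } else {
      c(a = 0, c = 0)
    }
  }
  m1 <- moment_split(r_cross1)
  m2 <- moment_split(r_cross2)
  m12 <- moment_split(r_cross12)
  clip <- function(x, lo = -0.3, hi = 0.9) pmin(pmax(x, lo), hi)
  a2 <- clip(c(m1["a"], m2["a"]), 0.05, 0.9) * has_A
  c2 <- clip(c(m1["c"], m2["c"]), 0.0, 0.6) * has_C
  a12 <- clip(m12["a"], -0.5, 0.5) * has_A
  c12 <- clip(m12["c"], -0.5, 0.5) * has_C
  e12 <- clip(rp - a12 - c12, -0.7, 0.7)

  par <- numeric(0)
  if (has_A) par <- c(par, a2[1], a2[2], a12)
  if (has_C) par <- c(par, c2[1], c2[2], c12)
  if (measurement == "binary") {
    par <- c(par, e12)
    p1 <- mean(c(pairs$m1_trait1, pairs$m2_trait1), na.rm = TRUE)
    p2 <- mean(c(pairs$m1_trait2, pairs$m2_trait2), na.rm = TRUE)
    par <- c(par, threshold_from_prevalence(min(max(p1, 1e-6), 1 - 1e-6)),
             threshold_from_prevalence(min(max(p2, 1e-6), 1 - 1e-6)))
  } else {
    v1 <- stats::var(c(pairs$m1_trait1, pairs$m2_trait1), na.rm = TRUE)
    v2 <- stats::var(c(pairs$m1_trait2, pairs$m2_trait2), na.rm = TRUE)
    par <- c(par, pmax(v1 * (1 - a2[1] - c2[1]), 0.05),
             pmax(v2 * (1 - a2[2] - c2[2]), 0.05), e12)
    par <- c(par, mean(c(pairs$m1_trait1, pairs$m2_trait1), na.rm = TRUE),
             mean(c(pairs$m1_trait2, pairs$m2_trait2), na.rm = TRUE))
  }
  if ("sex" %in% spec$covariates) par <- c(par, 0, 0)
  if ("birth_year" %in% spec$covariates) par <- c(par, 0, 0)
  unname(par)
}

#' Fit a bivariate ACE model by maximum likelihood
#'
#' Maximizes the continuous FIML or binary liability-threshold
#' log-likelihood over the free direct-symmetric parameters (component
#' matrix entries) plus mean or threshold coefficients.  Starting values
#' come from Falconer-style moment estimates (continuous) or tetrachoric
#' correlations (binary).  Identifiability requires at least two pair
#' types with distinct genetic relatedness.
#'
#' @param pairs Pair data frame (see \code{\link{simulate_kin_pairs}}).
#' @param spec An \code{\link{ace_model_spec}}.
#' @param ref_year Centering year for birth-year terms; defaults to the
#'   rounded mean birth year of the sample.
#' @param gh_points Gauss-Hermite nodes per dimension (binary model).
#' @param max_restarts Random restarts after a failed optimization.
#' @return An object of class \code{"ace_fit"}: components at the optimum,
#'   coefficient matrix, log-likelihood, AIC, free-parameter vector and
#'   covariance, convergence diagnostics and pair counts.
#' @export
fit_ace <- function(pairs, spec = ace_model_spec(), ref_year = NULL,
                    gh_points = 24, max_restarts = 5) {
  types <- unique(pairs$pair_type)
  rA <- vapply(types, function(tp) pair_relatedness(tp)$r_A, numeric(1))
  if (length(types) < 2L) {
    stop("need at least two pair types with distinct genetic relatedness ",
         "(got only: ", paste(types, collapse = ", "), ")")
  }
  if (all(c("A", "C") %in% spec$components) && length(unique(rA)) < 2L) {
    stop("need at least two pair types with distinct genetic relatedness ",
         "to separate A from C (got: ", paste(types, collapse = ", "), ")")
  }
  measurement <- spec$measurement
  if (measurement == "auto") {
    vals <- unlist(pairs[, c("m1_trait1", "m1_trait2", "m2_trait1", "m2_trait2")])
    measurement <- if (all(stats::na.omit(vals) %in% c(0, 1))) "binary"
                   else "continuous"
  }
  if (is.null(ref_year)) ref_year <- round(mean(c(pairs$m1_by, pairs$m2_by)))
  pnames <- par_names_for(spec, measurement)

  if (measurement == "binary") {
    cells <- aggregate_binary_pairs(
      pairs,
      use_sex = "sex" %in% spec$covariates,
      use_birth_year = "birth_year" %in% spec$covariates)
    objective <- function(par) {
      up <- unpack_par(par, spec, measurement)
      -as.numeric(binary_pair_loglik(up$components, up$coefs, cells,
                                     ref_year = ref_year,
                                     gh_points = gh_points))
    }
  } else {
    objective <- function(par) {
      up <- unpack_par(par, spec, measurement)
      -as.numeric(continuous_pair_loglik(up$components, up$coefs, pairs,
                                         ref_year = ref_year))
    }
  }

  start <- starting_values(pairs, spec, measurement, ref_year)
  best <- NULL
  set.seed(derive_seed(1L, "ace-fit-restarts"))
  for (attempt in 0:max_restarts) {
    st <- if (attempt == 0) start else start * stats::runif(length(start), 0.6, 1.4) +
      stats::rnorm(length(start), 0, 0.02)
    opt <- tryCatch(
      stats::nlminb(st, objective,
                    control = list(rel.tol = 1e-12, iter.max = 500,
                                   eval.max = 1000)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
    if (!is.null(best) && best$convergence == 0 && best$objective < 1e7) break
  }
  if (is.null(best)) stop("ACE optimization failed on all restarts")

  up <- unpack_par(best$par, spec, measurement)
  ll <- -best$objective
  k <- length(best$par)
  H <- tryCatch(numDeriv::hessian(objective, best$par), error = function(e) NULL)
  vcov <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(vcov)) vcov <- matrix(NA_real_, k, k)
  dimnames(vcov) <- list(pnames, pnames)
  grad <- tryCatch(numDeriv::grad(objective, best$par), error = function(e) rep(NA_real_, k))
  converged <- best$convergence == 0 && all(is.finite(grad)) &&
    max(abs(grad)) < 1e-3 * max(1, abs(ll))
  neg_var <- any(c(diag(up$components$V_A), diag(up$components$V_C),
                   diag(up$components$V_E)) < 0)

  structure(list(
    spec = spec, measurement = measurement,
    components = up$components, coefs = up$coefs, ref_year = ref_year,
    loglik = ll, npar = k, AIC = -2 * ll + 2 * k,
    par = stats::setNames(best$par, pnames), vcov = vcov,
    convergence = list(converged = converged, code = best$convergence,
                       grad_max = suppressWarnings(max(abs(grad))),
                       message = best$message),
    negative_variance = neg_var,
    n_pairs = table(pairs$pair_type)
  ), class = "ace_fit")
}

#' Likelihood-ratio and AIC comparison of nested ACE fits
#'
#' @param full,reduced Two \code{\link{ace_fit}} objects on the same data,
#'   the reduced model's components a strict subset of the full model's.
#' @return A list of class \code{"ace_model_comparison"}: \code{lrt},
#'   \code{df}, \code{p_value}, \code{delta_aic} (reduced minus full) and
#'   \code{preferred} (the reduced label when p >= 0.05).
#' @export
compare_models <- function(full, reduced) {
  if (!inherits(full, "ace_fit") || !inherits(reduced, "ace_fit")) {
    stop("both arguments must be ace_fit objects")
  }
  if (!all(reduced$spec$components %in% full$spec$components) ||
      length(reduced$spec$components) >= length(full$spec$components)) {
    stop("models are not strictly nested (reduced components must be a ",
         "proper subset of the full model's)")
  }
  if (full$measurement != reduced$measurement) {
    stop("models use different measurement types")
  }
  df <- full$npar - reduced$npar
  if (df < 1L) stop("nested comparison requires at least one dropped parameter")
  lrt <- 2 * (full$loglik - reduced$loglik)
  if (lrt < -1e-6 * max(1, abs(full$loglik))) {
    warning("reduced model fits better than full: LRT ", signif(lrt, 4),
            " truncated to 0 (likely non-convergence)")
  }
  lrt <- max(lrt, 0)
  p <- stats::pchisq(lrt, df = df, lower.tail = FALSE)
  lab <- function(f) paste(f$spec$components, collapse = "")
  structure(list(
    lrt = lrt, df = df, p_value = p,
    delta_aic = reduced$AIC - full$AIC,
    preferred = if (p >= 0.05) lab(reduced) else lab(full),
    full_label = lab(full), reduced_label = lab(reduced)
  ), class = "ace_model_comparison")
}

#' Fit the standard ACE model ladder
#'
#' Fits ACE-ACE, AE-AE, CE-CE and E-E to the same pair data and compares
#' each reduced model with the full ACE-ACE fit by likelihood-ratio test
#' and AIC.
#'
#' @inheritParams fit_ace
#' @param measurement Passed to \code{\link{ace_model_spec}}.
#' @param covariates Passed to \code{\link{ace_model_spec}}.
#' @return A list with \code{fits} (named list of \code{ace_fit}),
#'   \code{comparisons} (named list of comparisons against ACE) and
#'   \code{best} (label of the most parsimonious model not significantly
#'   worse than ACE-ACE, preferring smaller AIC among candidates).
#' @export
fit_ace_ladder <- function(pairs, measurement = "auto",
                           covariates = c("sex", "birth_year"),
                           ref_year = NULL, gh_points = 24) {
  ladder <- list(ACE = c("A", "C", "E"), AE = c("A", "E"),
                 CE = c("C", "E"), E = "E")
  fits <- lapply(ladder, function(cmp) {
    fit_ace(pairs, ace_model_spec(cmp, measurement, covariates),
            ref_year = ref_year, gh_points = gh_points)
  })
  comparisons <- lapply(fits[-1], function(f) compare_models(fits$ACE, f))
  ok <- vapply(comparisons, function(cm) cm$p_value >= 0.05, logical(1))
  if (any(ok)) {
    cand <- names(comparisons)[ok]
    aic <- vapply(fits[cand], function(f) f$AIC, numeric(1))
    best <- cand[which.min(aic)]
  } else {
    best <- "ACE"
  }
  list(fits = fits, comparisons = comparisons, best = best)
}

#' @export
print.ace_fit <- function(x, ...) {
  cat("Bivariate ACE fit (", x$measurement, "), components: ",
      paste(x$spec$components, collapse = ""), "\n", sep = "")
  cat("log-likelihood:", format(x$loglik, digits = 8),
      " AIC:", format(x$AIC, digits = 8),
      " converged:", x$convergence$converged, "\n")
  print(x$components)
  invisible(x)
}

#' @export
print.ace_model_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: LRT = %.3f (df = %d), p = %.4g, dAIC = %.2f -> %s\n",
              x$full_label, x$reduced_label, x$lrt, x$df, x$p_value,
              x$delta_aic, x$preferred))
  invisible(x)
}
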