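# Phenotypic-association stage: counting-process construction, Cox
# proportional hazards on the age timescale with delayed entry and a
# time-varying exposure, Kaplan-Meier cumulative incidence, and
# standardized linear regression with cluster-robust standard errors.

#' Build counting-process rows for one outcome category
#'
#' Converts registry persons into (start, stop] intervals with constant
#' exposure: a person diagnosed at age d inside their follow-up window
#' contributes an unexposed row (entry, d) and an exposed row (d, stop);
#' a diagnosis at or before entry yields a single exposed row.  Follow-up
#' for the outcome ends at the event or the censoring exit, whichever is
#' first; the event flag sits on the final row only.
#'
#' @param persons Registry data frame from \code{\link{simulate_registry}}.
#' @param outcome Outcome category name (there must be a column
#'   \code{event_age_<outcome>}).
#' @param ref_year Centering year for the birth-year covariate.
#' @return A data frame of rows \code{person_id}, \code{start_age},
#'   \code{stop_age}, \code{event}, \code{exposed}, \code{sex},
#'   \code{by_decade}.
#' @export
build_counting_process <- function(persons, outcome, ref_year = NULL) {
  col <- paste0("event_age_", outcome)
  if (!col %in% names(persons)) {
    stop("no column '", col, "' in persons; available outcomes: ",
         paste(sub("^event_age_", "", grep("^event_age_", names(persons),
                                           value = TRUE)), collapse = ", "))
  }
  if (is.null(ref_year)) ref_year <- round(mean(persons$birth_year))
  ev_age <- persons[[col]]
  bad <- !is.na(ev_age) & ev_age <= persons$entry_age
  if (any(bad)) {
    stop("event age at or before entry age for person(s): ",
         paste(utils::head(persons$person_id[bad], 5), collapse = ", "))
  }
  stop_age <- pmin(persons$exit_age, ifelse(is.na(ev_age), Inf, ev_age))
  event <- as.integer(!is.na(ev_age) & ev_age <= persons$exit_age)
  dx <- persons$ocd_dx_age
  by_dec <- (persons$birth_year - ref_year) / 10

  split_mask <- !is.na(dx) & dx > persons$entry_age & dx < stop_age
  pre <- data.frame(
    person_id = persons$person_id,
    start_age = persons$entry_age,
    stop_age = ifelse(split_mask, dx, stop_age),
    event = ifelse(split_mask, 0L, event),
    exposed = as.integer(!is.na(dx) & dx <= persons$entry_age),
    sex = persons$sex, by_decade = by_dec,
    stringsAsFactors = FALSE
  )
  post <- data.frame(
    person_id = persons$person_id[split_mask],
    start_age = dx[split_mask],
    stop_age = stop_age[split_mask],
    event = event[split_mask],
    exposed = 1L,
    sex = persons$sex[split_mask], by_decade = by_dec[split_mask],
    stringsAsFactors = FALSE
  )
  rows <- rbind(pre, post)
  rows <- rows[order(rows$person_id, rows$start_age), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Cox proportional hazards with delayed entry and time-varying exposure
#'
#' Fits a proportional-hazards model on the age timescale to
#' counting-process rows (Efron tie handling), with the time-varying
#' exposure indicator and any further covariates.
#'
#' @param rows Counting-process rows from
#'   \code{\link{build_counting_process}}.
#' @param covariates Character vector of additional covariate columns
#'   (default sex and the birth-year decade term).
#' @param ties Tie-handling method, \code{"efron"} (default) or
#'   \code{"breslow"}.
#' @return A list with \code{hr} (named hazard ratios), \code{ci}
#'   (2-column matrix of 95\% Wald limits), \code{coef}, \code{se},
#'   \code{loglik}, \code{n_events} and the underlying
#'   \code{survival::coxph} fit.
#' @export
cox_fit <- function(rows, covariates = c("sex", "by_decade"),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(rows$event) < 1) stop("no events in the counting-process data")
  vars <- c("exposed", covariates)
  for (v in vars) {
    if (length(unique(rows[[v]])) < 2L) {
      stop("covariate '", v, "' is constant across all rows")
    }
  }
  f <- stats::as.formula(paste(
    "survival::Surv(start_age, stop_age, event) ~",
    paste(vars, collapse = " + ")))
  fit <- survival::coxph(f, data = rows, ties = ties)
  if (any(!is.finite(stats::coef(fit))) ||
      any(!is.finite(sqrt(diag(stats::vcov(fit)))))) {
    warning("Cox fit did not converge cleanly (possible separation)")
  }
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  ci <- exp(cbind(lower = co - stats::qnorm(0.975) * se,
                  upper = co + stats::qnorm(0.975) * se))
  list(hr = exp(co), ci = ci, coef = co, se = se,
       loglik = fit$loglik[2], n_events = sum(rows$event), fit = fit)
}

#' Kaplan-Meier cumulative incidence with delayed entry
#'
#' Product-limit estimate of 1 minus survival per group, assuming no
#' competing risks, with pointwise 95\% confidence intervals from the
#' Greenwood variance on the log(-log) scale.
#'
#' @param rows Counting-process rows.
#' @param groups Vector of group labels, one per row (all rows of one
#'   person must share a label).
#' @param eval_ages Ages at which to evaluate the curves.
#' @return A data frame with \code{group}, \code{age},
#'   \code{cum_incidence}, \code{lower}, \code{upper}; evaluation ages
#'   before a group's first entry are NA (flagged undefined).
#' @export
km_cumulative_incidence <- function(rows, groups, eval_ages) {
  if (length(groups) != nrow(rows)) {
    stop("groups must have one label per counting-process row")
  }
  d <- cbind(rows, .grp = groups)
  out <- lapply(split(d, d$.grp), function(g) {
    fit <- survival::survfit(
      survival::Surv(start_age, stop_age, event) ~ 1,
      data = g, conf.type = "log-log")
    sm <- summary(fit, times = eval_ages, extend = TRUE)
    first_entry <- min(g$start_age)
    undef <- eval_ages < first_entry
    surv <- sm$surv[match(eval_ages, sm$time)]
    lo <- sm$lower[match(eval_ages, sm$time)]
    hi <- sm$upper[match(eval_ages, sm$time)]
    data.frame(group = g$.grp[1], age = eval_ages,
               cum_incidence = ifelse(undef, NA_real_, 1 - surv),
               lower = ifelse(undef, NA_real_, 1 - hi),
               upper = ifelse(undef, NA_real_, 1 - lo),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Standardized linear regression with cluster-robust standard errors
#'
#' Z-scores the outcome and the first predictor on the analysis sample,
#' fits ordinary least squares, and computes cluster-sandwich standard
#' errors with the small-sample factor
#' \code{G/(G-1) * (N-1)/(N-k)} (G clusters, N observations, k
#' coefficients).
#'
#' @param outcome Numeric outcome vector.
#' @param exposure Numeric exposure vector (standardized with the outcome).
#' @param covariates Optional data frame or matrix of further covariates
#'   (entered unstandardized).
#' @param cluster Cluster identifiers (e.g. pair ids).
#' @return A list with \code{beta} (standardized exposure coefficient),
#'   \code{se}, \code{ci}, \code{coef} (all coefficients), \code{robust_se}
#'   and \code{n}, \code{n_clusters}.
#' @export
ols_cluster_robust <- function(outcome, exposure, covariates = NULL, cluster) {
  ok <- stats::complete.cases(outcome, exposure, cluster)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  y <- scale(outcome[ok])[, 1]
  x <- scale(exposure[ok])[, 1]
  cl <- cluster[ok]
  G <- length(unique(cl))
  if (G < 2L) stop("need at least 2 clusters")
  X <- cbind(`(Intercept)` = 1, exposure = x)
  if (!is.null(covariates)) {
    Z <- as.matrix(as.data.frame(covariates)[ok, , drop = FALSE])
    X <- cbind(X, Z)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("predictor matrix is rank deficient")
  n <- nrow(X); k <- ncol(X)
  beta_hat <- qr.coef(qrX, y)
  e <- y - X %*% beta_hat
  bread <- chol2inv(qr.R(qrX))
  scores <- rowsum(X * as.numeric(e), group = cl)
  meat <- crossprod(scores)
  adj <- G / (G - 1) * (n - 1) / (n - k)
  V <- adj * bread %*% meat %*% bread
  se <- sqrt(diag(V))
  names(se) <- colnames(X)
  list(beta = unname(beta_hat["exposure"]), se = unname(se["exposure"]),
       ci = unname(beta_hat["exposure"] +
                     c(-1, 1) * stats::qnorm(0.975) * se["exposure"]),
       coef = beta_hat, robust_se = se, n = n, n_clusters = G)
}
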