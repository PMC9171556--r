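#' Shipped generator presets
#'
#' Four configurations calibrated to published Swedish register and
#' twin-cohort estimates of the co-occurrence of obsessive-compulsive
#' phenotypes and substance misuse:
#' \describe{
#'   \item{\code{catss-twin}}{MZ/DZ twin pairs with two continuous
#'     standardized symptom scores (obsessive-compulsive and alcohol
#'     dependence symptoms) under a bivariate AE structure.}
#'   \item{\code{population-liability}}{full-sibling and maternal
#'     half-sibling pairs with two binary lifetime diagnoses (OCD, any
#'     substance misuse) generated by thresholding bivariate-AE liabilities
#'     at prevalence-calibrated cutoffs.}
#'   \item{\code{population-registry}}{a registry cohort with a
#'     time-varying OCD diagnosis exposure and substance-misuse outcome
#'     categories under proportional hazards on the age timescale.}
#'   \item{\code{catss-bocs}}{a 12-item binary symptom checklist whose
#'     equal item loadings are calibrated to internal consistency
#'     (Cronbach's alpha) 0.76.}
#' }
#'
#' @param name Preset name.
#' @return A validated configuration list of class \code{"kinace_preset"}.
#'   Pair presets carry \code{components} (an
#'   \code{\link{ace_components}}), \code{counts}, \code{covariates} and,
#'   for binary traits, prevalence-calibrated \code{thresholds}; the
#'   registry preset carries the \code{\link{simulate_registry}} config;
#'   the item preset carries the \code{\link{simulate_items}} panel.
#' @examples
#' pr <- load_preset("catss-twin")
#' pr$components
#' @export
load_preset <- function(name) {
  available <- c("population-registry", "population-liability",
                 "catss-twin", "catss-bocs")
  if (!is.character(name) || length(name) != 1L || !(name %in% available)) {
    stop("unknown preset '", name, "'; available presets: ",
         paste(available, collapse = ", "))
  }
  path <- system.file("presets", paste0(name, ".yaml"), package = "kinace")
  if (path == "") stop("preset file for '", name, "' not found")
  raw <- yaml::read_yaml(path)
  out <- c(list(name = name), raw)
  class(out) <- "kinace_preset"

  if (raw$kind %in% c("pairs_continuous", "pairs_binary")) {
    sh <- raw$shares
    out$components <- components_from_shares(
      a2 = as.numeric(sh$a2), c2 = as.numeric(sh$c2 %||% c(0, 0)),
      e2 = as.numeric(sh$e2),
      rg = sh$rg %||% 0, rc = sh$rc %||% 0, re = sh$re %||% 0,
      traits = as.character(raw$traits)
    )
    cv <- raw$covariates
    out$covariates <- pair_covariate_model(
      sex_effect = as.numeric(cv$sex_effect),
      birth_year_effect = as.numeric(cv$birth_year_effect),
      p_female = cv$p_female,
      birth_window = as.numeric(cv$birth_window),
      ref_year = cv$ref_year
    )
    out$counts <- unlist(raw$counts)
    if (raw$kind == "pairs_binary") {
      out$thresholds <- vapply(seq_len(2L), function(tr) {
        calibrate_threshold(raw$prevalences[[tr]], out$covariates, tr)
      }, numeric(1))
    }
  } else if (raw$kind == "registry") {
    out$config <- raw$config
    out$config$birth_window <- as.numeric(raw$config$birth_window)
  } else if (raw$kind == "item_panel") {
    out$panel <- raw$panel
  } else {
    stop("preset '", name, "' has unknown kind '", raw$kind, "'")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate a liability threshold to a marginal prevalence
#'
#' With covariate effects shifting the liability mean, the cutoff giving a
#' target marginal prevalence is the root of
#' \code{E[pnorm(tau - shift, lower.tail = FALSE)] = p}, with the
#' expectation over the preset's sex and birth-year distributions.
#'
#' @param p Target marginal prevalence.
#' @param covariates A \code{\link{pair_covariate_model}} list.
#' @param trait Trait index (1 or 2).
#' @return The calibrated cutoff.
#' @export
calibrate_threshold <- function(p, covariates, trait) {
  if (p <= 0 || p >= 1) stop("prevalence must lie in (0, 1)")
  years <- seq(covariates$birth_window[1], covariates$birth_window[2])
  shifts <- outer(
    c(0, 1) * covariates$sex_effect[trait],
    covariates$birth_year_effect[trait] * (years - covariates$ref_year) / 10,
    "+"
  )
  wts <- outer(c(1 - covariates$p_female, covariates$p_female),
               rep(1 / length(years), length(years)))
  f <- function(tau) {
    sum(wts * stats::pnorm(tau - shifts, lower.tail = FALSE)) - p
  }
  stats::uniroot(f, interval = c(-10, 10), tol = 1e-10)$root
}

#' @export
print.kinace_preset <- function(x, ...) {
  cat("kinace preset '", x$name, "' (", x$kind, ")\n", sep = "")
  if (!is.null(x$components)) print(x$components)
  if (!is.null(x$counts)) {
    cat("pair counts:", paste(names(x$counts), x$counts, sep = "=",
                              collapse = ", "), "\n")
  }
  if (!is.null(x$thresholds)) {
    cat("thresholds:", paste(signif(x$thresholds, 4), collapse = ", "), "\n")
  }
  invisible(x)
}
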