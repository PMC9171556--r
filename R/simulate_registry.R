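#' Simulate a registry cohort with time-varying diagnosis exposure
#'
#' Emulates national-register follow-up on the age timescale: persons are
#' followed from the study start (or their 15th birthday, whichever is
#' later) until death, emigration or administrative censoring.  A subset
#' acquires a diagnosis at a lognormally distributed age; from that age
#' onward each outcome category's piecewise-constant baseline hazard is
#' multiplied by \code{exp(loghr_exposure)}.  Sex and birth year act
#' proportionally on every hazard.
#'
#' @param n Number of persons.
#' @param config List with elements:
#'   \describe{
#'     \item{birth_window}{integer range of birth years;}
#'     \item{p_female}{probability of being female (sex = 1);}
#'     \item{study_start, study_end}{calendar years delimiting follow-up
#'       (default 1997 and 2014, i.e. through the end of 2013);}
#'     \item{exposure}{list \code{p_lifetime}, \code{meanlog}, \code{sdlog},
#'       \code{min_age} for the diagnosis process;}
#'     \item{outcomes}{named list; each element has \code{breaks} (age band
#'       cutpoints starting at 15), \code{rates} (per-year baseline hazard
#'       per band), \code{loghr_exposure}, \code{loghr_female},
#'       \code{loghr_by_decade};}
#'     \item{censoring}{list \code{rate} (death/emigration hazard per year)
#'       and \code{p_death} (share of such exits labelled death);}
#'     \item{ref_year}{centering year for the birth-year term.}
#'   }
#' @param seed Integer root seed.
#' @return A data frame with one row per person: \code{person_id},
#'   \code{sex}, \code{birth_year}, \code{entry_age}, \code{exit_age}
#'   (censoring age), \code{ocd_dx_age} (NA if never diagnosed during
#'   follow-up), one \code{event_age_<category>} column per outcome (NA if
#'   none before \code{exit_age}) and \code{exit_reason} (\code{event} if
#'   any outcome precedes the censoring age, else \code{death},
#'   \code{emigration} or \code{admin_censor}).
#' @export
simulate_registry <- function(n, config, seed = 1L) {
  n <- as.integer(n)
  stopifnot(n > 0)
  cfg <- config
  if (is.null(cfg$study_start)) cfg$study_start <- 1997
  if (is.null(cfg$study_end)) cfg$study_end <- 2014
  if (is.null(cfg$ref_year)) cfg$ref_year <- round(mean(cfg$birth_window))
  exp_cfg <- cfg$exposure
  if (exp_cfg$p_lifetime <= 0 || exp_cfg$p_lifetime >= 1) {
    stop("exposure p_lifetime must lie in (0, 1)")
  }
  for (oc in names(cfg$outcomes)) {
    if (any(cfg$outcomes[[oc]]$rates < 0)) {
      stop("negative baseline hazard in outcome '", oc, "'")
    }
  }
  if (cfg$censoring$rate < 0) stop("negative censoring hazard")

  set.seed(derive_seed(seed, "registry-persons"))
  sex <- stats::rbinom(n, 1L, cfg$p_female)
  years <- seq(cfg$birth_window[1], cfg$birth_window[2])
  by <- years[sample.int(length(years), n, replace = TRUE)]
  # mid-year births: age attained at calendar time t is t - by - 0.5
  entry <- pmax(15, cfg$study_start - by - 0.5)
  admin <- cfg$study_end - by - 0.5
  keep_ok <- admin > entry
  if (!all(keep_ok)) stop("birth window produces persons with no follow-up")

  # death/emigration censoring
  cens_t <- entry + stats::rexp(n, rate = max(cfg$censoring$rate, 1e-300))
  if (cfg$censoring$rate == 0) cens_t <- rep(Inf, n)
  exit_age <- pmin(admin, cens_t)
  cens_reason <- ifelse(cens_t < admin,
                        ifelse(stats::runif(n) < cfg$censoring$p_death,
                               "death", "emigration"),
                        "admin_censor")

  # diagnosis ages (lifetime liability; observed when before exit)
  set.seed(derive_seed(seed, "registry-dx"))
  destined <- stats::rbinom(n, 1L, exp_cfg$p_lifetime) == 1L
  dx_raw <- rep(Inf, n)
  nd <- sum(destined)
  if (nd > 0) {
    dx_raw[destined] <- pmax(exp_cfg$min_age,
                             stats::rlnorm(nd, exp_cfg$meanlog, exp_cfg$sdlog))
  }
  ocd_dx_age <- ifelse(destined & dx_raw <= exit_age, dx_raw, NA_real_)

  out <- data.frame(person_id = paste0("P", seq_len(n)), sex = sex,
                    birth_year = by, entry_age = entry, exit_age = exit_age,
                    ocd_dx_age = ocd_dx_age, stringsAsFactors = FALSE)

  byterm <- (by - cfg$ref_year) / 10
  first_event <- rep(Inf, n)
  for (oc in names(cfg$outcomes)) {
    o <- cfg$outcomes[[oc]]
    set.seed(derive_seed(seed, paste0("registry-", oc)))
    mult0 <- exp(o$loghr_female * sex + o$loghr_by_decade * byterm)
    t_switch <- pmin(pmax(dx_raw, entry), exit_age)   # exposure onset clamped
    # unexposed phase [entry, t_switch)
    e1 <- stats::rexp(n)
    ev <- sample_piecewise_events(entry, t_switch, mult0, o$breaks, o$rates, e1)
    # exposed phase [t_switch, exit)
    e2 <- stats::rexp(n)
    mult1 <- mult0 * exp(o$loghr_exposure)
    ev2 <- sample_piecewise_events(t_switch, exit_age, mult1, o$breaks, o$rates, e2)
    ev[is.na(ev)] <- ev2[is.na(ev)]
    # events only count before the censoring exit and after age 15
    ev[!is.na(ev) & (ev > exit_age | ev < 15)] <- NA
    out[[paste0("event_age_", oc)]] <- ev
    first_event <- pmin(first_event, ifelse(is.na(ev), Inf, ev))
  }
  out$exit_reason <- ifelse(first_event <= exit_age, "event", cens_reason)
  out
}

# Inverse-transform sampling of one event time per person under a
# piecewise-constant baseline hazard times a per-person multiplier, on
# the window [start, stop).  `e` is the person's unit-exponential draw.
# Returns NA where the cumulative hazard over the window is below e.
sample_piecewise_events <- function(start, stop, mult, breaks, rates, e) {
  n <- length(start)
  K <- length(rates)
  if (length(breaks) != K + 1L) stop("breaks must have length(rates) + 1")
  event <- rep(NA_real_, n)
  remaining <- e
  for (k in seq_len(K)) {
    lo <- pmax(start, breaks[k])
    hi <- pmin(stop, breaks[k + 1L])
    dur <- pmax(0, hi - lo)
    h <- rates[k] * mult * dur
    hit <- is.na(event) & h > 0 & remaining <= h
    event[hit] <- lo[hit] + remaining[hit] / (rates[k] * mult[hit])
    remaining <- ifelse(is.na(event), remaining - h, remaining)
  }
  # hazard beyond the last break: treated as zero (no events)
  event
}
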