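#' Simulate binary item responses from latent trait scores
#'
#' Each item is an independent probit response: item j of person i is 1
#' when \code{loading[j] * latent[i] + noise >= threshold[j]}, with
#' standard-normal noise.  This emulates self-report symptom checklists
#' where each endorsed item is coded 1 and never-endorsed 0.
#'
#' @param latent Numeric vector of latent trait scores, one per person.
#' @param panel List describing the item panel: \code{n_items},
#'   \code{loadings} (scalar or per-item), \code{item_thresholds} (scalar or
#'   per-item).
#' @param seed Integer seed.
#' @return A list of class \code{"item_panel"}: \code{n_items},
#'   \code{loadings}, \code{item_thresholds}, \code{responses}
#'   (persons x items 0/1 matrix) and \code{sum_score}.
#' @examples
#' panel <- list(n_items = 12, loadings = 0.6, item_thresholds = 0.5)
#' ip <- simulate_items(rnorm(500), panel, seed = 1)
#' cronbach_alpha(ip$responses)
#' @export
simulate_items <- function(latent, panel, seed = 1L) {
  k <- as.integer(panel$n_items)
  if (k < 1L) stop("n_items must be at least 1")
  load <- rep_len(as.numeric(panel$loadings), k)
  thr <- rep_len(as.numeric(panel$item_thresholds), k)
  if (length(panel$loadings) > 1L && length(panel$loadings) != k) {
    stop("loadings length must be 1 or n_items")
  }
  if (length(panel$item_thresholds) > 1L && length(panel$item_thresholds) != k) {
    stop("item_thresholds length must be 1 or n_items")
  }
  if (any(!is.finite(load))) stop("loadings must be finite")
  n <- length(latent)
  set.seed(derive_seed(seed, "items"))
  noise <- matrix(stats::rnorm(n * k), n, k)
  x <- outer(latent, load) + noise
  resp <- (x >= matrix(thr, n, k, byrow = TRUE)) + 0L
  structure(list(n_items = k, loadings = load, item_thresholds = thr,
                 responses = resp, sum_score = rowSums(resp)),
            class = "item_panel")
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' \code{(k/(k-1)) * (1 - sum of item variances / variance of the sum
#' score)}.
#'
#' @param responses Persons x items numeric matrix without missing values
#'   (at least 2 persons and 2 items).
#' @return The alpha coefficient (dimensionless).
#' @examples
#' m <- matrix(rbinom(200, 1, 0.5), 100, 2)
#' cronbach_alpha(cbind(m, m))  # parallel duplicates push alpha up
#' @export
cronbach_alpha <- function(responses) {
  m <- as.matrix(responses)
  if (ncol(m) < 2L || nrow(m) < 2L) {
    stop("need at least 2 items and 2 persons")
  }
  if (anyNA(m)) stop("responses must not contain missing values")
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) stop("the sum score has zero variance")
  k <- ncol(m)
  (k / (k - 1)) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}
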