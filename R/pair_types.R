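#' Kinship pair types and their genetic/environmental sharing
#'
#' The four supported relative-pair designs and the coefficients that scale
#' the additive-genetic (A) and shared-environment (C) covariance between
#' pair members: monozygotic twins (\code{MZ}, genetically identical),
#' dizygotic twins (\code{DZ}, sharing on average half of their segregating
#' genes), full siblings (\code{FS}, likewise one half) and maternal
#' half-siblings (\code{MHS}, one quarter).  All pair types are assumed to
#' share their common environment fully (\code{r_C = 1}).
#'
#' @return A data frame with columns \code{label}, \code{r_A}, \code{r_C},
#'   one row per pair type.
#' @examples
#' kin_pair_types()
#' @export
kin_pair_types <- function() {
  data.frame(
    label = c("MZ", "DZ", "FS", "MHS"),
    r_A   = c(1.0, 0.5, 0.5, 0.25),
    r_C   = c(1.0, 1.0, 1.0, 1.0),
    stringsAsFactors = FALSE
  )
}

#' Genetic relatedness coefficient for a pair type
#'
#' @param label Pair type label, one of \code{"MZ"}, \code{"DZ"},
#'   \code{"FS"}, \code{"MHS"}.
#' @return A list with elements \code{r_A} and \code{r_C}.
#' @export
pair_relatedness <- function(label) {
  tab <- kin_pair_types()
  i <- match(label, tab$label)
  if (any(is.na(i))) {
    stop("unknown pair type(s): ", paste(unique(label[is.na(i)]), collapse = ", "),
         "; expected one of ", paste(tab$label, collapse = ", "))
  }
  list(r_A = tab$r_A[i], r_C = tab$r_C[i])
}
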