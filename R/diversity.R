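#' Shannon entropy of an NRAD
#'
#' \eqn{H = -\sum_{r=1}^{R} a_r \log a_r} in nats (natural logarithm), of the
#' mean abundance vector. For NRADs normalized to a common MaxRank R the
#' richness is fixed at R, so entropy differences between samples reflect
#' evenness of the abundance structure, not richness.
#'
#' @param x an `"nrad"` object or a numeric probability vector.
#' @return entropy in nats, in `[0, log R]`.
#' @export
shannon_entropy <- function(x) {
  a <- if (is_nrad(x)) x$abundances else x
  stopifnot(is.numeric(a), all(a >= 0))
  a <- a[a > 0]
  -sum(a * log(a))
}

#' Shannon evenness of an NRAD
#'
#' \eqn{J = H / \log R}, in `[0, 1]`. Since all NRADs of a set share richness
#' R, evenness is a rescaled entropy; it is 1 for the uniform distribution
#' and tends to 0 as the distribution approaches a point mass. Evenness also
#' varies only weakly with the choice of R (approximately
#' \eqn{H_R/\log R \approx c} per sample when R changes by up to an order of
#' magnitude), which makes it the natural scale-free diversity measure for
#' NRADs.
#'
#' @param x an `"nrad"` object.
#' @return evenness in `[0, 1]`.
#' @export
evenness <- function(x) {
  stopifnot(is_nrad(x))
  if (x$R < 2L) stop("evenness requires R >= 2", call. = FALSE)
  shannon_entropy(x) / log(x$R)
}

#' Entropy and evenness table for a set of NRADs
#'
#' @param nrads list of `"nrad"` objects.
#' @return data.frame with columns `label`, `R`, `H` (nats), `J`.
#' @export
entropy_table <- function(nrads) {
  stopifnot(all(vapply(nrads, is_nrad, logical(1))))
  data.frame(
    label = vapply(nrads, function(x) x$label, character(1)),
    R = vapply(nrads, function(x) x$R, integer(1)),
    H = vapply(nrads, shannon_entropy, numeric(1)),
    J = vapply(nrads, evenness, numeric(1)),
    row.names = NULL
  )
}
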