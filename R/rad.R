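#' Build a rank abundance distribution (RAD) from raw abundances
#'
#' A RAD is the vector of per-species abundances of one sample, sorted in
#' descending order and stripped of zeros. Species identities are discarded:
#' only the abundance structure is retained, so RADs from taxonomically
#' unrelated communities remain comparable.
#'
#' Abundances must be non-negative integer counts (read counts, individuals).
#' Tables of relative abundances are rejected rather than rescaled, because
#' MaxRank normalization draws individual organisms from a finite pool; see
#' [maxrank_normalize()].
#'
#' @param abundances numeric vector of non-negative integer counts, one entry
#'   per species/OTU/variant. Zeros mean "species absent from this sample"
#'   and are dropped.
#' @param label sample identifier.
#' @return An object of class `"rad"`: a list with elements
#'   \describe{
#'     \item{counts}{integer vector, strictly positive, non-increasing}
#'     \item{richness}{number of ranks \eqn{R_s} (length of `counts`)}
#'     \item{n_individuals}{total count \eqn{N_s}}
#'     \item{label}{sample identifier}
#'   }
#' @examples
#' r <- rad(c(1, 3, 0, 2), label = "toy")
#' r$counts        # 3 2 1
#' r$richness      # 3
#' relative_abundances(r)
#' @seealso [maxrank_normalize()], [relative_abundances()]
#' @export
rad <- function(abundances, label = "sample") {
  if (length(abundances) == 0L) {
    stop("empty community: no abundances supplied", call. = FALSE)
  }
  if (!is.numeric(abundances)) {
    stop("abundances must be numeric counts", call. = FALSE)
  }
  if (anyNA(abundances)) {
    stop("abundances contain NA", call. = FALSE)
  }
  if (any(abundances < 0)) {
    stop("abundances must be non-negative counts", call. = FALSE)
  }
  if (any(abundances != round(abundances))) {
    stop(paste0(
      "abundances must be integer counts; MaxRank normalization draws ",
      "individuals from a finite pool. If your table holds relative ",
      "abundances, rescale it to counts before building RADs."
    ), call. = FALSE)
  }
  counts <- as.integer(round(abundances))
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) {
    stop("empty community: all abundances are zero", call. = FALSE)
  }
  counts <- sort(counts, decreasing = TRUE)
  structure(
    list(
      counts = counts,
      richness = length(counts),
      n_individuals = sum(as.numeric(counts)),
      label = as.character(label)[1L]
    ),
    class = "rad"
  )
}

#' @export
print.rad <- function(x, ...) {
  cat(sprintf(
    "RAD '%s': richness %d, %s individuals\n",
    x$label, x$richness, format(x$n_individuals, big.mark = ",")
  ))
  head_n <- min(6L, x$richness)
  cat("  head counts:", paste(x$counts[seq_len(head_n)], collapse = " "),
      if (x$richness > head_n) "..." else "", "\n")
  invisible(x)
}

is_rad <- function(x) inherits(x, "rad")

#' Relative abundances of a RAD
#'
#' Divides the sorted counts by the sample total \eqn{N_s}, giving a
#' probability vector over ranks (non-increasing, summing to 1).
#'
#' @param x a [rad()] object.
#' @return numeric vector of length `x$richness` summing to 1.
#' @export
relative_abundances <- function(x) {
  stopifnot(is_rad(x))
  x$counts / x$n_individuals
}
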