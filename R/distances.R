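#' Manhattan distance between two NRADs
#'
#' The distance \eqn{d_R(a_i, a_j) = \sum_{r=1}^{R} |a_{ir} - a_{jr}|}
#' between two NRADs of the same MaxRank R. The Manhattan distance weighs the
#' few large differences in the NRAD heads and the many small differences in
#' the long tails approximately equally, which is why it is the default
#' metric for NRAD comparison. Distances are computed between the mean
#' abundance vectors; confidence intervals are not propagated.
#'
#' @param a,b `"nrad"` objects sharing the same `R`.
#' @return non-negative number in `[0, 2)`.
#' @export
manhattan_distance <- function(a, b) {
  stopifnot(is_nrad(a), is_nrad(b))
  if (a$R != b$R) {
    stop("incompatible MaxRank: NRADs have R = ", a$R, " and ", b$R,
         call. = FALSE)
  }
  sum(abs(a$abundances - b$abundances))
}

#' Kolmogorov-Smirnov statistic between two RADs (baseline comparator)
#'
#' The two-sample KS statistic D between the rank-indexed cumulative
#' relative-abundance functions of two RADs, i.e. the Chebyshev distance
#' between the two CDFs. RADs of unequal richness are compared by treating
#' the missing ranks of the shorter RAD as zero abundance. This requires no
#' normalization but treats the tail regions poorly; it is provided only as
#' the baseline against which MaxRank normalization is compared, and is not
#' used in ordination or clustering defaults.
#'
#' @param rad_a,rad_b [rad()] objects, possibly of different richness.
#' @return number in `[0, 1]`.
#' @export
ks_distance <- function(rad_a, rad_b) {
  stopifnot(is_rad(rad_a), is_rad(rad_b))
  len <- max(rad_a$richness, rad_b$richness)
  pad <- function(r) {
    a <- numeric(len)
    a[seq_len(r$richness)] <- relative_abundances(r)
    a
  }
  max(abs(cumsum(pad(rad_a)) - cumsum(pad(rad_b))))
}

#' Pairwise distance matrix over a set of NRADs
#'
#' Computes all n(n-1)/2 pairwise distances and assembles them into a
#' symmetric matrix with zero diagonal, labelled by sample.
#'
#' @param nrads list of `"nrad"` objects sharing the same `R` (for
#'   `metric = "manhattan"`).
#' @param metric distance to use; currently `"manhattan"` ([manhattan_distance()]).
#' @return object of class `"nrad_dist"`: list with `labels`, square numeric
#'   `values`, and `metric`. Use [as.dist()] to pass it to clustering.
#' @export
distance_matrix <- function(nrads, metric = "manhattan") {
  metric <- match.arg(metric, c("manhattan"))
  stopifnot(length(nrads) >= 1L, all(vapply(nrads, is_nrad, logical(1))))
  Rs <- vapply(nrads, function(x) x$R, integer(1))
  if (length(unique(Rs)) != 1L) {
    stop("incompatible MaxRank: all NRADs must share the same R",
         call. = FALSE)
  }
  labels <- vapply(nrads, function(x) x$label, character(1))
  n <- length(nrads)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1L) {
    A <- do.call(rbind, lapply(nrads, function(x) x$abundances))
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d <- sum(abs(A[i, ] - A[j, ]))
        m[i, j] <- d
        m[j, i] <- d
      }
    }
  }
  structure(list(labels = labels, values = m, metric = metric),
            class = "nrad_dist")
}

#' @export
print.nrad_dist <- function(x, ...) {
  cat(sprintf("%s distance matrix over %d samples\n",
              x$metric, length(x$labels)))
  print(signif(x$values, 4))
  invisible(x)
}

#' @export
as.dist.nrad_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$values, diag = diag, upper = upper)
}

#' Write a distance matrix as square TSV
#'
#' Square tab-separated matrix with a header row and a leading label column.
#'
#' @param dm an `"nrad_dist"` object.
#' @param path output file path.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "nrad_dist"))
  df <- data.frame(sample = dm$labels, dm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square TSV distance matrix
#'
#' @param path file written by [write_distance_matrix()].
#' @param metric metric name recorded in the returned object.
#' @return an `"nrad_dist"` object.
#' @export
read_distance_matrix <- function(path, metric = "manhattan") {
  df <- utils::read.delim(path, check.names = FALSE)
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(m) <- list(labels, labels)
  structure(list(labels = labels, values = m, metric = metric),
            class = "nrad_dist")
}
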