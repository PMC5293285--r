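#' @title MaxRank normalization of rank abundance distributions
#' @description Core resampling algorithm mapping RADs of arbitrary richness
#'   to normalized RADs (NRADs) of a common maximum rank R.
#' @name normalization
NULL

# Internal constructor for the NRAD container. `abundances` must already be
# sorted non-increasing and sum to 1 (up to floating error).
new_nrad <- function(abundances, R, ci_low, ci_high, n_reps, seed, label) {
  structure(
    list(
      abundances = abundances,
      R = as.integer(R),
      ci_low = ci_low,
      ci_high = ci_high,
      n_reps = as.integer(n_reps),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      label = as.character(label)[1L]
    ),
    class = "nrad"
  )
}

#' @export
print.nrad <- function(x, ...) {
  cat(sprintf(
    "NRAD '%s': R = %d, %d repetitions\n", x$label, x$R, x$n_reps
  ))
  head_n <- min(5L, x$R)
  cat("  head abundances:",
      paste(signif(x$abundances[seq_len(head_n)], 4), collapse = " "),
      if (x$R > head_n) "..." else "", "\n")
  invisible(x)
}

is_nrad <- function(x) inherits(x, "nrad")

#' @export
as.data.frame.nrad <- function(x, ...) {
  data.frame(
    rank = seq_len(x$R),
    mean = x$abundances,
    ci_low = x$ci_low,
    ci_high = x$ci_high
  )
}

# Run `expr` under a temporary RNG state seeded with `seed` (if non-NULL),
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
  }
  force(expr)
}

check_maxrank <- function(rad, R) {
  if (length(R) != 1L || !is.finite(R) || R != round(R)) {
    stop("MaxRank R must be a single integer", call. = FALSE)
  }
  if (R < 2) stop("MaxRank below 2", call. = FALSE)
  if (R > rad$richness) stop("MaxRank exceeds sample richness", call. = FALSE)
  as.integer(R)
}

#' Single MaxRank subsample of a RAD
#'
#' Draws individuals uniformly at random without replacement from the pool of
#' \eqn{N_s} individuals of the sample. The draw that would introduce the
#' (R+1)-th distinct rank is rejected and sampling stops, so the subsample
#' contains exactly `R` distinct ranks. Counts are re-sorted in descending
#' order before return, since subsampling can invert near-equal ranks.
#'
#' Implemented as a random permutation of the multiset of individuals,
#' truncated just before the first occurrence of the (R+1)-th distinct rank;
#' this is equal in distribution to sequential one-at-a-time drawing.
#'
#' @param rad a [rad()] object.
#' @param R target maximum rank, `2 <= R <= rad$richness`.
#' @return integer vector of length `R`, sorted non-increasing; the per-rank
#'   counts of one subsample.
#' @export
maxrank_sample_once <- function(rad, R) {
  stopifnot(is_rad(rad))
  R <- check_maxrank(rad, R)
  pool <- rep.int(seq_len(rad$richness), rad$counts)
  perm <- pool[sample.int(length(pool))]
  first_seen <- which(!duplicated(perm))
  if (length(first_seen) > R) {
    perm <- perm[seq_len(first_seen[R + 1L] - 1L)]
  }
  sub <- tabulate(perm, nbins = rad$richness)
  sort.int(sub[sub > 0L], decreasing = TRUE)
}

#' MaxRank normalization of a RAD
#'
#' Maps a RAD to a normalized RAD (NRAD) of a chosen common maximum rank `R`.
#' Each of `n_reps` repetitions subsamples individuals without replacement
#' until exactly `R` distinct ranks are present (see [maxrank_sample_once()]),
#' divides each subsample's counts by its own total, and the resulting
#' relative-abundance vectors are averaged rank-wise. 90% confidence
#' intervals of the per-rank mean are estimated as the 5% and 95% percentiles
#' of bootstrapped averages of the repetition vectors.
#'
#' When `R` equals the sample richness the subsampling never removes a rank
#' and the NRAD equals the relative abundances of the RAD exactly, with
#' zero-width confidence intervals.
#'
#' @param rad a [rad()] object.
#' @param R common maximum rank, `2 <= R <= rad$richness`. See
#'   [choose_max_R()] for the recommended default over a set of samples.
#' @param n_reps number of subsampling repetitions (default 100).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @param n_boot number of bootstrap resamples used for the CI of the mean.
#' @return an object of class `"nrad"`: list with `abundances` (length `R`,
#'   non-increasing, summing to 1), `ci_low`, `ci_high`, `R`, `n_reps`,
#'   `seed`, `label`.
#' @examples
#' r <- rad(c(40, 30, 20, 5, 3, 2), "toy")
#' n <- maxrank_normalize(r, R = 4, n_reps = 50, seed = 1)
#' sum(n$abundances)  # 1
#' @export
maxrank_normalize <- function(rad, R, n_reps = 100, seed = NULL,
                              n_boot = 200) {
  stopifnot(is_rad(rad))
  R <- check_maxrank(rad, R)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)

  if (R == rad$richness) {
    # Exact identity: the stop rule never triggers, every repetition returns
    # the original counts.
    a <- relative_abundances(rad)
    return(new_nrad(a, R, a, a, n_reps, seed, rad$label))
  }

  with_seed(seed, {
    reps <- matrix(0, nrow = n_reps, ncol = R)
    pool <- rep.int(seq_len(rad$richness), rad$counts)
    n_pool <- length(pool)
    for (i in seq_len(n_reps)) {
      perm <- pool[sample.int(n_pool)]
      first_seen <- which(!duplicated(perm))
      if (length(first_seen) > R) {
        perm <- perm[seq_len(first_seen[R + 1L] - 1L)]
      }
      sub <- tabulate(perm, nbins = rad$richness)
      sub <- sort.int(sub[sub > 0L], decreasing = TRUE)
      reps[i, ] <- sub / sum(sub)
    }
    a <- colMeans(reps)
    if (n_reps == 1L) {
      ci_low <- ci_high <- a
    } else {
      boot_means <- matrix(0, nrow = n_boot, ncol = R)
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n_reps, n_reps, replace = TRUE)
        boot_means[b, ] <- colMeans(reps[idx, , drop = FALSE])
      }
      ci <- apply(boot_means, 2L, stats::quantile,
                  probs = c(0.05, 0.95), names = FALSE)
      ci_low <- pmin(ci[1L, ], a)
      ci_high <- pmax(ci[2L, ], a)
    }
    new_nrad(a, R, ci_low, ci_high, n_reps, seed, rad$label)
  })
}

#' Recommended common MaxRank for a set of RADs
#'
#' The largest admissible common `R` is the minimum richness over the set;
#' larger values would require inventing unobserved ranks. Using this maximum
#' possible `R` retains the abundance structure of all samples in the
#' greatest detail and is the recommended default.
#'
#' @param rads list of [rad()] objects.
#' @return integer, the minimum richness of the set.
#' @export
choose_max_R <- function(rads) {
  if (length(rads) == 0L) stop("empty collection of RADs", call. = FALSE)
  stopifnot(all(vapply(rads, is_rad, logical(1))))
  min(vapply(rads, function(r) r$richness, integer(1)))
}

#' Normalize a set of RADs to a common MaxRank
#'
#' Convenience wrapper applying [maxrank_normalize()] to every RAD. A single
#' user seed deterministically derives an independent seed per sample, so
#' results are reproducible regardless of evaluation order.
#'
#' @param rads list of [rad()] objects.
#' @param R common maximum rank; defaults to [choose_max_R()].
#' @param n_reps,seed,n_boot passed to [maxrank_normalize()].
#' @return list of `"nrad"` objects, named by sample labels.
#' @export
maxrank_normalize_set <- function(rads, R = choose_max_R(rads),
                                  n_reps = 100, seed = NULL, n_boot = 200) {
  seeds <- if (is.null(seed)) {
    vector("list", length(rads))
  } else {
    with_seed(seed, as.list(sample.int(.Machine$integer.max, length(rads))))
  }
  out <- mapply(function(r, s) maxrank_normalize(r, R, n_reps, s, n_boot),
                rads, seeds, SIMPLIFY = FALSE)
  names(out) <- vapply(rads, function(r) r$label, character(1))
  out
}

#' Cutoff normalization (baseline comparator)
#'
#' The simple alternative to MaxRank normalization: keep the first `R` ranks,
#' discard the tail, and renormalize the kept mass to 1 so that distances
#' between the resulting vectors remain on the same scale as NRAD distances.
#' Deterministic; provided for robustness comparisons, where it is less
#' stable under reduction of `R` than MaxRank normalization.
#'
#' @inheritParams maxrank_normalize
#' @return an `"nrad"` object with zero-width confidence intervals.
#' @export
cutoff_normalize <- function(rad, R) {
  stopifnot(is_rad(rad))
  R <- check_maxrank(rad, R)
  kept <- rad$counts[seq_len(R)]
  a <- kept / sum(as.numeric(kept))
  new_nrad(a, R, a, a, 0L, NULL, rad$label)
}

#' Down-sample a RAD to a target richness
#'
#' Draws individuals without replacement from the sample pool with the same
#' stop rule as [maxrank_sample_once()] until exactly `target_richness`
#' distinct ranks are present, and returns the subsample as a new RAD. Used
#' to test robustness of NRADs against sample size.
#'
#' @param rad a [rad()] object.
#' @param target_richness desired richness, `2 <= target_richness <= richness`.
#' @param seed optional integer seed.
#' @return a new [rad()] object with richness exactly `target_richness`.
#' @export
downsample_individuals <- function(rad, target_richness, seed = NULL) {
  stopifnot(is_rad(rad))
  target_richness <- check_maxrank(rad, target_richness)
  counts <- with_seed(seed, maxrank_sample_once(rad, target_richness))
  rad(counts, label = paste0(rad$label, "_downsampled"))
}
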