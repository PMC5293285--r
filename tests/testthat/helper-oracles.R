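# Independent oracles used by the tests. These deliberately use naive,
# brute-force implementations so they stay independent of the package code
# paths they check.

# All distinct orderings (multiset permutations) of the rank labels of a
# pool. Every distinct ordering of the pool's individuals is equally likely
# under uniform drawing without replacement, and orderings that coincide as
# rank-label sequences correspond to equally many individual orderings, so
# the distinct label sequences are themselves equally likely.
multiset_permutations <- function(counts) {
  out <- list()
  recurse <- function(remaining, prefix) {
    if (all(remaining == 0L)) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (r in which(remaining > 0L)) {
      remaining[r] <- remaining[r] - 1L
      recurse(remaining, c(prefix, r))
      remaining[r] <- remaining[r] + 1L
    }
  }
  recurse(as.integer(counts), integer(0))
  out
}

# Exact expected normalized sorted abundance vector of the MaxRank stop rule,
# by exhaustive enumeration of all equally likely draw orders of the pool.
enumerate_maxrank_mean <- function(counts, R) {
  perms <- multiset_permutations(counts)
  vecs <- vapply(perms, function(perm) {
    seen <- integer(0)
    kept <- integer(length(counts))
    for (x in perm) {
      if (!(x %in% seen)) {
        if (length(seen) == R) break
        seen <- c(seen, x)
      }
      kept[x] <- kept[x] + 1L
    }
    v <- sort(kept[kept > 0L], decreasing = TRUE)
    v / sum(v)
  }, numeric(R))
  rowMeans(vecs)
}

# Monte-Carlo mean and standard error of the normalized sorted subsample,
# built directly on maxrank_sample_once.
mc_maxrank_mean <- function(rad_obj, R, n_reps, seed) {
  set.seed(seed)
  reps <- vapply(seq_len(n_reps), function(i) {
    v <- maxrank_sample_once(rad_obj, R)
    v / sum(v)
  }, numeric(R))
  list(mean = rowMeans(reps),
       se = apply(reps, 1L, stats::sd) / sqrt(n_reps))
}

# Cohen's kappa from a confusion table (rows = predicted, cols = true) via
# the independent e1071 implementation.
cohen_kappa_oracle <- function(tab) {
  e1071::classAgreement(tab)$kappa
}

# A maximally heterogeneous set of n log-normal communities for the
# down-sampling robustness study. At R = 1000 the generator's NRAD shapes
# occupy an effectively one-dimensional evenness continuum (richness at
# fixed depth, geometric p, and broken stick all collapse onto the axis
# that sdlog parameterizes), so the most mutually distinct set is a ladder
# along that axis, spaced uniformly in *measured* NRAD Manhattan distance.
# arc_segs holds measured adjacent distances per sdlog segment at richness
# 1e5 / depth 1e6; the cumulative arc is inverted piecewise-linearly.
# Large richness and depth keep the 10x-down-sampled communities far richer
# than R = 1000, suppressing the single-realization down-sampling bias.
evenness_ladder_set <- function(n, seed = 1) {
  arc_breaks <- c(1.0, 1.25, 1.5, 1.75, 2.0, 2.25, 2.5, 2.75, 3.0, 3.2, 3.4)
  arc_segs <- c(0.022, 0.035, 0.063, 0.085, 0.161, 0.19, 0.154, 0.351,
                0.428, 0.2)
  cum <- c(0, cumsum(arc_segs))
  sdl <- stats::approx(cum, arc_breaks,
                       xout = seq(0, cum[length(cum)], length.out = n))$y
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n)
  lapply(seq_len(n), function(i) {
    generate_community(community_spec("lognormal", richness = 1e5,
                                      depth = 1e6, sdlog = sdl[i],
                                      seed = seeds[i],
                                      label = sprintf("c%02d", i)))
  })
}

# Communities whose richness spans more than an order of magnitude at fixed
# depth, so that pairwise differences sit substantially in the RAD tails.
richness_gradient_set <- function(n, depth, richness_range = c(1500, 30000),
                                  sdlog_range = c(1.2, 2.2), seed = 1) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n)
  rich <- round(exp(seq(log(richness_range[1]), log(richness_range[2]),
                        length.out = n)))
  sdl <- rep_len(seq(sdlog_range[1], sdlog_range[2],
                     length.out = ceiling(n / 2)), n)
  lapply(seq_len(n), function(i) {
    generate_community(community_spec("lognormal", richness = rich[i],
                                      depth = depth, sdlog = sdl[i],
                                      seed = seeds[i],
                                      label = sprintf("s%02d", i)))
  })
}
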