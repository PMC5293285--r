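#' Specification of a synthetic community
#'
#' Describes a community whose true relative abundances follow a standard
#' abundance law, observed through multinomial sampling of a finite
#' sequencing depth. Families:
#' \describe{
#'   \item{geometric}{abundance proportional to \eqn{p(1-p)^{r-1}} over ranks
#'     r = 1..richness; parameter `p`.}
#'   \item{lognormal}{abundances drawn from a log-normal with parameters
#'     `meanlog`, `sdlog` of log-abundance, then sorted and normalized.}
#'   \item{broken_stick}{the parameter-free expected broken-stick
#'     proportions ([broken_stick_nrad()]).}
#'   \item{uniform}{equal abundances.}
#' }
#'
#' @param family one of `"geometric"`, `"lognormal"`, `"broken_stick"`,
#'   `"uniform"`.
#' @param richness number of species in the true community.
#' @param depth total number of individuals sampled (sequencing depth);
#'   must be at least `richness`.
#' @param p geometric parameter in `(0, 1)`.
#' @param meanlog,sdlog log-normal parameters.
#' @param seed optional integer seed.
#' @param label sample label.
#' @return list of class `"community_spec"`.
#' @export
community_spec <- function(family = c("geometric", "lognormal",
                                      "broken_stick", "uniform"),
                           richness, depth, p = 0.01, meanlog = 0,
                           sdlog = 1, seed = NULL, label = "synthetic") {
  family <- match.arg(family)
  stopifnot(richness >= 2, depth >= 1)
  if (depth < richness) {
    stop("depth must be at least the richness", call. = FALSE)
  }
  if (family == "geometric" && (p <= 0 || p >= 1)) {
    stop("geometric parameter p must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(family = family, richness = as.integer(richness),
         depth = depth, p = p, meanlog = meanlog, sdlog = sdlog,
         seed = seed, label = label),
    class = "community_spec"
  )
}

# True relative abundances of a community spec (before sampling noise).
true_abundances <- function(spec) {
  S <- spec$richness
  a <- switch(spec$family,
    geometric = {
      w <- spec$p * (1 - spec$p)^(seq_len(S) - 1)
      w / sum(w)
    },
    lognormal = {
      w <- sort(stats::rlnorm(S, spec$meanlog, spec$sdlog), decreasing = TRUE)
      w / sum(w)
    },
    broken_stick = broken_stick_nrad(S)$abundances,
    uniform = rep(1 / S, S)
  )
  a
}

#' Generate an observed synthetic community RAD
#'
#' Draws the true relative abundances from the family of the spec, then a
#' multinomial sample of `depth` individuals from them, and returns the
#' observed RAD (species with zero observed count are dropped, so the
#' observed richness can be below the true richness for shallow depths).
#'
#' @param spec a [community_spec()].
#' @return a [rad()] object.
#' @examples
#' spec <- community_spec("geometric", richness = 50, depth = 1e4,
#'                        p = 0.05, seed = 1)
#' generate_community(spec)
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(spec$seed, {
    a <- true_abundances(spec)
    counts <- stats::rmultinom(1L, size = spec$depth, prob = a)[, 1L]
    rad(counts, label = spec$label)
  })
}

#' Generate a synthetic entropy-versus-age dataset
#'
#' Ages are drawn log-uniformly over `age_range` (mirroring log-age binning
#' of developmental studies, which concentrates samples at young ages where
#' change is fastest); entropies follow [entropy_age_curve()] plus additive
#' Gaussian noise.
#'
#' @param H0,Hmax,lambda true curve parameters (`Hmax > H0 > 0`,
#'   `lambda > 0`).
#' @param n number of samples (`n >= 4`).
#' @param noise_sd standard deviation of additive Gaussian noise (nats).
#' @param age_range ages in years, `c(min, max)` with `min > 0`.
#' @param seed optional integer seed.
#' @return data.frame with columns `age` (years) and `H` (nats).
#' @export
generate_entropy_age_dataset <- function(H0, Hmax, lambda, n,
                                         noise_sd = 0,
                                         age_range = c(0.03, 80),
                                         seed = NULL) {
  stopifnot(Hmax > H0, H0 > 0, lambda > 0, n >= 4, noise_sd >= 0,
            age_range[1] > 0, age_range[2] > age_range[1])
  with_seed(seed, {
    ages <- exp(stats::runif(n, log(age_range[1]), log(age_range[2])))
    H <- entropy_age_curve(ages, H0, Hmax, lambda) +
      stats::rnorm(n, 0, noise_sd)
    data.frame(age = ages, H = H)
  })
}

#' Shape specification for labeled NRAD classes
#'
#' Defines a class of NRAD shapes: a geometric-like exponential decay of
#' log-abundance with rate `decay` per rank, plus an optional triangular bump
#' of height `bump` (in log-abundance) confined to the rank interval `band`.
#' The bump rises and falls linearly inside the band; keeping its slope below
#' `decay` preserves monotonicity of the template.
#'
#' @param decay decay rate of log-abundance per rank.
#' @param band integer rank interval `c(lo, hi)` carrying the class signal.
#' @param bump bump height in log-abundance at the band center (0 = no
#'   signal).
#' @return list of class `"nrad_shape"`.
#' @export
nrad_shape <- function(decay = 0.02, band = c(100, 160), bump = 0) {
  stopifnot(decay > 0, length(band) == 2L, band[1] < band[2], bump >= 0)
  structure(list(decay = decay, band = as.integer(band), bump = bump),
            class = "nrad_shape")
}

shape_template <- function(shape, R) {
  r <- seq_len(R)
  log_a <- -shape$decay * r
  if (shape$bump > 0) {
    lo <- shape$band[1]; hi <- shape$band[2]
    mid <- (lo + hi) / 2
    inside <- r >= lo & r <= hi
    tri <- pmax(0, 1 - abs(r - mid) / (mid - lo))
    log_a <- log_a + shape$bump * tri * inside
  }
  a <- exp(log_a)
  a / sum(a)
}

#' Generate a labeled set of synthetic NRADs for classification tests
#'
#' Produces two classes of NRADs whose shapes differ only in a configurable
#' middle-rank band (see [nrad_shape()]), emulating datasets where the
#' discriminative information sits neither in the head nor in the tail.
#' Per-sample variability is multiplicative log-normal noise on the
#' abundances; vectors are re-sorted and renormalized, so every output is a
#' valid NRAD.
#'
#' @param n_per_class samples per class (`>= 2`; a single sample per class
#'   cannot be cross-validated).
#' @param class_shapes list of two [nrad_shape()] objects.
#' @param R MaxRank of the generated NRADs.
#' @param noise_sd standard deviation of the log-normal per-rank noise.
#' @param seed optional integer seed.
#' @return list with `nrads` (list of `"nrad"` objects), `labels`
#'   (character vector `"A"`/`"B"`), and `band` (the rank interval of the
#'   shape with the larger bump, i.e. where the planted signal sits).
#' @export
generate_labeled_nrad_set <- function(n_per_class,
                                      class_shapes = list(
                                        nrad_shape(bump = 0),
                                        nrad_shape(bump = 0.45)
                                      ),
                                      R = 300, noise_sd = 0.15,
                                      seed = NULL) {
  stopifnot(length(class_shapes) == 2L,
            all(vapply(class_shapes, inherits, logical(1), "nrad_shape")))
  if (n_per_class < 2L) {
    stop("need at least 2 samples per class for cross-validation",
         call. = FALSE)
  }
  if (identical(class_shapes[[1L]], class_shapes[[2L]])) {
    warning("identical class shapes: classes carry no signal", call. = FALSE)
  }
  with_seed(seed, {
    nrads <- list()
    labels <- character(0)
    for (cls in 1:2) {
      template <- shape_template(class_shapes[[cls]], R)
      for (i in seq_len(n_per_class)) {
        a <- template * stats::rlnorm(R, 0, noise_sd)
        a <- sort(a / sum(a), decreasing = TRUE)
        lab <- c("A", "B")[cls]
        nrads[[length(nrads) + 1L]] <-
          new_nrad(a, R, a, a, 0L, NULL, sprintf("%s%02d", lab, i))
        labels <- c(labels, lab)
      }
    }
    signal_shape <- class_shapes[[which.max(vapply(class_shapes, `[[`,
                                                   numeric(1), "bump"))]]
    list(nrads = nrads, labels = labels, band = signal_shape$band)
  })
}
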