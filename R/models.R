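#' Broken-stick reference NRAD
#'
#' Expected relative abundances of MacArthur's broken-stick null model at
#' richness R: a unit resource is split at R-1 uniform random points and the
#' expected sorted segment lengths are
#' \eqn{a_r = \frac{1}{R}\sum_{k=r}^{R} 1/k}. The model has no free
#' parameters, so it needs no fitting and serves as a parameter-free
#' reference shape (e.g. for B-cell receptor V-segment usage, whose NRADs it
#' describes well).
#'
#' @param R richness (number of segments), `R >= 2`.
#' @return an `"nrad"` object (deterministic, zero-width CIs), label
#'   `"broken_stick"`.
#' @export
broken_stick_nrad <- function(R) {
  if (length(R) != 1L || !is.finite(R) || R != round(R) || R < 2) {
    stop("broken-stick model requires integer R >= 2", call. = FALSE)
  }
  R <- as.integer(R)
  a <- rev(cumsum(rev(1 / seq_len(R)))) / R
  new_nrad(a, R, a, a, 0L, NULL, "broken_stick")
}

#' Monte-Carlo broken-stick simulation
#'
#' Breaks a unit stick at R-1 uniform random points, sorts segment lengths
#' in descending order, and averages over `n_sticks` replicates. This is the
#' stochastic counterpart (and test oracle) of the closed form in
#' [broken_stick_nrad()].
#'
#' @param R number of segments, `R >= 2`.
#' @param n_sticks number of replicate sticks.
#' @param seed optional integer seed.
#' @return list with `mean` (length-R vector of mean sorted segment lengths)
#'   and `se` (per-rank standard errors of the mean).
#' @export
simulate_broken_stick <- function(R, n_sticks, seed = NULL) {
  stopifnot(R >= 2, n_sticks >= 1)
  with_seed(seed, {
    segs <- matrix(0, nrow = n_sticks, ncol = R)
    for (i in seq_len(n_sticks)) {
      cuts <- sort(stats::runif(R - 1L))
      segs[i, ] <- sort(diff(c(0, cuts, 1)), decreasing = TRUE)
    }
    list(
      mean = colMeans(segs),
      se = apply(segs, 2L, stats::sd) / sqrt(n_sticks)
    )
  })
}

#' Maximum-likelihood geometric fit with KS consistency test
#'
#' Fits a geometric distribution on support \{1, 2, ...\} to positive integer
#' counts (e.g. numbers of distinct sequence variants per V-segment) by
#' maximum likelihood, `p_hat = 1/mean(counts)`, and tests consistency with a
#' one-sample Kolmogorov-Smirnov test against Geometric(`p_hat`).
#'
#' The support starts at 1 because each observed species/variant contributes
#' at least one count; note that some libraries parameterize the geometric on
#' \{0, 1, ...\}. The KS test uses the plug-in estimate `p_hat`, which makes
#' the p-value conservative, and the test statistic is computed on discrete
#' data (ties), so borderline p-values should be read with caution.
#'
#' @param counts vector of positive integers.
#' @return list of class `"geometric_fit"`: `p_hat`, `ks_D`, `ks_p`, `n`.
#' @export
fit_geometric <- function(counts) {
  if (length(counts) == 0L) stop("empty input", call. = FALSE)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("counts must be positive integers", call. = FALSE)
  }
  p_hat <- 1 / mean(counts)
  ks <- suppressWarnings(
    stats::ks.test(counts, function(q) stats::pgeom(q - 1, p_hat))
  )
  structure(
    list(p_hat = p_hat, ks_D = unname(ks$statistic),
         ks_p = unname(ks$p.value), n = length(counts)),
    class = "geometric_fit"
  )
}

#' @export
print.geometric_fit <- function(x, ...) {
  cat(sprintf("Geometric ML fit (support 1, 2, ...): p = %.4f (n = %d)\n",
              x$p_hat, x$n))
  cat(sprintf("  one-sample KS: D = %.4f, p = %.3g\n", x$ks_D, x$ks_p))
  invisible(x)
}

#' Saturating growth curve of NRAD entropy with age
#'
#' \eqn{H_R(t) = H_R^{max} - (H_R^{max} - H_R^0) e^{-\lambda_R t}}: entropy
#' starts at `H0` shortly after birth and saturates at `Hmax` with rate
#' `lambda` (1/yr). This captures diversification of a community (e.g. the
#' infant gut microbiome) whose diversity gains per new exposure shrink as
#' diversity accumulates.
#'
#' @param t age in years.
#' @param H0 entropy at t = 0 (nats).
#' @param Hmax asymptotic entropy (nats).
#' @param lambda growth rate (1/yr).
#' @return entropy values at `t`.
#' @export
entropy_age_curve <- function(t, H0, Hmax, lambda) {
  Hmax - (Hmax - H0) * exp(-lambda * t)
}

#' Fit the entropy-versus-age growth model
#'
#' Least-squares fit of [entropy_age_curve()] to (entropy, age) pairs with
#' the Levenberg-Marquardt algorithm. 90% confidence intervals are derived
#' from the Jacobian at the optimum (t-based Wald intervals on the
#' asymptotic standard errors); the coefficient of determination r-squared is
#' reported.
#'
#' @param entropies NRAD entropies in nats.
#' @param ages ages in years, same length.
#' @param init named starting values `c(H0, lambda, Hmax)`; the defaults are
#'   rough estimates suitable for gut-microbiome NRAD entropies.
#' @param R MaxRank at which the entropies were computed (metadata only).
#' @return object of class `"entropy_age_fit"`: `H0`, `Hmax`, `lambda`,
#'   `ci_half_widths` (named, 90%), `r2`, `n`, `R`.
#' @export
fit_entropy_age_model <- function(entropies, ages,
                                  init = c(H0 = 3.5, lambda = 0.19,
                                           Hmax = 6.0),
                                  R = NA_integer_) {
  stopifnot(length(entropies) == length(ages))
  if (length(entropies) < 4L) {
    stop("need at least 4 (entropy, age) pairs", call. = FALSE)
  }
  df <- data.frame(H = entropies, t = ages)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      H ~ Hmax - (Hmax - H0) * exp(-lambda * t),
      data = df,
      start = as.list(init),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("entropy-age model fit did not converge: ", conditionMessage(e),
           "\n  starting values: ",
           paste(names(init), signif(init, 4), sep = "=", collapse = ", "),
           call. = FALSE)
    }
  )
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  dfree <- length(entropies) - length(est)
  half <- stats::qt(0.95, dfree) * se
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / sum((entropies - mean(entropies))^2)
  structure(
    list(
      H0 = unname(est["H0"]),
      Hmax = unname(est["Hmax"]),
      lambda = unname(est["lambda"]),
      ci_half_widths = half[c("H0", "Hmax", "lambda")],
      r2 = r2,
      n = length(entropies),
      R = R
    ),
    class = "entropy_age_fit"
  )
}

#' @export
print.entropy_age_fit <- function(x, ...) {
  cat("Entropy-vs-age model fit (90% CIs):\n")
  cat(sprintf("  H0     = %.3f +/- %.3f nats\n", x$H0,
              x$ci_half_widths["H0"]))
  cat(sprintf("  Hmax   = %.3f +/- %.3f nats\n", x$Hmax,
              x$ci_half_widths["Hmax"]))
  cat(sprintf("  lambda = %.3f +/- %.3f 1/yr\n", x$lambda,
              x$ci_half_widths["lambda"]))
  cat(sprintf("  r^2 = %.3f, n = %d\n", x$r2, x$n))
  invisible(x)
}

#' Serialize a fitted model as a JSON record
#'
#' @param x an `"entropy_age_fit"` or `"geometric_fit"` object.
#' @param path output file path.
#' @export
write_model_json <- function(x, path) {
  rec <- unclass(x)
  rec$ci_half_widths <- as.list(rec$ci_half_widths)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
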