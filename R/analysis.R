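#' Average a group of NRADs with bootstrap confidence intervals
#'
#' The rank-wise arithmetic mean of NRADs sharing the same MaxRank R is
#' itself an NRAD (same R, total abundance 1, non-increasing). The 90%
#' confidence interval of the group mean is estimated per rank as the 5% and
#' 95% percentiles of `n_boot` bootstrap resamples of the group members
#' (sampling members with replacement).
#'
#' @param nrads list of `"nrad"` objects with common `R`.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed optional integer seed for the bootstrap.
#' @param label group label for the returned NRAD.
#' @return an `"nrad"` object with an extra element `n_members`.
#' @export
average_nrads <- function(nrads, n_boot = 1000, seed = NULL,
                          label = "group_mean") {
  stopifnot(length(nrads) >= 1L, all(vapply(nrads, is_nrad, logical(1))))
  Rs <- vapply(nrads, function(x) x$R, integer(1))
  if (length(unique(Rs)) != 1L) {
    stop("incompatible MaxRank: all NRADs must share the same R",
         call. = FALSE)
  }
  A <- do.call(rbind, lapply(nrads, function(x) x$abundances))
  n <- nrow(A)
  m <- colMeans(A)
  if (n == 1L) {
    ci_low <- ci_high <- m
  } else {
    ci <- with_seed(seed, {
      boot <- matrix(0, nrow = n_boot, ncol = ncol(A))
      for (b in seq_len(n_boot)) {
        boot[b, ] <- colMeans(A[sample.int(n, n, replace = TRUE), ,
                                drop = FALSE])
      }
      apply(boot, 2L, stats::quantile, probs = c(0.05, 0.95), names = FALSE)
    })
    ci_low <- pmin(ci[1L, ], m)
    ci_high <- pmax(ci[2L, ], m)
  }
  out <- new_nrad(m, Rs[1L], ci_low, ci_high, 0L, seed, label)
  out$n_members <- n
  out
}

#' Classical multidimensional scaling of an NRAD distance matrix
#'
#' Double-centered eigendecomposition (via [stats::cmdscale()]) embedding the
#' samples into `k` dimensions. The explained fraction is the sum of the top
#' `k` positive eigenvalues divided by the sum of all positive eigenvalues;
#' negative eigenvalues (non-Euclidean residual of the Manhattan metric) are
#' excluded from the denominator.
#'
#' @param dm an `"nrad_dist"` object.
#' @param k number of output dimensions (default 2).
#' @return list of class `"nrad_mds"`: `coordinates` (n x k matrix, labelled
#'   rows), `explained` (fraction in `[0, 1]`), `eigenvalues`.
#' @export
cmds <- function(dm, k = 2) {
  stopifnot(inherits(dm, "nrad_dist"), k >= 1)
  n <- length(dm$labels)
  fit <- stats::cmdscale(stats::as.dist(dm$values), k = min(k, n - 1L),
                         eig = TRUE)
  pos <- fit$eig[fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig), 1)]
  n_pos <- length(pos)
  if (k > n_pos) {
    warning("requested ", k, " dimensions but only ", n_pos,
            " positive eigenvalues; reducing k", call. = FALSE)
    k <- max(n_pos, 1L)
  }
  coords <- fit$points[, seq_len(min(k, ncol(fit$points))), drop = FALSE]
  rownames(coords) <- dm$labels
  explained <- if (n_pos == 0L) 0 else sum(pos[seq_len(min(k, n_pos))]) / sum(pos)
  structure(
    list(coordinates = coords, explained = explained, eigenvalues = fit$eig),
    class = "nrad_mds"
  )
}

#' @export
print.nrad_mds <- function(x, ...) {
  cat(sprintf("cMDS embedding: %d samples, %d dimensions, %.1f%% explained\n",
              nrow(x$coordinates), ncol(x$coordinates), 100 * x$explained))
  invisible(x)
}

#' Hierarchical clustering of an NRAD distance matrix
#'
#' Agglomerative clustering via [stats::hclust()], complete linkage by
#' default. The tree can be exported as Newick with branch lengths derived
#' from the merge heights.
#'
#' @param dm an `"nrad_dist"` object.
#' @param linkage agglomeration criterion (default `"complete"`).
#' @return an object of class `"hclust"` with the sample labels.
#' @export
hierarchical_cluster <- function(dm, linkage = "complete") {
  stopifnot(inherits(dm, "nrad_dist"))
  stats::hclust(stats::as.dist(dm$values), method = linkage)
}

#' Export a dendrogram as a Newick tree
#'
#' @param hc an `"hclust"` object (from [hierarchical_cluster()]).
#' @param path output file path.
#' @export
write_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Chance-corrected classification agreement (kappa statistic)
#'
#' \eqn{\kappa = (ACC - ACC_{expect}) / (1 - ACC_{expect})} with
#' \eqn{ACC = n_{correct}/N} and the expected accuracy of random guessing at
#' the model's marginal rates,
#' \eqn{ACC_{expect} = \sum_c (n_{pred,c}/N)(n_{true,c}/N)}. A perfect model
#' has kappa = 1, random guessing kappa = 0. Equals Cohen's kappa on the
#' corresponding confusion table.
#'
#' @param n_correct number of correct predictions.
#' @param N total number of predictions.
#' @param n_pred vector of predicted counts per class (sums to N).
#' @param n_true vector of true counts per class (sums to N).
#' @return kappa in `(-Inf, 1]`.
#' @export
kappa_statistic <- function(n_correct, N, n_pred, n_true) {
  if (N <= 0) stop("N must be positive", call. = FALSE)
  if (sum(n_pred) != N || sum(n_true) != N) {
    stop("marginals must each sum to N", call. = FALSE)
  }
  acc <- n_correct / N
  acc_expect <- sum((n_pred / N) * (n_true / N))
  if (acc_expect >= 1) {
    stop("degenerate marginals: expected accuracy is 1, kappa undefined",
         call. = FALSE)
  }
  (acc - acc_expect) / (1 - acc_expect)
}

# Stratified fold assignment: each class is split as evenly as possible
# across folds.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Random-forest classification of NRADs with kappa evaluation
#'
#' Trains a random forest with the R per-rank NRAD abundances as predictors
#' and a binary class label (e.g. country of origin) as response, evaluated
#' by k-fold cross-validation (default threefold: train on 2/3, predict the
#' held-out 1/3). Performance is reported as accuracy ACC and the
#' chance-corrected kappa statistic ([kappa_statistic()]), as mean and
#' standard error over folds. Folds are stratified by class to stabilize
#' kappa under class imbalance.
#'
#' Per-rank importance is the standard permutation importance (mean decrease
#' in accuracy): for each tree, the drop in out-of-bag accuracy when the
#' abundances of one rank are randomly permuted, averaged over trees and
#' folds. Per-tree out-of-bag permutation resolves the contributions of
#' strongly correlated ranks, which whole-model feature permutation cannot
#' (permuting one of many redundant informative ranks barely changes a full
#' forest's predictions).
#'
#' @param nrads list of `"nrad"` objects sharing `R`.
#' @param labels class label per NRAD (two classes).
#' @param n_folds number of cross-validation folds (default 3).
#' @param n_trees trees per forest (default 500).
#' @param seed optional integer seed (folds, forests, permutations).
#' @return list of class `"nrad_classifier_report"`: `acc`, `acc_se`,
#'   `kappa`, `kappa_se`, `importance` (length-R vector), `fold` (fold
#'   assignment), `per_fold` (data.frame of ACC and kappa per fold), `seed`.
#' @export
classify_nrads <- function(nrads, labels, n_folds = 3, n_trees = 500,
                           seed = NULL) {
  stopifnot(all(vapply(nrads, is_nrad, logical(1))))
  Rs <- vapply(nrads, function(x) x$R, integer(1))
  if (length(unique(Rs)) != 1L) {
    stop("incompatible MaxRank: all NRADs must share the same R",
         call. = FALSE)
  }
  labels <- factor(labels)
  if (nlevels(labels) < 2L) {
    stop("need at least two classes to train a classifier", call. = FALSE)
  }
  if (min(table(labels)) < n_folds) {
    stop("each class needs at least n_folds members for cross-validation",
         call. = FALSE)
  }
  X <- do.call(rbind, lapply(nrads, function(x) x$abundances))
  colnames(X) <- paste0("rank", seq_len(ncol(X)))
  R <- ncol(X)

  with_seed(seed, {
    fold <- stratified_folds(labels, n_folds)
    acc <- kap <- numeric(n_folds)
    importance <- matrix(0, nrow = n_folds, ncol = R)
    for (f in seq_len(n_folds)) {
      train <- fold != f
      rf <- randomForest::randomForest(x = X[train, , drop = FALSE],
                                       y = labels[train], ntree = n_trees,
                                       importance = TRUE)
      test_x <- X[!train, , drop = FALSE]
      test_y <- labels[!train]
      pred <- stats::predict(rf, test_x)
      N <- length(test_y)
      n_correct <- sum(pred == test_y)
      n_pred <- as.vector(table(factor(pred, levels = levels(labels))))
      n_true <- as.vector(table(test_y))
      acc[f] <- n_correct / N
      kap[f] <- kappa_statistic(n_correct, N, n_pred, n_true)
      importance[f, ] <- randomForest::importance(rf, type = 1,
                                                  scale = FALSE)[, 1L]
    }
    structure(
      list(
        acc = mean(acc), acc_se = stats::sd(acc) / sqrt(n_folds),
        kappa = mean(kap), kappa_se = stats::sd(kap) / sqrt(n_folds),
        importance = colMeans(importance),
        fold = fold,
        per_fold = data.frame(fold = seq_len(n_folds), acc = acc,
                              kappa = kap),
        seed = if (is.null(seed)) NA_integer_ else seed
      ),
      class = "nrad_classifier_report"
    )
  })
}

#' @export
print.nrad_classifier_report <- function(x, ...) {
  cat(sprintf("NRAD random-forest classification (%d-fold CV):\n",
              nrow(x$per_fold)))
  cat(sprintf("  ACC   = %.3f +/- %.3f\n", x$acc, x$acc_se))
  cat(sprintf("  kappa = %.3f +/- %.3f\n", x$kappa, x$kappa_se))
  top <- order(x$importance, decreasing = TRUE)[seq_len(min(3L, length(x$importance)))]
  cat("  most informative ranks:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a classifier report as JSON
#'
#' @param x an `"nrad_classifier_report"`.
#' @param path output file path.
#' @export
write_classifier_json <- function(x, path) {
  rec <- unclass(x)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
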