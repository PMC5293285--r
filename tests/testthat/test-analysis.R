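test_that("NRAD averages are NRADs with sensible bootstrap CIs", {
  a <- make_nrad(c(0.6, 0.4), "a")
  b <- make_nrad(c(0.8, 0.2), "b")
  g <- average_nrads(list(a, b), n_boot = 500, seed = 1)
  expect_equal(g$abundances, c(0.7, 0.3))
  expect_equal(sum(g$abundances), 1, tolerance = 1e-12)
  expect_true(all(diff(g$abundances) <= 0))
  expect_true(all(g$ci_low <= g$abundances & g$abundances <= g$ci_high))
  expect_identical(g$n_members, 2L)

  solo <- average_nrads(list(a))
  expect_equal(solo$abundances, a$abundances)
  expect_equal(solo$ci_low, solo$abundances)

  twins <- average_nrads(list(a, a), n_boot = 100, seed = 2)
  expect_equal(twins$ci_low, twins$abundances)
  expect_equal(twins$ci_high, twins$abundances)

  expect_error(average_nrads(list(a, make_nrad(c(1, 1, 1)))),
               "incompatible MaxRank")
})

test_that("cMDS reproduces collinear and planar geometries", {
  # three collinear points, distances 1, 1, 2
  m <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  dm <- structure(list(labels = letters[1:3], values = m,
                       metric = "manhattan"), class = "nrad_dist")
  fit <- cmds(dm, k = 1)
  expect_equal(as.numeric(dist(fit$coordinates)), c(1, 2, 1),
               tolerance = 1e-8)
  expect_equal(fit$explained, 1, tolerance = 1e-8)

  # planar points: recovered pairwise distances equal the input distances
  set.seed(4)
  pts <- matrix(rnorm(14), ncol = 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("p", 1:7), paste0("p", 1:7))
  dm2 <- structure(list(labels = rownames(d), values = d,
                        metric = "euclidean"), class = "nrad_dist")
  fit2 <- cmds(dm2, k = 2)
  expect_equal(as.matrix(dist(fit2$coordinates)), d, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit2$explained, 1, tolerance = 1e-8)

  # identical points embed at the origin, excess k is reduced with a warning
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  dmz <- structure(list(labels = letters[1:3], values = z,
                        metric = "manhattan"), class = "nrad_dist")
  suppressWarnings(  # cmdscale itself also warns on the degenerate input
    expect_warning(fitz <- cmds(dmz, k = 2), "positive eigenvalues")
  )
  expect_true(all(abs(fitz$coordinates) < 1e-12))
})

test_that("complete-linkage clustering follows the manual agglomeration", {
  labs <- c("a", "b", "c", "d")
  m <- matrix(0, 4, 4, dimnames = list(labs, labs))
  m["a", "b"] <- m["b", "a"] <- 0.2
  m["a", "c"] <- m["c", "a"] <- 0.5
  m["b", "c"] <- m["c", "b"] <- 0.6
  m["a", "d"] <- m["d", "a"] <- 0.9
  m["b", "d"] <- m["d", "b"] <- 1.0
  m["c", "d"] <- m["d", "c"] <- 0.4
  dm <- structure(list(labels = labs, values = m, metric = "manhattan"),
                  class = "nrad_dist")
  hc <- hierarchical_cluster(dm, "complete")
  # manual trace: {a,b}@0.2, {c,d}@0.4, then max(0.5,0.6,0.9,1.0)=1.0
  expect_equal(hc$height, c(0.2, 0.4, 1.0))

  two <- structure(list(labels = c("x", "y"),
                        values = matrix(c(0, 0.3, 0.3, 0), 2, 2,
                                        dimnames = list(c("x", "y"),
                                                        c("x", "y"))),
                        metric = "manhattan"), class = "nrad_dist")
  hc2 <- hierarchical_cluster(two)
  expect_equal(hc2$height, 0.3)

  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, labs)
})

test_that("kappa matches hand-worked and degenerate cases", {
  expect_equal(kappa_statistic(7, 10, c(6, 4), c(5, 5)), 0.4)
  expect_equal(kappa_statistic(10, 10, c(6, 4), c(6, 4)), 1)
  # ACC == ACC_expect gives 0
  expect_equal(kappa_statistic(5, 10, c(5, 5), c(5, 5)), 0)
  expect_error(kappa_statistic(10, 10, c(10, 0), c(10, 0)),
               "degenerate marginals")
  expect_error(kappa_statistic(3, 10, c(5, 4), c(5, 5)), "sum to N")
})

test_that("kappa equals the independent Cohen's kappa on random tables", {
  skip_if_not_installed("e1071")
  set.seed(77)
  n_checked <- 0
  while (n_checked < 1000) {
    tab <- matrix(sample(0:30, 4, replace = TRUE), 2, 2)
    N <- sum(tab)
    if (N == 0) next
    n_pred <- rowSums(tab)
    n_true <- colSums(tab)
    if (sum((n_pred / N) * (n_true / N)) >= 1) next
    ours <- kappa_statistic(sum(diag(tab)), N, n_pred, n_true)
    expect_equal(ours, cohen_kappa_oracle(tab), tolerance = 1e-12)
    n_checked <- n_checked + 1
  }
})

test_that("classifier separates planted classes and collapses without signal", {
  set_sep <- generate_labeled_nrad_set(15, R = 200, seed = 31)
  rep_sep <- classify_nrads(set_sep$nrads, set_sep$labels, seed = 5)
  expect_gt(rep_sep$kappa, 0.8)
  expect_true(rep_sep$acc >= rep_sep$kappa)

  # shuffled labels carry no information: kappa near 0
  set.seed(6)
  rep_null <- classify_nrads(set_sep$nrads, sample(set_sep$labels), seed = 7)
  expect_lt(abs(rep_null$kappa), 0.3)

  expect_error(classify_nrads(set_sep$nrads, rep("A", 30)), "two classes")
})
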