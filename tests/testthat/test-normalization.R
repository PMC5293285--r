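test_that("MaxRank subsampling at R = richness reproduces the RAD exactly", {
  r <- rad(c(4, 3, 1))
  set.seed(1)
  for (i in 1:10) {
    expect_identical(maxrank_sample_once(r, 3), c(4L, 3L, 1L))
  }
  n <- maxrank_normalize(r, 3, n_reps = 7, seed = 1)
  expect_identical(n$abundances, relative_abundances(r))
  expect_identical(n$ci_low, n$abundances)
  expect_identical(n$ci_high, n$abundances)
})

test_that("MaxRank preconditions are enforced", {
  r <- rad(c(3, 3))
  expect_error(maxrank_sample_once(r, 3), "exceeds sample richness")
  expect_error(maxrank_sample_once(r, 1), "below 2")
  expect_error(maxrank_normalize(r, 2, n_reps = 0), "n_reps")
})

test_that("subsamples contain exactly R ranks, sorted, bounded by the pool", {
  set.seed(11)
  for (i in 1:20) {
    counts <- sort(rpois(30, 20) + 1, decreasing = TRUE)
    r <- rad(counts)
    R <- sample(2:(r$richness - 1), 1)
    v <- maxrank_sample_once(r, R)
    expect_length(v, R)
    expect_true(all(v >= 1))
    expect_true(all(diff(v) <= 0))
    expect_lte(sum(v), r$n_individuals)
  }
})

test_that("subsample mean matches the exhaustive draw-order enumeration", {
  # pools of <= 8 individuals; exact expectation by brute-force enumeration
  cases <- list(
    list(counts = c(2, 1, 1), R = 2),
    list(counts = c(3, 2, 1), R = 2),
    list(counts = c(4, 2, 2), R = 2),
    list(counts = c(2, 2, 1, 1), R = 3)
  )
  for (cs in cases) {
    exact <- enumerate_maxrank_mean(cs$counts, cs$R)
    mc <- mc_maxrank_mean(rad(cs$counts), cs$R, n_reps = 10000, seed = 99)
    expect_true(all(abs(mc$mean - exact) <= 3 * mc$se + 1e-12),
                info = paste("counts", paste(cs$counts, collapse = ",")))
    # maxrank_normalize averages the same quantity
    n <- maxrank_normalize(rad(cs$counts), cs$R, n_reps = 10000, seed = 5)
    expect_true(all(abs(n$abundances - exact) <= 3 * mc$se + 1e-12))
  }
})

test_that("NRADs conserve mass, ordering, and CI containment", {
  set.seed(21)
  for (i in 1:15) {
    counts <- rpois(sample(10:200, 1), sample(3:50, 1)) + 1
    r <- rad(counts)
    R <- sample(2:r$richness, 1)
    n <- maxrank_normalize(r, R, n_reps = 25, seed = i)
    expect_equal(sum(n$abundances), 1, tolerance = 1e-9)
    expect_true(all(diff(n$abundances) <= 0))
    expect_true(all(n$ci_low <= n$abundances + 1e-12))
    expect_true(all(n$ci_high >= n$abundances - 1e-12))
  }
})

test_that("normalization is reproducible from the seed", {
  r <- rad(rpois(100, 10) + 1)
  a <- maxrank_normalize(r, 40, n_reps = 20, seed = 123)
  b <- maxrank_normalize(r, 40, n_reps = 20, seed = 123)
  expect_identical(a$abundances, b$abundances)
  expect_identical(a$ci_low, b$ci_low)
  set_a <- maxrank_normalize_set(list(r, rad(rpois(80, 8) + 1)), R = 40,
                                 n_reps = 10, seed = 7)
  set_b <- maxrank_normalize_set(list(r, rad(rpois(80, 8) + 1)), R = 40,
                                 n_reps = 10, seed = 7)
  expect_identical(lapply(set_a, `[[`, "abundances"),
                   lapply(set_b, `[[`, "abundances"))
})

test_that("symmetric RADs normalize to the uniform NRAD", {
  n <- maxrank_normalize(rad(c(10, 10)), 2, n_reps = 50, seed = 3)
  expect_equal(n$abundances, c(0.5, 0.5))
})

test_that("choose_max_R returns the minimum richness of the set", {
  rads <- list(rad(rep(1, 7)), rad(rep(2, 3)), rad(rep(1, 12)))
  expect_identical(choose_max_R(rads), 3L)
  expect_identical(choose_max_R(list(rad(rep(1, 7)))), 7L)
  expect_error(choose_max_R(list()), "empty")
})

test_that("cutoff normalization truncates and renormalizes", {
  r <- rad(c(4, 3, 1))
  expect_equal(cutoff_normalize(r, 2)$abundances, c(4 / 7, 3 / 7))
  expect_equal(cutoff_normalize(r, 3)$abundances, c(0.5, 0.375, 0.125))
  expect_equal(cutoff_normalize(rad(c(1, 1, 1, 1)), 2)$abundances,
               c(0.5, 0.5))
  expect_error(cutoff_normalize(r, 4), "exceeds sample richness")
})

test_that("down-sampling hits the target richness exactly", {
  r <- rad(c(4, 3, 1))
  expect_identical(downsample_individuals(r, 3, seed = 1)$counts, r$counts)

  big <- generate_community(
    community_spec("lognormal", richness = 2000, depth = 5e4, sdlog = 1,
                   seed = 42)
  )
  target <- floor(big$richness / 10)
  d <- downsample_individuals(big, target, seed = 2)
  expect_identical(d$richness, as.integer(target))
  expect_lte(d$n_individuals, big$n_individuals)
  expect_error(downsample_individuals(r, 5), "exceeds sample richness")
})
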