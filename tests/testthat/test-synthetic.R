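test_that("community specs validate their parameters", {
  expect_error(community_spec("geometric", richness = 10, depth = 5),
               "depth")
  expect_error(community_spec("geometric", richness = 10, depth = 100,
                              p = 1.5), "p must be")
  expect_error(community_spec("zipf", richness = 10, depth = 100))
})

test_that("uniform communities sample to near-uniform abundances", {
  spec <- community_spec("uniform", richness = 10, depth = 1e6, seed = 1)
  r <- generate_community(spec)
  a <- relative_abundances(r)
  se <- sqrt(0.1 * 0.9 / 1e6)
  expect_identical(r$richness, 10L)
  expect_true(all(abs(a - 0.1) <= 4 * se))
})

test_that("broken-stick communities reproduce the reference NRAD", {
  spec <- community_spec("broken_stick", richness = 35, depth = 1e6,
                         seed = 2)
  r <- generate_community(spec)
  n <- maxrank_normalize(r, 35, n_reps = 1, seed = 3)
  ref <- broken_stick_nrad(35)$abundances
  se <- sqrt(ref * (1 - ref) / 1e6)
  expect_true(all(abs(n$abundances - ref) <= 4 * se + 1e-9))
})

test_that("generated RADs satisfy RAD invariants and are seed-reproducible", {
  for (fam in c("geometric", "lognormal", "broken_stick", "uniform")) {
    spec <- community_spec(fam, richness = 200, depth = 1e4, p = 0.01,
                           sdlog = 1.5, seed = 9, label = fam)
    r1 <- generate_community(spec)
    r2 <- generate_community(spec)
    expect_identical(r1$counts, r2$counts)
    expect_true(all(r1$counts >= 1))
    expect_true(all(diff(r1$counts) <= 0))
    expect_equal(sum(r1$counts), r1$n_individuals)
  }
})

test_that("entropy-age datasets follow the curve and its boundaries", {
  d0 <- generate_entropy_age_dataset(3.4, 5.8, 0.7, n = 50, noise_sd = 0,
                                     seed = 4)
  expect_equal(d0$H, entropy_age_curve(d0$age, 3.4, 5.8, 0.7))
  expect_true(all(d0$age >= 0.03 & d0$age <= 80))

  d <- generate_entropy_age_dataset(3.41, 5.82, 0.69, n = 181,
                                    noise_sd = 0.4, seed = 5)
  fit <- fit_entropy_age_model(d$H, d$age)
  expect_lt(abs(fit$lambda - 0.69), 4 * fit$ci_half_widths["lambda"])
  expect_lt(abs(fit$Hmax - 5.82), 4 * fit$ci_half_widths["Hmax"])

  expect_error(generate_entropy_age_dataset(5, 3, 0.7, 10), "Hmax > H0")
})

test_that("labeled NRAD sets plant signal only in the configured band", {
  s <- generate_labeled_nrad_set(5, R = 250, seed = 11)
  expect_length(s$nrads, 10)
  expect_identical(sort(unique(s$labels)), c("A", "B"))
  for (n in s$nrads) {
    expect_equal(sum(n$abundances), 1, tolerance = 1e-9)
    expect_true(all(diff(n$abundances) <= 0))
    expect_identical(n$R, 250L)
  }
  # class templates differ inside the band, match in the head
  ta <- radnorm:::shape_template(nrad_shape(bump = 0), 250)
  tb <- radnorm:::shape_template(nrad_shape(bump = 0.45), 250)
  ratio <- tb / ta
  expect_lt(diff(range(ratio[1:50])), 1e-12)  # constant ratio off-band
  expect_gt(max(ratio[100:160]) / ratio[1], 1.5)  # e^bump boost in-band

  expect_warning(
    generate_labeled_nrad_set(2, class_shapes = list(nrad_shape(),
                                                     nrad_shape()),
                              R = 50, seed = 1),
    "identical class shapes"
  )
  expect_error(generate_labeled_nrad_set(1, R = 50), "at least 2")
})
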