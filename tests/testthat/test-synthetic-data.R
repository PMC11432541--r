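# Generators: binding profiles, toy contact maps, ellipsoid clouds and
# baseline chains.

test_that("binding profiles honour their parameters over many seeds", {
  # homopolymer corner case
  homo <- make_binding_profile(50, 1, n_domains = 1, overlap_prob = 0,
                               inert_frac = 0, seed = 1)
  expect_true(all(vapply(homo$bead_types, identical, TRUE, "A")))

  # paper-scale preset: 10 types, all present
  big <- make_binding_profile(800, 10, n_domains = 25,
                              domain_length = 32, seed = 2)
  expect_equal(length(big$type_catalog), 10)
  expect_setequal(unique(unlist(big$bead_types)), big$type_catalog)

  # coverage statistics track the requested fractions across seeds
  cov <- t(vapply(1:20, function(s) {
    profile_coverage(make_binding_profile(
      200, 4, n_domains = 8, domain_length = 25, overlap_prob = 0.3,
      inert_frac = 0.1, seed = s))
  }, c(inert_frac = 0, multi_frac = 0, mean_labels = 0)))
  expect_lt(abs(mean(cov[, "multi_frac"]) - 0.3), 0.05)
  expect_lt(abs(mean(cov[, "inert_frac"]) - 0.1), 0.03)

  # deterministic per seed
  expect_identical(
    make_binding_profile(100, 3, seed = 7)$bead_types,
    make_binding_profile(100, 3, seed = 7)$bead_types)
  expect_error(make_binding_profile(10, 2, n_domains = 8),
               "domains exceed chain")
})

test_that("toy contact maps combine TADs, decay, loops and noise", {
  m <- make_toy_contact_map(40, tad_boundaries = c(15, 28),
                            noise = 0)$matrix
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 1))
  expect_true(all(m >= 0 & m <= 1))
  # intra-TAD beats inter-TAD at matched separation
  expect_gt(m[2, 6], m[14, 18])

  # decay-only map is a pure function of |i-j|: degenerate under r'
  decay <- make_toy_contact_map(30)$matrix
  r <- distance_corrected_pearson(decay, decay)
  expect_true(is.na(r) && isTRUE(attr(r, "undefined")))

  # shared TAD structure survives independent noise
  a <- make_toy_contact_map(40, tad_boundaries = c(13, 26),
                            noise = 0.2, seed = 5)
  b <- make_toy_contact_map(40, tad_boundaries = c(13, 26),
                            noise = 0.2, seed = 6)
  expect_gt(distance_corrected_pearson(a, b), 0)

  # loop peaks rise above the background
  lp <- make_toy_contact_map(40, loops = data.frame(i = 5, j = 35,
                                                    height = 0.5))
  bg <- make_toy_contact_map(40)
  expect_gt(lp$matrix[5, 35], bg$matrix[5, 35])

  expect_error(make_toy_contact_map(20, tad_boundaries = c(25)),
               "inside")
})

test_that("ellipsoid clouds and baseline chains match their analytics", {
  ball <- sample_ellipsoid_cloud(2, 2, 2, 50000, seed = 9)
  expect_equal(radius_of_gyration(ball), sqrt(3 / 5) * 2,
               tolerance = 0.01)
  inside <- rowSums(sweep(ball$bead_coords, 2, c(2, 2, 2), "/")^2)
  expect_true(all(inside <= 1 + 1e-12))

  rod <- sample_baseline_chain(10, "rod")
  d <- distance_map(rod)$matrix
  expect_equal(d, abs(outer(0:9, 0:9, "-")))

  # ideal chain: mean squared end-to-end approaches N - 1
  e2 <- vapply(1:300, function(s) {
    x <- sample_baseline_chain(100, "ideal", seed = s)$bead_coords
    sum((x[100, ] - x[1, ])^2)
  }, numeric(1))
  expect_equal(mean(e2), 99, tolerance = 0.15)

  saw <- sample_baseline_chain(50, "saw", seed = 3)
  bonds <- sqrt(rowSums(diff(saw$bead_coords)^2))
  expect_true(all(bonds >= 0.9 & bonds <= 1.1))
})
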