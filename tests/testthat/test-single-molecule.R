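# Distance maps, heterogeneity statistics, shape tensors and the
# Mann-Whitney test, checked against closed forms and brute force.

test_that("distance maps are Euclidean and guard against wrapped input", {
  two <- distance_map(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(two$matrix, rbind(c(0, 3), c(3, 0)))

  coll <- distance_map(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(coll$matrix[1, 3], 2)

  cloud <- sample_ellipsoid_cloud(2, 2, 2, 25, seed = 1)
  d <- distance_map(cloud)$matrix
  expect_identical(d, t(d))
  expect_true(all(diag(d) == 0))
  # triangle inequality over all triples
  n <- nrow(d)
  for (i in 1:(n - 2))
    for (j in (i + 1):(n - 1))
      for (k in (j + 1):n)
        expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-12)

  wrapped <- conformation(rbind(c(0, 0, 0), c(9, 0, 0)), box_edge = 10)
  expect_error(distance_map(wrapped), "wrapped")
})

test_that("heterogeneity r' matches brute force and known ensembles", {
  # identical non-degenerate maps: every pairwise r' is 1, variance 0
  base <- distance_map(sample_baseline_chain(20, "ideal", seed = 3))
  het1 <- heterogeneity(list(base, base, base, base))
  expect_true(all(abs(het1$r_prime - 1) < 1e-10))
  expect_equal(het1$variance, 0, tolerance = 1e-12)

  # brute-force double loop on K = 6 maps
  maps <- lapply(1:6, function(s)
    distance_map(sample_baseline_chain(12, "ideal", seed = 40 + s)))
  het <- heterogeneity(maps)
  brute <- brute_heterogeneity(lapply(maps, `[[`, "matrix"))
  expect_equal(sort(het$r_prime), sort(brute), tolerance = 1e-12)
  expect_equal(het$mean, mean(brute), tolerance = 1e-12)

  # independent random coils decorrelate
  coils <- lapply(1:30, function(s)
    distance_map(sample_baseline_chain(40, "ideal", seed = 100 + s)))
  het0 <- heterogeneity(coils)
  expect_lt(abs(het0$mean), 0.05)
})

test_that("inertia tensor recovers ellipsoid semi-axes", {
  ball <- sample_ellipsoid_cloud(2, 2, 2, 1e5, seed = 11)
  sb <- inertia_shape(ball)
  expect_equal(unname(sb$semi_axes), rep(2, 3), tolerance = 0.02)

  ell <- sample_ellipsoid_cloud(4, 2, 1, 1e5, seed = 12)
  se <- inertia_shape(ell)
  expect_equal(unname(se$semi_axes), c(4, 2, 1), tolerance = 0.02)
  expect_equal(unname(se$axis_ratios["a_over_c"]), 4, tolerance = 0.05)

  line <- conformation(cbind(seq_len(50), 0, 0), box_edge = 100)
  sl <- inertia_shape(line)
  expect_true(sl$degenerate)
  expect_equal(unname(sl$semi_axes["c"]), 0, tolerance = 1e-6)
})

test_that("gyration tensor gives ellipticity, Rg and the inertia identity", {
  ball <- sample_ellipsoid_cloud(3, 3, 3, 1e5, seed = 13)
  gb <- gyration_shape(ball)
  expect_equal(gb$ellipticity, 1, tolerance = 0.02)

  two <- rbind(c(0, 0, 0), c(0, 0, 2))
  g2 <- gyration_shape(two)
  expect_equal(unname(g2$eigenvalues[2:3]), c(0, 0), tolerance = 1e-12)
  expect_equal(g2$ellipticity, 0)

  # Rg^2 = sum of eigenvalues, and Rg matches the direct formula
  cloud <- sample_ellipsoid_cloud(3, 2, 1, 500, seed = 14)
  g <- gyration_shape(cloud)
  expect_equal(g$rg^2, sum(g$eigenvalues), tolerance = 1e-10)
  expect_equal(g$rg, radius_of_gyration(cloud), tolerance = 1e-12)

  # centred inertia eigenvalues obey I_k = N (tr T - lambda_k):
  # descending gyration eigenvalues pair with ascending inertia moments
  ish <- inertia_shape(cloud)
  n <- nrow(cloud$bead_coords)
  lam_desc <- unname(g$eigenvalues)
  expected_moments <- n * (sum(lam_desc) - lam_desc)
  expect_equal(unname(ish$moments), expected_moments, tolerance = 1e-8)
})

test_that("shape descriptors are invariant under rigid motions", {
  cloud <- sample_ellipsoid_cloud(3, 2, 1, 400, seed = 15)
  d0 <- shape_descriptors(cloud)
  withr::local_seed(16)
  for (k in 1:3) {
    qr_d <- qr(matrix(rnorm(9), 3, 3))
    rot <- qr.Q(qr_d)
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
    moved <- conformation(
      sweep(cloud$bead_coords %*% rot, 2, c(5, -3, 2), "+"),
      box_edge = cloud$box_edge)
    d1 <- shape_descriptors(moved)
    expect_equal(d1[c("a", "b", "c", "ellipticity", "rg")],
                 d0[c("a", "b", "c", "ellipticity", "rg")],
                 tolerance = 1e-8)
  }
})

test_that("molecule volumes follow the ellipsoid formulas", {
  unit <- sample_ellipsoid_cloud(1, 1, 1, 2000, seed = 17)
  v <- molecule_volumes(unit)
  # V_abc for a true unit ball approaches 4 pi / 3
  expect_equal(unname(v["volume_abc"]), 4 * pi / 3, tolerance = 0.15)

  # V_rg at the reported plateau Rg: (4/3) pi 6.4^3
  g <- list(rg = 6.4, volume_rg = 4 / 3 * pi * 6.4^3)
  class(g) <- "sbs_gyration"
  expect_equal(unname(molecule_volumes(g)["volume_rg"]),
               1098.066, tolerance = 1e-3)

  line <- conformation(cbind(seq_len(30), 0, 0), box_edge = 100)
  vl <- molecule_volumes(line)
  expect_equal(unname(vl["volume_abc"]), 0, tolerance = 1e-6)
})

test_that("ensemble shape statistics aggregate and exclude degenerates", {
  sphere <- sample_ellipsoid_cloud(2, 2, 2, 5000, seed = 18)
  st <- ensemble_shape_stats(list(sphere, sphere, sphere))
  expect_equal(unname(st$means["a_over_c"]), 1, tolerance = 0.05)
  expect_equal(unname(st$means["b_over_c"]), 1, tolerance = 0.05)
  expect_equal(unname(st$variances["ellipticity"]), 0,
               tolerance = 1e-12)

  prolate <- lapply(1:5, function(s)
    sample_ellipsoid_cloud(2, 1, 1, 20000, seed = 18 + s))
  stp <- ensemble_shape_stats(prolate)
  expect_equal(unname(stp$means["a_over_c"]), 2, tolerance = 0.1)
  expect_equal(unname(stp$means["b_over_c"]), 1, tolerance = 0.1)

  mixed <- c(prolate[1:2], list(sphere))
  stm <- ensemble_shape_stats(mixed)
  expect_gt(unname(stm$variances["a_over_c"]), 0)

  line <- conformation(cbind(seq_len(30), 0, 0), box_edge = 100)
  std <- ensemble_shape_stats(list(sphere, sphere, line))
  expect_equal(std$n_excluded, 1)
})

test_that("Mann-Whitney matches enumeration, identities and wilcox.test", {
  # fully tied case
  expect_warning(m1 <- mann_whitney(c(2, 2), c(2, 2)), "tied")
  expect_equal(m1$p_value, 1)

  # tied-but-informative case from exact enumeration of arrangements
  m2 <- mann_whitney(c(1, 2), c(1, 2))
  expect_equal(m2$p_value, 1.0)

  # full separation, n = m = 3: U = 9, exact two-sided p = 2/20
  m3 <- mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(m3$U, 9)
  expect_equal(m3$p_value, 0.1)

  # antisymmetry U(x,y) + U(y,x) = n m, with ties present
  withr::local_seed(19)
  x <- sample(1:5, 7, replace = TRUE)
  y <- sample(1:5, 9, replace = TRUE)
  expect_equal(mann_whitney(x, y)$U + mann_whitney(y, x)$U, 63)

  # agreement with stats::wilcox.test (exact, no ties)
  x2 <- c(0.3, 1.2, 2.8, 3.1, 4.4, 5.9, 6.2, 7.7)
  y2 <- c(0.9, 1.8, 2.2, 3.9, 5.1, 5.5, 8.4, 9.0)
  ours <- mann_whitney(x2, y2)
  ref <- stats::wilcox.test(x2, y2, exact = TRUE, correct = FALSE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)

  # exact and normal-approximation p agree at n = m = 15
  withr::local_seed(20)
  x3 <- rnorm(15)
  y3 <- rnorm(15, 0.4)
  exact_p <- mann_whitney(x3, y3)$p_value
  approx_p <- sbsfold:::mw_normal_p(
    x3, y3, mann_whitney(x3, y3)$U)
  expect_lt(abs(exact_p - approx_p), 0.01)
})
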