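# MD engine: initial states, potentials/forces, integrator thermodynamics
# and collapse detection.

test_that("SAW initial states respect bonds, excluded volume and seeds", {
  params <- simulation_params(box_edge = 10)
  c2 <- init_saw(2, params, seed = 1)
  expect_equal(sqrt(sum(diff(c2$bead_coords)^2)), 1, tolerance = 0.06)

  # excluded volume and bond-length window across seeds
  p <- simulation_params(box_edge = 12)
  min_image_dist <- function(x, L) {
    n <- nrow(x)
    dd <- x[rep(1:n, each = n), ] - x[rep(1:n, times = n), ]
    dd <- dd - L * round(dd / L)
    matrix(sqrt(rowSums(dd^2)), n, n)
  }
  for (s in 1:20) {
    conf <- init_saw(60, p, seed = s)
    x <- conf$bead_coords
    bonds <- sqrt(rowSums(diff(x)^2))
    expect_true(all(bonds >= 0.9 & bonds <= 1.1))
    r <- min_image_dist(x, 12)
    r[abs(row(r) - col(r)) <= 1] <- Inf  # self and bonded pairs
    expect_gte(min(r), 0.9)
  }
  expect_identical(init_saw(60, p, seed = 7)$bead_coords,
                   init_saw(60, p, seed = 7)$bead_coords)
  expect_false(identical(init_saw(60, p, seed = 7)$bead_coords,
                         init_saw(60, p, seed = 8)$bead_coords))
})

test_that("SAW ensembles show the self-avoiding end-to-end exponent", {
  sizes <- c(40, 80, 160, 320)
  reps <- 30
  mean_e2e2 <- vapply(sizes, function(n) {
    p <- simulation_params(box_edge = max(30, 4 * sqrt(n)))
    e2 <- vapply(seq_len(reps), function(s) {
      x <- init_saw(n, p, seed = 1000 * n + s)$bead_coords
      sum((x[n, ] - x[1, ])^2)
    }, numeric(1))
    mean(e2)
  }, numeric(1))
  fit <- stats::lm(log(mean_e2e2) ~ log(sizes))
  nu <- unname(coef(fit)[2]) / 2
  expect_gt(nu, 0.588 - 0.05)
  expect_lt(nu, 0.588 + 0.05)
})

test_that("binder placement honours counts, seeds and minimum separation", {
  spec <- homopolymer_spec(20)
  params <- simulation_params(box_edge = 50)
  conf <- init_saw(spec, params, seed = 3)

  # zero binders leaves the conformation untouched
  b0 <- binder_ensemble("A", affinity = 5, count = 0)
  expect_identical(place_binders(conf, b0, params)$binder_coords, NULL)

  # the derived count for c = 0.1 in the 50-sigma box is placed in full
  b <- binder_ensemble("A", affinity = 5, volume_fraction = 0.1)
  filled <- place_binders(conf, b, params, seed = 4)
  expect_equal(nrow(filled$binder_coords), 23873)

  # same counts, different coordinates under a different seed
  filled2 <- place_binders(conf, b, params, seed = 5)
  expect_equal(nrow(filled2$binder_coords), 23873)
  expect_false(identical(filled$binder_coords, filled2$binder_coords))

  # spot-check separations on a small placement
  bs <- binder_ensemble("A", affinity = 5, count = 200)
  ps <- simulation_params(box_edge = 12)
  confs <- place_binders(init_saw(spec, ps, seed = 6), bs, ps, seed = 7)
  all_xyz <- rbind(confs$bead_coords, confs$binder_coords)
  n <- nrow(all_xyz)
  dd <- all_xyz[rep(1:n, each = n), ] - all_xyz[rep(1:n, times = n), ]
  dd <- dd - 12 * round(dd / 12)
  r <- matrix(sqrt(rowSums(dd^2)), n, n)
  diag(r) <- Inf
  # bonded bead pairs may be below 0.9; exclude them
  for (i in seq_len(19)) r[i, i + 1] <- r[i + 1, i] <- Inf
  expect_gte(min(r), 0.9)
})

test_that("potential terms match their closed forms and cut-offs", {
  spec <- polymer_spec(list("A", "A"), type_catalog = "A")
  params <- simulation_params(box_edge = 20)
  binders <- binder_ensemble("A", affinity = 5, count = 1)

  # non-cognate pair exactly at the WCA cut-off: zero energy and force
  spec_ab <- polymer_spec(list("A", "A"), type_catalog = c("A", "B"))
  binders_b <- binder_ensemble("B", affinity = 5, count = 1)
  conf_nc <- conformation(rbind(c(0, 0, 0), c(0, 1, 0)),
                          binder_coords = rbind(c(2^(1 / 6), 0, 0)),
                          binder_types = "B", box_edge = 20)
  e_nc <- system_energy(conf_nc, spec_ab, binders_b, params)
  # the bonded bead pair at r = 1 contributes WCA = 1 kT; the binder at
  # the WCA cut-off contributes nothing and feels no force
  expect_equal(e_nc$repulsive, 1, tolerance = 1e-12)
  expect_equal(e_nc$attractive, 0, tolerance = 1e-12)
  expect_equal(unname(e_nc$forces[3, ]), c(0, 0, 0), tolerance = 1e-9)

  # cognate bead-binder pair at the attraction cut-off: exactly zero
  conf_att <- conformation(rbind(c(0, 0, 0), c(0, 1, 0)),
                           binder_coords = rbind(c(1.5, 0, 0)),
                           binder_types = "A", box_edge = 20)
  e_att <- system_energy(conf_att, spec, binders, params)
  expect_equal(e_att$attractive, 0, tolerance = 1e-12)

  # bonded pair: FENE + WCA minimum near 0.97 sigma
  bond_energy <- function(r) {
    cf <- conformation(rbind(c(0, 0, 0), c(r, 0, 0)), box_edge = 20)
    system_energy(cf, spec, binders, params)$total
  }
  opt <- stats::optimize(bond_energy, c(0.8, 1.2))
  expect_equal(opt$minimum, 0.97, tolerance = 0.01)

  # energy breakdown additivity
  sys <- small_system(seed = 2)
  e <- system_energy(sys$conf, sys$spec, sys$binders, sys$params)
  expect_equal(e$total, e$fene + e$repulsive + e$attractive,
               tolerance = 1e-12)

  # a bond at or beyond R0 diverges with a pointed error
  conf_bad <- conformation(rbind(c(0, 0, 0), c(1.6, 0, 0)),
                           box_edge = 20)
  expect_error(system_energy(conf_bad, spec, binders, params),
               "FENE bond 1")
})

test_that("forces are exact gradients and neighbour lists match brute force", {
  for (s in 1:3) {
    sys <- small_system(seed = s)
    e <- system_energy(sys$conf, sys$spec, sys$binders, sys$params)
    g <- numeric_forces(sys)
    scale <- max(abs(g), 1)
    expect_lt(max(abs(e$forces - g)) / scale, 1e-4)

    e_cell <- system_energy(sys$conf, sys$spec, sys$binders, sys$params,
                            method = "cell")
    expect_equal(e_cell$total, e$total, tolerance = 1e-10)
    expect_equal(e_cell$forces, e$forces, tolerance = 1e-9)
  }
})

test_that("energies are invariant under lattice translations (minimum image)", {
  sys <- small_system(seed = 4)
  e0 <- system_energy(sys$conf, sys$spec, sys$binders, sys$params)
  L <- sys$params$box_edge
  for (shift in list(c(L, 0, 0), c(-L, 2 * L, 0), c(L, L, L))) {
    conf_t <- conformation(
      sweep(sys$conf$bead_coords, 2, shift, "+"),
      sweep(sys$conf$binder_coords, 2, shift, "+"),
      sys$conf$binder_types, L)
    e1 <- system_energy(conf_t, sys$spec, sys$binders, sys$params)
    expect_equal(e1$total, e0$total, tolerance = 1e-10)
  }
})

test_that("NVE integration conserves energy and Langevin recovers T", {
  spec <- homopolymer_spec(30)
  params <- simulation_params(box_edge = 12, friction = 0,
                              n_steps = 2000, seed = 11)
  binders <- binder_ensemble("A", affinity = 3, count = 60)
  conf <- place_binders(init_saw(spec, params, seed = 11), binders,
                        params, seed = 12)
  traj <- run_dynamics(conf, spec, binders, params, sample_every = 50,
                       store = "rg", seed = 13)
  etot <- traj$kinetic + traj$potential
  expect_lt(max(abs(etot - etot[1])) / abs(etot[1]), 5e-3)

  # equipartition at T = 1, friction 0.5: kinetic per dof within 3%
  params_t <- simulation_params(box_edge = 12, friction = 0.5,
                                n_steps = 4e4, seed = 21)
  traj_t <- run_dynamics(conf, spec, binders, params_t,
                         sample_every = 200, store = "rg", seed = 22)
  burn <- seq_len(length(traj_t$kinetic) %/% 4)
  t_est <- mean(traj_t$kinetic[-burn]) / (0.5 * traj_t$n_dof)
  expect_equal(t_est, 1, tolerance = 0.03)

  # FENE bound holds in every sampled frame
  params_f <- simulation_params(box_edge = 12, friction = 0.5,
                                n_steps = 5000, seed = 31)
  traj_f <- run_dynamics(conf, spec, binders, params_f,
                         sample_every = 100, store = "beads", seed = 32)
  for (fr in traj_f$frames) {
    bonds <- sqrt(rowSums(diff(fr)^2))
    expect_true(all(bonds < params_f$fene_r0))
  }
})

test_that("engine noise is standard normal", {
  x <- sbsfold:::cpp_normal_draws(2e6, 91)
  expect_equal(mean(x), 0, tolerance = 5e-3)
  expect_equal(var(x), 1, tolerance = 5e-3)
  expect_equal(mean(x^3), 0, tolerance = 2e-2)
  expect_equal(mean(x^4), 3, tolerance = 3e-2)
})

test_that("gyration radius matches closed forms", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(0, 0, 4))
  expect_equal(radius_of_gyration(two), 2)
  ball <- sample_ellipsoid_cloud(3, 3, 3, 1e5, seed = 5)
  expect_equal(radius_of_gyration(ball), sqrt(3 / 5) * 3,
               tolerance = 0.01)
})

test_that("collapse detection finds steps, ramps and flat series", {
  step_series <- c(rep(10, 49), rep(3, 151))
  cs <- detect_collapse(step_series)
  expect_equal(cs$drop_fraction, 0.7, tolerance = 1e-6)
  expect_equal(cs$collapse_index, 50, tolerance = 3)

  flat <- detect_collapse(rep(5, 60))
  expect_true(is.na(flat$collapse_index))

  # noiseless ramp 10 -> 2 over 101 samples: midpoint analytically at the
  # sample where the ramp equals (coil_mean + plateau_mean)/2
  ramp <- seq(10, 2, length.out = 101)
  coil <- mean(ramp[1:5])
  plateau <- mean(ramp[77:101])
  target <- (coil + plateau) / 2
  expected_idx <- which(ramp <= target)[1]
  cr <- detect_collapse(ramp)
  expect_equal(cr$collapse_index, expected_idx, tolerance = 2)

  expect_error(detect_collapse(rep(1, 10)), "at least 20")
})
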