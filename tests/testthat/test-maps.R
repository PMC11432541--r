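# Contact maps, binning, contact-probability curves and the three
# map-comparison statistics against brute-force oracles.

# helper local to this file: an empty frequency map with a resolution
new_map_for_test <- function(n, res) {
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  structure(list(n = n, matrix = m, threshold = NA_real_,
                 resolution_bp = res), class = "sbs_contact_map")
}

test_that("contact maps follow the strict-threshold definition", {
  rod <- sample_baseline_chain(8, "rod")
  cm <- contact_map(rod, threshold = 2)
  sep <- abs(row(cm$matrix) - col(cm$matrix))
  expect_true(all(cm$matrix[sep <= 1] == 1))
  expect_true(all(cm$matrix[sep >= 2] == 0))

  # symmetry for an arbitrary conformation
  cloud <- sample_ellipsoid_cloud(3, 2, 1, 30, seed = 2)
  m <- contact_map(cloud, threshold = 1.5)$matrix
  expect_identical(m, t(m))

  # threshold below the minimum pair distance leaves only the diagonal
  tiny <- contact_map(rod, threshold = 0.5)
  expect_equal(tiny$matrix, diag(8))
})

test_that("ensemble means and binning behave like block averages", {
  rod <- sample_baseline_chain(8, "rod")
  m1 <- contact_map(rod, threshold = 2)
  expect_equal(ensemble_mean(list(m1))$matrix, m1$matrix)
  expect_equal(ensemble_mean(list(m1, m1, m1))$matrix, m1$matrix)

  # map and its off-diagonal complement average to 0.5
  comp <- m1
  comp$matrix <- 1 - m1$matrix
  diag(comp$matrix) <- 1
  avg <- ensemble_mean(list(m1, comp))$matrix
  off <- abs(row(avg) - col(avg)) > 0
  expect_true(all(avg[off] == 0.5))

  # binning: factor 1 is the identity; constants stay constant
  expect_equal(bin_matrix(m1, 1)$matrix, m1$matrix)
  const <- matrix(0.3, 8, 8)
  expect_equal(bin_matrix(const, 2), matrix(0.3, 4, 4))

  # 4x4 checkerboard, factor 2: every block mean is 0.5
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  expect_equal(bin_matrix(cb, 2), matrix(0.5, 2, 2))
  expect_error(bin_matrix(cb, 3), "divide")

  # resolution bookkeeping: 800 beads at 2.5 kb binned by 10 -> 25 kb
  big <- new_map_for_test(800, 2500)
  binned <- bin_matrix(big, 10)
  expect_equal(binned$n, 80)
  expect_equal(binned$resolution_bp, 25000)
})

test_that("contact probability curves match hand-computed cases", {
  rod <- sample_baseline_chain(6, "rod")
  curve <- contact_probability(contact_map(rod, threshold = 2))
  expect_equal(curve$pc[curve$s == 1], 1)
  expect_true(all(curve$pc[curve$s >= 2] == 0))

  ones <- matrix(1, 5, 5)
  expect_true(all(contact_probability(ones)$pc == 1))

  # ideal-chain ensembles decay (weakly monotone within sampling error)
  maps <- lapply(1:40, function(s)
    contact_map(sample_baseline_chain(30, "ideal", seed = s),
                threshold = 2))
  pc <- contact_probability(ensemble_mean(maps))$pc
  smoothed <- stats::filter(pc, rep(1 / 5, 5), sides = 2)
  ok <- !is.na(smoothed)
  expect_true(all(diff(smoothed[ok]) < 0.05))
})

test_that("comparison statistics equal brute-force double loops", {
  A <- random_symmetric(10, 31)
  B <- random_symmetric(10, 32)
  expect_equal(pearson_map(A, B), brute_pearson(A, B),
               tolerance = 1e-12)
  expect_equal(spearman_map(A, B), brute_spearman(A, B),
               tolerance = 1e-12)
  expect_equal(distance_corrected_pearson(A, B), brute_r_prime(A, B),
               tolerance = 1e-12)

  # identities and sign flips
  expect_equal(pearson_map(A, A), 1, tolerance = 1e-12)
  expect_equal(pearson_map(A, -A + 2), -1, tolerance = 1e-12)
  expect_equal(spearman_map(A, exp(A)), 1, tolerance = 1e-12)
  expect_equal(distance_corrected_pearson(A, A), 1, tolerance = 1e-10)

  # symmetry in the arguments
  expect_equal(distance_corrected_pearson(A, B),
               distance_corrected_pearson(B, A), tolerance = 1e-12)

  # r' invariant under adding any pure function of |i-j|
  sep <- abs(row(A) - col(A))
  A_shift <- A + 0.7 * exp(-sep / 3)
  expect_equal(distance_corrected_pearson(A_shift, B),
               distance_corrected_pearson(A, B), tolerance = 1e-10)

  # simultaneous bin reordering leaves the statistics unchanged
  perm <- c(3, 1, 2, 4, 5, 6, 10, 9, 8, 7)
  expect_equal(pearson_map(A[perm, perm], B[perm, perm]),
               pearson_map(A, B), tolerance = 1e-12)
  expect_equal(spearman_map(A[perm, perm], B[perm, perm]),
               spearman_map(A, B), tolerance = 1e-12)
})

test_that("degenerate comparisons are flagged, not silently zero", {
  n <- 8
  sep <- abs(row(diag(n)) - col(diag(n)))
  toeplitz_a <- exp(-sep)
  toeplitz_b <- 1 / (1 + sep)
  r <- distance_corrected_pearson(toeplitz_a, toeplitz_b)
  expect_true(is.na(r))
  expect_true(isTRUE(attr(r, "undefined")))

  flat <- matrix(0.4, n, n)
  p <- pearson_map(flat, random_symmetric(n, 5))
  expect_true(is.na(p) && isTRUE(attr(p, "undefined")))
})

test_that("independent noise matrices decorrelate under all statistics", {
  set.seed(77)
  r_p <- replicate(200, {
    A <- random_symmetric(20, sample.int(1e6, 1))
    B <- random_symmetric(20, sample.int(1e6, 1))
    pearson_map(A, B)
  })
  expect_lt(abs(mean(r_p)), 0.05)
  r_s <- replicate(100, {
    A <- random_symmetric(20, sample.int(1e6, 1))
    B <- random_symmetric(20, sample.int(1e6, 1))
    spearman_map(A, B)
  })
  expect_lt(abs(mean(r_s)), 0.05)
})

test_that("dense matrix TSV input handles headers, masks and asymmetry", {
  f <- withr::local_tempfile(fileext = ".tsv")
  m <- random_symmetric(5, 9)
  writeLines("#resolution_bp=25000", f)
  suppressWarnings(write.table(m, f, append = TRUE, sep = "\t",
                               quote = FALSE, row.names = FALSE,
                               col.names = FALSE))
  cm <- read_contact_matrix(f)
  expect_equal(cm$matrix, m, tolerance = 1e-10)
  expect_equal(cm$resolution_bp, 25000)

  # asymmetric input is symmetrized with a warning
  f2 <- withr::local_tempfile(fileext = ".tsv")
  m2 <- m
  m2[1, 2] <- m2[1, 2] + 0.2
  write.table(m2, f2, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_warning(cm2 <- read_contact_matrix(f2), "symmetrized")
  expect_equal(cm2$matrix, (m2 + t(m2)) / 2, tolerance = 1e-10)

  # non-square input is rejected
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(m[1:3, ], f3, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(read_contact_matrix(f3), "square")

  # write -> read round trip
  f4 <- withr::local_tempfile(fileext = ".tsv")
  write_contact_matrix(cm, f4)
  expect_equal(read_contact_matrix(f4)$matrix, cm$matrix,
               tolerance = 1e-10)
})

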