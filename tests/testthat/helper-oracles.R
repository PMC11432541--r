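# Brute-force reference implementations (independent oracles) and small
# fixture builders shared across the test files.

# Pearson over upper-triangle off-diagonal entries, two explicit loops
brute_pearson <- function(A, B) {
  a <- c()
  b <- c()
  n <- nrow(A)
  for (i in seq_len(n - 1))
    for (j in seq.int(i + 1, n)) {
      a <- c(a, A[i, j])
      b <- c(b, B[i, j])
    }
  sa <- sqrt(sum((a - mean(a))^2))
  sb <- sqrt(sum((b - mean(b))^2))
  sum((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

# per-|i-j| class means subtracted, explicit loops
brute_residualize <- function(M) {
  n <- nrow(M)
  out <- M
  for (d in 0:(n - 1)) {
    vals <- c()
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (abs(i - j) == d) vals <- c(vals, M[i, j])
    mu <- mean(vals)
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (abs(i - j) == d) out[i, j] <- M[i, j] - mu
  }
  out
}

brute_r_prime <- function(A, B)
  brute_pearson(brute_residualize(A), brute_residualize(B))

brute_spearman <- function(A, B) {
  n <- nrow(A)
  a <- c()
  b <- c()
  for (i in seq_len(n - 1))
    for (j in seq.int(i + 1, n)) {
      a <- c(a, A[i, j])
      b <- c(b, B[i, j])
    }
  brute_cor_vec(rank(a), rank(b))
}

brute_cor_vec <- function(a, b)
  sum((a - mean(a)) * (b - mean(b))) /
    (sqrt(sum((a - mean(a))^2)) * sqrt(sum((b - mean(b))^2)))

# pairwise r' over K maps via an explicit double loop
brute_heterogeneity <- function(mats) {
  K <- length(mats)
  vals <- c()
  for (p in seq_len(K - 1))
    for (q in seq.int(p + 1, K))
      vals <- c(vals, brute_r_prime(mats[[p]], mats[[q]]))
  vals
}

random_symmetric <- function(n, seed) {
  withr::local_seed(seed)
  m <- matrix(runif(n * n), n, n)
  (m + t(m)) / 2
}

# a small mixed bead+binder system for force/energy checks
small_system <- function(seed = 1, n_beads = 8, n_binders = 6,
                         box = 12) {
  spec <- polymer_spec(
    rep(list("A", "B"), length.out = n_beads),
    type_catalog = c("A", "B"))
  params <- simulation_params(box_edge = box, seed = seed)
  binders <- binder_ensemble(c("A", "B"), affinity = c(3, 5),
                             count = c(ceiling(n_binders / 2),
                                       floor(n_binders / 2)))
  conf <- init_saw(spec, params, seed = seed)
  conf <- place_binders(conf, binders, params, seed = seed + 1)
  list(spec = spec, params = params, binders = binders, conf = conf)
}

# numerical gradient of the total potential energy wrt all coordinates
numeric_forces <- function(sys, h = 1e-6) {
  coords <- rbind(sys$conf$bead_coords, sys$conf$binder_coords)
  nb <- nrow(sys$conf$bead_coords)
  energy_at <- function(m) {
    cf <- conformation(m[seq_len(nb), , drop = FALSE],
                       m[-seq_len(nb), , drop = FALSE],
                       sys$conf$binder_types, sys$conf$box_edge)
    system_energy(cf, sys$spec, sys$binders, sys$params)$total
  }
  g <- matrix(0, nrow(coords), 3)
  for (i in seq_len(nrow(coords)))
    for (d in 1:3) {
      up <- coords
      dn <- coords
      up[i, d] <- up[i, d] + h
      dn[i, d] <- dn[i, d] - h
      g[i, d] <- -(energy_at(up) - energy_at(dn)) / (2 * h)
    }
  g
}
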