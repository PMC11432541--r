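# Per-conformation analytics: spatial distance maps, pairwise-r'
# heterogeneity, inertia- and gyration-tensor shape descriptors,
# ellipsoid volumes and the Mann-Whitney comparison.

#' Pairwise spatial distance map of a conformation
#'
#' Euclidean distances between all bead pairs, in sigma. Coordinates must
#' be unwrapped (molecules reassembled across periodic images); a bond
#' longer than half the box is taken as evidence of wrapped input.
#'
#' @param conf an `sbs_conformation` or N x 3 coordinate matrix.
#' @return an `sbs_distance_map` (list with `n` and `matrix`).
#' @export
distance_map <- function(conf) {
  box <- NULL
  if (inherits(conf, "sbs_conformation")) {
    box <- conf$box_edge
    coords <- conf$bead_coords
  } else coords <- as.matrix(conf)
  if (!is.null(box) && nrow(coords) > 1) {
    bonds <- sqrt(rowSums(diff(coords)^2))
    if (any(bonds > box / 2))
      stop("bond longer than box/2: coordinates look wrapped; ",
           "analyse unwrapped conformations")
  }
  m <- as.matrix(stats::dist(coords))
  dimnames(m) <- NULL
  structure(list(n = nrow(m), matrix = m), class = "sbs_distance_map")
}

#' @export
print.sbs_distance_map <- function(x, ...) {
  cat("SBS distance map: ", x$n, " x ", x$n, " (sigma)\n", sep = "")
  invisible(x)
}

#' Structural heterogeneity of an ensemble of distance maps
#'
#' The genomic-distance corrected Pearson correlation r' (see
#' [distance_corrected_pearson()]) is computed for every unordered pair
#' of single-molecule distance maps. A tight structural consensus gives
#' r' near 1 for all pairs; fully independent folds give a distribution
#' centred at zero.
#'
#' @param maps list of `sbs_distance_map`s (or matrices) of equal size,
#'   K >= 2.
#' @return list of class `sbs_heterogeneity`: `r_prime` (vector of
#'   K(K-1)/2 values for non-degenerate pairs), `mean`, `variance`,
#'   `n_maps`, `n_degenerate`.
#' @export
heterogeneity <- function(maps) {
  K <- length(maps)
  stopifnot(K >= 2)
  mats <- lapply(maps, function(m)
    if (inherits(m, "sbs_distance_map")) m$matrix else as.matrix(m))
  n <- nrow(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == n), TRUE)))
    stop("distance maps differ in shape")
  ut <- upper.tri(mats[[1]], diag = FALSE)
  resid <- vapply(mats, function(m) residualize_by_distance(m)[ut],
                  numeric(sum(ut)))
  sds <- apply(resid, 2, stats::sd)
  degenerate <- !is.finite(sds) | sds < 1e-12
  if (any(degenerate))
    message(sum(degenerate),
            " degenerate map(s) excluded from heterogeneity statistics")
  keep <- which(!degenerate)
  if (length(keep) < 2) stop("fewer than 2 non-degenerate maps")
  cm <- stats::cor(resid[, keep, drop = FALSE])
  vals <- cm[upper.tri(cm)]
  structure(list(r_prime = vals, mean = mean(vals),
                 variance = stats::var(vals), n_maps = K,
                 n_degenerate = sum(degenerate)),
            class = "sbs_heterogeneity")
}

#' @export
print.sbs_heterogeneity <- function(x, ...) {
  cat(sprintf(
    "heterogeneity over %d maps: %d pairwise r' values, mean %.3f, variance %.3f\n",
    x$n_maps, length(x$r_prime), x$mean, x$variance))
  if (x$n_degenerate)
    cat("  (", x$n_degenerate, " degenerate maps excluded)\n", sep = "")
  invisible(x)
}

# centred second moments shared by the two tensors
centred_coords <- function(conf) {
  coords <- if (inherits(conf, "sbs_conformation")) conf$bead_coords else
    as.matrix(conf)
  sweep(coords, 2, colMeans(coords))
}

#' Inertia-tensor shape descriptors
#'
#' The inertia tensor `I = sum_a m (r_a^2 Id - r_a r_a^T)` is computed
#' about the centre of mass (unit masses) and diagonalized. Its sorted
#' principal moments `I_a <= I_b <= I_c` are converted to the semi-axes
#' of the equivalent uniform triaxial ellipsoid:
#' `a^2 = (5/2N)(I_b + I_c - I_a)` (cyclically), so that the smallest
#' moment corresponds to the longest semi-axis and `a >= b >= c`.
#' Negative radicands (degenerate clouds) are clipped to zero and
#' flagged.
#'
#' @param conf an `sbs_conformation` or N x 3 matrix, N >= 4.
#' @return list of class `sbs_shape` with `moments` (I_a, I_b, I_c),
#'   `semi_axes` (a, b, c), `axis_ratios` (a/c, b/c), `volume_abc` and
#'   `degenerate` flag.
#' @export
inertia_shape <- function(conf) {
  x <- centred_coords(conf)
  n <- nrow(x)
  stopifnot(n >= 4)
  r2 <- rowSums(x^2)
  inertia <- diag(sum(r2), 3) - crossprod(x)
  moments <- sort(eigen(inertia, symmetric = TRUE, only.values = TRUE)
                  $values)
  a2 <- (5 / (2 * n)) * (moments[2] + moments[3] - moments[1])
  b2 <- (5 / (2 * n)) * (moments[1] + moments[3] - moments[2])
  c2 <- (5 / (2 * n)) * (moments[1] + moments[2] - moments[3])
  rad <- c(a2, b2, c2)
  degenerate <- any(rad < 1e-12 * max(abs(rad), 1))
  semi <- sqrt(pmax(rad, 0))
  structure(list(
    moments = stats::setNames(moments, c("I_a", "I_b", "I_c")),
    semi_axes = stats::setNames(semi, c("a", "b", "c")),
    axis_ratios = c(a_over_c = if (semi[3] > 0) semi[1] / semi[3] else
      NA_real_, b_over_c = if (semi[3] > 0) semi[2] / semi[3] else
        NA_real_),
    volume_abc = 4 / 3 * pi * prod(semi),
    degenerate = degenerate), class = "sbs_shape")
}

#' Gyration-tensor shape descriptors
#'
#' The gyration tensor `T = (1/N) sum_a (r_a - rbar)(r_a - rbar)^T` is
#' diagonalized; eigenvalues are sorted descending
#' `lambda1 >= lambda2 >= lambda3`. The ellipticity
#' `eps = 2 lambda3 / (lambda1 + lambda2)` equals 1 for spherical
#' clouds and tends to 0 for elongated ones, and
#' `Rg^2 = lambda1 + lambda2 + lambda3`.
#'
#' @param conf an `sbs_conformation` or N x 3 matrix, N >= 2.
#' @return list of class `sbs_gyration`: `eigenvalues`, `ellipticity`,
#'   `rg`, `volume_rg`.
#' @export
gyration_shape <- function(conf) {
  x <- centred_coords(conf)
  n <- nrow(x)
  stopifnot(n >= 2)
  gyr <- crossprod(x) / n
  lambda <- sort(eigen(gyr, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
  rg <- sqrt(sum(lambda))
  structure(list(
    eigenvalues = stats::setNames(lambda,
                                  c("lambda1", "lambda2", "lambda3")),
    ellipticity = 2 * lambda[3] / (lambda[1] + lambda[2]),
    rg = rg, volume_rg = 4 / 3 * pi * rg^3), class = "sbs_gyration")
}

#' Combined per-molecule shape descriptors
#'
#' Convenience wrapper returning both tensor analyses as one flat named
#' vector (used for descriptor tables).
#'
#' @inheritParams inertia_shape
#' @return named numeric vector: a, b, c, a_over_c, b_over_c, lambda1..3,
#'   ellipticity, rg, volume_abc, volume_rg, degenerate (0/1).
#' @export
shape_descriptors <- function(conf) {
  ish <- inertia_shape(conf)
  gsh <- gyration_shape(conf)
  c(ish$semi_axes, ish$axis_ratios, gsh$eigenvalues,
    ellipticity = gsh$ellipticity, rg = gsh$rg,
    volume_abc = ish$volume_abc, volume_rg = gsh$volume_rg,
    degenerate = as.numeric(ish$degenerate))
}

#' Ellipsoid volumes of a single molecule
#'
#' Two estimates: `V_abc = (4/3) pi a b c` from the inertia-tensor
#' semi-axes, and `V_rg = (4/3) pi Rg^3` from the gyration radius.
#'
#' @param shape an `sbs_shape`, `sbs_gyration`, or a conformation (both
#'   tensors are then computed).
#' @return named vector `c(volume_abc, volume_rg)` in sigma^3 (either
#'   entry NA when the corresponding tensor was not supplied).
#' @export
molecule_volumes <- function(shape) {
  if (inherits(shape, "sbs_shape"))
    return(c(volume_abc = shape$volume_abc, volume_rg = NA_real_))
  if (inherits(shape, "sbs_gyration"))
    return(c(volume_abc = NA_real_, volume_rg = shape$volume_rg))
  d <- shape_descriptors(shape)
  c(volume_abc = unname(d["volume_abc"]),
    volume_rg = unname(d["volume_rg"]))
}

#' Ensemble shape statistics
#'
#' Per-molecule descriptors for a list of conformations, aggregated into
#' a tidy table plus ensemble means and variances. Degenerate molecules
#' (collinear or coincident clouds) are excluded from the summary with
#' their count reported. Ensemble volumes are means of per-molecule
#' volumes, not volumes of mean descriptors.
#'
#' @param confs list of conformations (K >= 2).
#' @return list of class `sbs_shape_stats`: `per_molecule` (tibble),
#'   `means`, `variances`, `n_excluded`.
#' @export
ensemble_shape_stats <- function(confs) {
  stopifnot(length(confs) >= 2)
  per <- t(vapply(confs, shape_descriptors, shape_descriptors(confs[[1]])))
  per <- tibble::as_tibble(as.data.frame(per))
  per$molecule <- seq_len(nrow(per))
  keep <- per$degenerate == 0
  agg_cols <- c("a_over_c", "b_over_c", "ellipticity", "rg",
                "volume_abc", "volume_rg")
  means <- vapply(per[keep, agg_cols], mean, numeric(1))
  vars <- vapply(per[keep, agg_cols], stats::var, numeric(1))
  structure(list(per_molecule = per, means = means, variances = vars,
                 n_excluded = sum(!keep)),
            class = "sbs_shape_stats")
}

#' @export
print.sbs_shape_stats <- function(x, ...) {
  cat("ensemble shape statistics over",
      nrow(x$per_molecule) - x$n_excluded, "molecules")
  if (x$n_excluded) cat(" (", x$n_excluded, " degenerate excluded)",
                        sep = "")
  cat("\n")
  s <- rbind(mean = x$means, variance = x$variances)
  print(round(s, 4))
  invisible(x)
}

#' Write a per-molecule shape descriptor table
#'
#' One TSV row per conformation with semi-axes, axis ratios, gyration
#' eigenvalues, ellipticity, Rg, both volumes and the degeneracy flag.
#'
#' @param stats an `sbs_shape_stats`.
#' @param path output path.
#' @export
write_shapes_tsv <- function(stats, path) {
  write.table(as.data.frame(stats$per_molecule), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mann-Whitney U test
#'
#' `U = sum over pairs [x_i > y_j] + 0.5 [x_i == y_j]`. The two-sided
#' p-value is exact - computed from the full permutation distribution of
#' U given the pooled values (ties included) - whenever `n*m <= 400`;
#' larger samples use the normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param x,y numeric samples.
#' @return list of class `sbs_mann_whitney`: `U`, `p_value`, `method`.
#' @export
mann_whitney <- function(x, y) {
  n <- length(x)
  m <- length(y)
  stopifnot(n >= 1, m >= 1)
  U <- sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y),
                  numeric(1)))
  if (length(unique(c(x, y))) == 1) {
    warning("all values tied across both samples; p = 1")
    return(structure(list(U = U, p_value = 1, method = "degenerate"),
                     class = "sbs_mann_whitney"))
  }
  if (n * m <= 400) {
    p <- mw_exact_p(x, y, U)
    method <- "exact"
  } else {
    p <- mw_normal_p(x, y, U)
    method <- "normal approximation"
  }
  structure(list(U = U, p_value = p, method = method),
            class = "sbs_mann_whitney")
}

#' @export
print.sbs_mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, two-sided p = %g (%s)\n", x$U,
              x$p_value, x$method))
  invisible(x)
}

# Exact permutation distribution of U over all C(n+m, n) assignments of
# the pooled (possibly tied) values, by dynamic programming over the
# sorted pool. Using ranks, U = W - n(n+1)/2 with W the rank sum of x;
# 2*W is always integral, so the DP tracks 2W.
mw_exact_p <- function(x, y, U) {
  n <- length(x)
  m <- length(y)
  pool <- c(x, y)
  r2 <- as.integer(round(2 * rank(pool)))  # twice the mid-ranks
  maxs <- sum(sort(r2, decreasing = TRUE)[seq_len(n)])
  # dp[k+1, s+1] = number of ways to choose k values with 2W = s
  dp <- matrix(0, nrow = n + 1, ncol = maxs + 1)
  dp[1, 1] <- 1
  for (v in r2) {
    # iterate k downwards so each value is used at most once
    for (k in seq(n, 1)) {
      src <- dp[k, ]
      nz <- which(src != 0)
      if (length(nz)) {
        tgt <- nz + v
        ok <- tgt <= maxs + 1
        dp[k + 1, tgt[ok]] <- dp[k + 1, tgt[ok]] + src[nz[ok]]
      }
    }
  }
  counts <- dp[n + 1, ]
  total <- sum(counts)
  # observed 2W from U: W = U + n(n+1)/2
  w2_obs <- as.integer(round(2 * U + n * (n + 1)))
  support <- which(counts != 0)
  mu <- sum((support - 1) * counts[support]) / total
  dev_obs <- abs(w2_obs - mu)
  p <- sum(counts[support][abs((support - 1) - mu) >= dev_obs - 1e-9]) /
    total
  min(1, p)
}

mw_normal_p <- function(x, y, U) {
  n <- length(x)
  m <- length(y)
  mu <- n * m / 2
  pool <- c(x, y)
  tie_tab <- table(pool)
  Np <- n + m
  tie_term <- sum(tie_tab^3 - tie_tab) / (Np * (Np - 1))
  sigma2 <- n * m / 12 * (Np + 1 - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
}
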