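# Generators for synthetic study inputs: SBS binding profiles with
# overlapping combinatorial domains, toy TAD contact maps, and analytic
# point-cloud / chain fixtures used as oracles.

#' Generate a synthetic SBS binding profile
#'
#' Emulates the statistical structure of inferred chromatin binding
#' profiles: contiguous binding-site domains tile the chain, additional
#' overlay domains create beads carrying several types (overlapping,
#' combinatorial organisation), and a fraction of beads is left inert.
#' Domain lengths are geometric with the requested mean. Every type is
#' guaranteed to occur at least once and generation is deterministic per
#' seed.
#'
#' @param n_beads chain length.
#' @param n_types number of binding-site types (<= 30).
#' @param n_domains number of base domains tiling the chain (>= n_types).
#' @param domain_length mean domain length in beads (default
#'   `n_beads / n_domains`).
#' @param overlap_prob target fraction of beads carrying more than one
#'   type.
#' @param inert_frac target fraction of unlabelled beads.
#' @param seed integer seed.
#' @inheritParams polymer_spec
#' @return an `sbs_polymer_spec`; the generator parameters are attached
#'   as the `"profile_params"` attribute.
#' @export
make_binding_profile <- function(n_beads, n_types, n_domains = 2 * n_types,
                                 domain_length = n_beads / n_domains,
                                 overlap_prob = 0.3, inert_frac = 0.1,
                                 seed = 1, chrom = "chrS", start_bp = 0,
                                 bp_per_bead = 2500) {
  stopifnot(n_types >= 1, n_domains >= n_types,
            overlap_prob >= 0, overlap_prob <= 1,
            inert_frac >= 0, inert_frac < 1,
            overlap_prob + inert_frac <= 1)
  if (n_domains * 2 > n_beads)
    stop("domains exceed chain: n_domains too large for n_beads")
  withr::local_seed(seed)
  types <- if (n_types <= 26) LETTERS[seq_len(n_types)] else
    paste0("T", seq_len(n_types))
  labels <- rep(list(character(0)), n_beads)

  # base layer: n_domains contiguous domains tiling the chain; the first
  # n_types domains carry distinct types so every type is used
  lens <- rgeom(n_domains, 1 / max(domain_length, 2)) + 1
  lens <- pmax(1, round(lens * n_beads / sum(lens)))
  bounds <- pmin(cumsum(lens), n_beads)
  bounds[n_domains] <- n_beads
  starts <- c(1, utils::head(bounds, -1) + 1)
  dom_types <- c(sample(types), sample(types, n_domains - n_types,
                                       replace = TRUE))
  for (d in seq_len(n_domains)) {
    if (starts[d] > bounds[d]) next
    for (i in seq.int(starts[d], bounds[d]))
      labels[[i]] <- dom_types[d]
  }

  # inert beads first, so the overlap target refers to the final profile
  inert <- sample.int(n_beads, round(inert_frac * n_beads))
  for (i in inert) labels[[i]] <- character(0)

  # overlay domains until the multi-label fraction reaches the target
  target_multi <- round(overlap_prob * n_beads)
  n_multi <- 0L
  guard <- 0L
  while (n_multi < target_multi && guard < 50L * n_domains) {
    guard <- guard + 1L
    len <- rgeom(1, 1 / max(domain_length, 2)) + 2
    st <- sample.int(max(1, n_beads - len + 1), 1)
    ty <- sample(types, 1)
    cand <- labels
    for (i in seq.int(st, min(n_beads, st + len - 1))) {
      if (i %in% inert) next
      cand[[i]] <- union(cand[[i]], ty)
    }
    new_multi <- sum(lengths(cand) > 1)
    # accept unless the overlay overshoots the target
    if (new_multi <= target_multi + 2L) {
      labels <- cand
      n_multi <- new_multi
    }
  }

  # re-seed any type lost to inert clearing
  missing <- setdiff(types, unique(unlist(labels)))
  for (ty in missing) {
    cand <- setdiff(seq_len(n_beads), inert)
    i <- sample(cand, 1)
    labels[[i]] <- union(labels[[i]], ty)
  }

  spec <- polymer_spec(labels, type_catalog = types, chrom = chrom,
                       start_bp = start_bp, bp_per_bead = bp_per_bead)
  attr(spec, "profile_params") <- list(
    n_beads = n_beads, n_types = n_types, n_domains = n_domains,
    domain_length = domain_length, overlap_prob = overlap_prob,
    inert_frac = inert_frac, seed = seed)
  spec
}

#' Summary statistics of a binding profile
#'
#' @param spec an `sbs_polymer_spec`.
#' @return named vector: fraction of inert beads, fraction of
#'   multi-label beads, mean labels per (labelled) bead.
#' @export
profile_coverage <- function(spec) {
  lens <- lengths(spec$bead_types)
  c(inert_frac = mean(lens == 0), multi_frac = mean(lens > 1),
    mean_labels = mean(lens[lens > 0]))
}

#' Toy contact map with TADs, distance decay and loops
#'
#' Block-constant TAD structure multiplied by a power-law distance decay
#' envelope `|i-j|^(-decay_exponent)`, optional loop peaks, and optional
#' multiplicative log-normal noise. Symmetric with unit diagonal - a
#' self-contained target for exercising the map-comparison statistics.
#'
#' @param n bins.
#' @param tad_boundaries sorted interior boundary indices (a boundary at
#'   b puts bins 1..b and b+1.. in different TADs).
#' @param intra_level,inter_level contact level inside / between TADs,
#'   both in [0, 1].
#' @param decay_exponent power-law exponent of the distance decay.
#' @param loops optional data frame with columns `i`, `j`, `height`
#'   (peak height added at (i, j), spread over a small Gaussian
#'   neighbourhood).
#' @param noise multiplicative log-normal noise sd (0 = none).
#' @param seed integer seed (used only when `noise > 0`).
#' @return an `sbs_contact_map`.
#' @export
make_toy_contact_map <- function(n, tad_boundaries = integer(0),
                                 intra_level = 0.8, inter_level = 0.2,
                                 decay_exponent = 1, loops = NULL,
                                 noise = 0, seed = 1) {
  stopifnot(n >= 2, intra_level >= 0, intra_level <= 1,
            inter_level >= 0, inter_level <= 1,
            !is.unsorted(tad_boundaries))
  if (length(tad_boundaries) &&
      (min(tad_boundaries) < 1 || max(tad_boundaries) >= n))
    stop("tad_boundaries must lie strictly inside 1..n-1")
  tad_of <- findInterval(seq_len(n) - 1, tad_boundaries)
  base <- ifelse(outer(tad_of, tad_of, "=="), intra_level, inter_level)
  sep <- abs(row(base) - col(base))
  envelope <- ifelse(sep == 0, 1, sep^(-decay_exponent))
  m <- base * envelope
  if (!is.null(loops)) {
    stopifnot(all(c("i", "j", "height") %in% names(loops)))
    idx <- seq_len(n)
    for (k in seq_len(nrow(loops))) {
      bump <- loops$height[k] *
        exp(-outer((idx - loops$i[k])^2, (idx - loops$j[k])^2, "+") / 4)
      m <- m + bump + t(bump)
    }
  }
  if (noise > 0) {
    withr::local_seed(seed)
    f <- matrix(exp(rnorm(n * n, 0, noise)), n, n)
    f[lower.tri(f)] <- t(f)[lower.tri(f)]
    m <- m * f
  }
  m <- pmin(pmax((m + t(m)) / 2, 0), 1)
  diag(m) <- 1
  new_contact_map(m)
}

#' Uniform sample inside a triaxial ellipsoid
#'
#' Rejection sampling from the bounding box; the analytic second moments
#' of the uniform solid ellipsoid make these clouds exact oracles for the
#' shape-descriptor routines.
#'
#' @param a,b,c semi-axes.
#' @param m number of points.
#' @param seed integer seed.
#' @return an `sbs_conformation` (no binders; nominal box 2 max(a,b,c)).
#' @export
sample_ellipsoid_cloud <- function(a, b, c, m, seed = 1) {
  stopifnot(a > 0, b > 0, c > 0, m >= 1)
  withr::local_seed(seed)
  got <- 0
  out <- matrix(NA_real_, m, 3)
  while (got < m) {
    k <- max(1000, 2 * (m - got))
    pts <- cbind(runif(k, -a, a), runif(k, -b, b), runif(k, -c, c))
    keep <- (pts[, 1] / a)^2 + (pts[, 2] / b)^2 + (pts[, 3] / c)^2 <= 1
    pts <- pts[keep, , drop = FALSE]
    take <- min(nrow(pts), m - got)
    if (take > 0) out[got + seq_len(take), ] <- pts[seq_len(take), ]
    got <- got + take
  }
  conformation(out, box_edge = 8 * max(a, b, c))
}

#' Baseline (null-model) chain conformations
#'
#' `rod`: collinear beads at unit spacing; `ideal`: cumulative Gaussian
#' steps of unit RMS length (random-walk chain); `saw`: a self-avoiding
#' walk grown in a large box via [init_saw()].
#'
#' @param n beads.
#' @param model "rod", "ideal" or "saw".
#' @param seed integer seed.
#' @return an `sbs_conformation`.
#' @export
sample_baseline_chain <- function(n, model = c("ideal", "rod", "saw"),
                                  seed = 1) {
  model <- match.arg(model)
  stopifnot(n >= 2)
  box <- max(4 * sqrt(n), n + 2)
  if (model == "rod") {
    coords <- cbind(seq_len(n) - 1, 0, 0)
    return(conformation(coords, box_edge = box))
  }
  if (model == "ideal") {
    withr::local_seed(seed)
    steps <- matrix(rnorm(3 * (n - 1), sd = 1 / sqrt(3)), n - 1, 3)
    coords <- rbind(0, apply(steps, 2, cumsum))
    return(conformation(coords, box_edge = box))
  }
  params <- simulation_params(box_edge = box)
  init_saw(n, params, seed = seed)
}
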