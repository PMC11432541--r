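# Langevin dynamics front-end: initial states, binder injection, energy
# breakdown, integration and gyration-radius tracking.

#' Self-avoiding-walk initial conformation
#'
#' Grows an open self-avoiding chain inside the periodic box: bond lengths
#' near 1 sigma and all non-bonded pairs at least 0.9 sigma apart
#' (minimum-image). Placement uses randomized growth with backtracking and
#' is reproducible per seed.
#'
#' @param spec a [polymer_spec()] or a bead count.
#' @param params a [simulation_params()].
#' @param seed integer seed (defaults to `params$seed`).
#' @return an `sbs_conformation` with bead coordinates only.
#' @export
init_saw <- function(spec, params, seed = params$seed) {
  n <- if (inherits(spec, "sbs_polymer_spec")) spec$n_beads else
    as.integer(spec)
  stopifnot(n >= 2)
  xyz <- cpp_init_saw(n, params$box_edge, as.integer(seed))
  conformation(bead_coords = xyz, box_edge = params$box_edge)
}

#' Construct a conformation object
#'
#' Holds unwrapped 3D coordinates of the chain beads and (optionally) of
#' the diffusing binders, with per-binder type labels.
#'
#' @param bead_coords N x 3 numeric matrix, sigma units, unwrapped.
#' @param binder_coords M x 3 matrix or NULL.
#' @param binder_types character vector of length M or NULL.
#' @param box_edge box edge in sigma.
#' @export
conformation <- function(bead_coords, binder_coords = NULL,
                         binder_types = NULL, box_edge) {
  bead_coords <- as.matrix(bead_coords)
  stopifnot(ncol(bead_coords) == 3, all(is.finite(bead_coords)))
  if (!is.null(binder_coords)) {
    binder_coords <- as.matrix(binder_coords)
    stopifnot(ncol(binder_coords) == 3,
              nrow(binder_coords) == length(binder_types))
  }
  structure(list(bead_coords = bead_coords, binder_coords = binder_coords,
                 binder_types = binder_types, box_edge = box_edge),
            class = "sbs_conformation")
}

#' @export
print.sbs_conformation <- function(x, ...) {
  cat("SBS conformation: ", nrow(x$bead_coords), " beads",
      if (!is.null(x$binder_coords))
        paste0(", ", nrow(x$binder_coords), " binders"),
      ", box ", x$box_edge, " sigma\n", sep = "")
  cat(sprintf("  bead Rg: %.3f sigma\n",
              radius_of_gyration(x$bead_coords)))
  invisible(x)
}

#' Inject binders into the simulation box
#'
#' Binders are placed uniformly at random, then rejected until every pair
#' of particles (binders and beads alike) is at least 0.9 sigma apart
#' under the minimum-image convention.
#'
#' @param conf an `sbs_conformation` (beads already placed).
#' @param binders a [binder_ensemble()]; counts are resolved from volume
#'   fractions if needed.
#' @param params a [simulation_params()].
#' @param seed integer seed.
#' @return the conformation with `binder_coords`/`binder_types` filled.
#' @export
place_binders <- function(conf, binders, params, seed = params$seed) {
  binders <- resolve_binder_counts(binders, params)
  m <- sum(binders$count)
  if (m == 0) return(conf)
  xyz <- cpp_place_binders(conf$bead_coords, as.integer(m),
                           params$box_edge, as.integer(seed))
  types <- rep(binders$type, times = binders$count)
  conformation(conf$bead_coords, xyz, types, params$box_edge)
}

# Assemble the particle-level encoding used by the C++ core:
# per-particle bitmask of binding-site labels and per-particle affinity.
system_encoding <- function(conf, spec, binders) {
  bead_mask <- type_masks(spec)
  n <- spec$n_beads
  stopifnot(nrow(conf$bead_coords) == n)
  if (is.null(conf$binder_coords)) {
    list(coords = conf$bead_coords, mask = bead_mask,
         eps = numeric(n), n_beads = n)
  } else {
    bm <- binder_type_masks(conf$binder_types, spec)
    if (anyNA(bm)) stop("binder type absent from polymer catalog")
    aff <- stats::setNames(binders$affinity, binders$type)
    list(coords = rbind(conf$bead_coords, conf$binder_coords),
         mask = c(bead_mask, bm),
         eps = c(numeric(n), as.numeric(aff[conf$binder_types])),
         n_beads = n)
  }
}

#' Potential-energy breakdown of a system
#'
#' FENE bond energy over adjacent bead pairs, WCA (purely repulsive
#' truncated-shifted Lennard-Jones, cut at 2^(1/6) sigma) over all other
#' pairs, and the cognate bead-binder attraction: a truncated-shifted
#' Lennard-Jones with depth parameter equal to the binder type's affinity,
#' cut at 1.5 sigma, acting only between a binder and beads whose label
#' set contains the binder's type. All separations use the minimum-image
#' convention.
#'
#' @inheritParams place_binders
#' @param method "all" (brute-force reference, default) or "cell"
#'   (production neighbour-list path; identical results).
#' @return list of class `sbs_energy` with `fene`, `repulsive`,
#'   `attractive`, `total` (kT) and the `forces` matrix.
#' @export
system_energy <- function(conf, spec, binders, params, method = "all") {
  enc <- system_encoding(conf, spec, binders)
  res <- cpp_energy_forces(enc$coords, enc$n_beads, enc$mask, enc$eps,
                           params$box_edge, params$fene_r0, params$fene_k,
                           params$r_rep, params$r_att, method,
                           params$skin)
  if (res$diverged)
    stop("FENE bond ", res$bad_bond,
         " at or beyond maximum extension R0; energy diverges")
  structure(res[c("fene", "repulsive", "attractive", "total", "forces")],
            class = "sbs_energy")
}

#' @export
print.sbs_energy <- function(x, ...) {
  cat(sprintf(
    "SBS energy (kT): FENE %.4f + repulsive %.4f + attractive %.4f = %.4f\n",
    x$fene, x$repulsive, x$attractive, x$total))
  invisible(x)
}

#' Run Langevin dynamics
#'
#' Velocity-Verlet integration of the underdamped Langevin equation at
#' friction `params$friction` and temperature `params$temperature`;
#' friction and Gaussian noise (per-component variance 2 zeta m kT / dt)
#' enter the force evaluation once per step. Positions are integrated
#' unwrapped; periodic wrapping is applied internally for the force
#' computation. With `friction = 0` the integrator is plain NVE.
#'
#' @inheritParams place_binders
#' @param n_steps number of steps (defaults to `params$n_steps`).
#' @param sample_every sampling stride for the gyration-radius track.
#' @param store "rg" (series only), "beads" (bead frames) or "all"
#'   (bead + binder frames).
#' @param seed integer seed.
#' @return an `sbs_trajectory`: sampled frames, step stamps, the bead
#'   gyration-radius series `rg`, kinetic/potential-energy series, and the
#'   final full conformation.
#' @export
run_dynamics <- function(conf, spec, binders, params,
                         n_steps = params$n_steps,
                         sample_every = max(1L, n_steps %/% 100L),
                         store = c("beads", "rg", "all"),
                         seed = params$seed) {
  store <- match.arg(store)
  binders <- resolve_binder_counts(binders, params)
  enc <- system_encoding(conf, spec, binders)
  store_code <- c(rg = 0L, beads = 1L, all = 2L)[[store]]
  res <- cpp_run_md(enc$coords, enc$n_beads, enc$mask, enc$eps,
                    params$box_edge, params$fene_r0, params$fene_k,
                    params$r_rep, params$r_att, params$dt,
                    params$friction, params$temperature,
                    as.integer(n_steps), as.integer(sample_every),
                    as.integer(seed), store_code, params$skin)
  if (res$aborted)
    warning("dynamics aborted at step ", res$abort_step,
            " (bond divergence or numeric overflow); ",
            "returning samples up to the last stable frame")
  n <- enc$n_beads
  final <- conformation(
    res$final[seq_len(n), , drop = FALSE],
    if (nrow(res$final) > n) res$final[-seq_len(n), , drop = FALSE],
    if (nrow(res$final) > n) conf$binder_types,
    params$box_edge)
  structure(
    list(frames = res$frames, steps = res$steps, rg = res$rg,
         kinetic = res$kinetic, potential = res$potential,
         n_dof = res$n_dof, final = final, sample_every = sample_every,
         n_beads = n, seed = as.integer(seed), aborted = res$aborted,
         store = store),
    class = "sbs_trajectory")
}

#' @export
print.sbs_trajectory <- function(x, ...) {
  cat("SBS trajectory: ", length(x$rg), " samples (every ",
      x$sample_every, " steps), ", x$n_beads, " beads\n", sep = "")
  if (length(x$rg))
    cat(sprintf("  Rg first/last: %.3f / %.3f sigma\n",
                x$rg[1], x$rg[length(x$rg)]))
  if (x$aborted) cat("  [aborted before completing all steps]\n")
  invisible(x)
}

#' Gyration radius of a coordinate cloud
#'
#' `sqrt(mean(|r_i - r_com|^2))` over rows.
#'
#' @param coords N x 3 matrix (or an `sbs_conformation`, beads only).
#' @return Rg in the coordinate units.
#' @export
radius_of_gyration <- function(coords) {
  if (inherits(coords, "sbs_conformation")) coords <- coords$bead_coords
  coords <- as.matrix(coords)
  if (nrow(coords) == 1) return(0)
  centred <- sweep(coords, 2, colMeans(coords))
  sqrt(sum(centred^2) / nrow(coords))
}

#' Gyration-radius time track of a trajectory
#'
#' @param traj an `sbs_trajectory`.
#' @return numeric vector of Rg samples (sigma), as recorded during the
#'   run (beads only).
#' @export
rg_series <- function(traj) {
  stopifnot(inherits(traj, "sbs_trajectory"))
  if (!length(traj$rg)) stop("empty trajectory")
  traj$rg
}

#' Detect the coil-globule collapse in an Rg track
#'
#' The coil level is the mean of the first 5% of samples, the plateau
#' level the mean of the last 25%. The collapse step is the first sample
#' at which the (moving-average smoothed) series crosses the midpoint
#' between the two levels; no collapse is reported when the relative drop
#' is below 10%.
#'
#' @param series numeric Rg series (or an `sbs_trajectory`).
#' @param smooth_window moving-average window (samples).
#' @return list of class `sbs_collapse`: `collapse_index` (sample index,
#'   NA when no collapse), `collapse_step` (step stamp if available),
#'   `coil_mean`, `plateau_mean`, `drop_fraction`.
#' @export
detect_collapse <- function(series, smooth_window = 5) {
  steps <- NULL
  if (inherits(series, "sbs_trajectory")) {
    steps <- series$steps
    series <- series$rg
  }
  n <- length(series)
  if (n < 20) stop("need at least 20 samples to detect a collapse")
  coil_mean <- mean(series[seq_len(max(1, floor(0.05 * n)))])
  plateau_mean <- mean(series[seq.int(n - floor(0.25 * n) + 1, n)])
  drop_fraction <- 1 - plateau_mean / coil_mean
  smoothed <- if (smooth_window > 1)
    stats::filter(series, rep(1 / smooth_window, smooth_window),
                  sides = 2)
  else series
  smoothed[is.na(smoothed)] <- series[is.na(smoothed)]
  out <- list(collapse_index = NA_integer_, collapse_step = NA_integer_,
              coil_mean = coil_mean, plateau_mean = plateau_mean,
              drop_fraction = drop_fraction)
  if (is.finite(drop_fraction) && drop_fraction >= 0.1) {
    midpoint <- (coil_mean + plateau_mean) / 2
    idx <- which(smoothed <= midpoint)[1]
    if (!is.na(idx)) {
      out$collapse_index <- idx
      out$collapse_step <- if (!is.null(steps)) steps[idx] else idx
    }
  }
  class(out) <- "sbs_collapse"
  out
}

#' @export
print.sbs_collapse <- function(x, ...) {
  if (is.na(x$collapse_index)) {
    cat(sprintf("no collapse detected (drop %.1f%%)\n",
                100 * x$drop_fraction))
  } else {
    cat(sprintf(
      "collapse at sample %d (step %s): coil %.3f -> plateau %.3f (drop %.1f%%)\n",
      x$collapse_index, format(x$collapse_step), x$coil_mean,
      x$plateau_mean, 100 * x$drop_fraction))
  }
  invisible(x)
}
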