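# Canonical study configurations: the desk-scale ensemble used throughout
# the tests and the full-scale preset mirroring the original study setup.

#' Desk-scale study preset
#'
#' A scaled-down heteropolymer ensemble that reproduces the phenomenology
#' of the full-size system on a single CPU: N = 200 beads carrying 4
#' binding-site types in overlapping domains (about 55% multi-label
#' beads, 10% inert), a 20 sigma periodic box, binders at total volume
#' fraction 0.01 (split equally across types) with affinity 5 kT - a
#' point inside the phase-separated (globular) region of the phase
#' diagram - integrated for 3e5 steps per replicate, 50 replicates.
#'
#' @param replicates number of independent collapses.
#' @param n_steps integration steps per replicate.
#' @param seed master seed (drives profile, placements and dynamics).
#' @return list with `spec`, `binders`, `params`, `replicates`,
#'   `n_steps`, `sample_every`, `seed`.
#' @export
desk_preset <- function(replicates = 50, n_steps = 3e5, seed = 1) {
  spec <- make_binding_profile(
    n_beads = 200, n_types = 4, n_domains = 8, domain_length = 25,
    overlap_prob = 0.55, inert_frac = 0.1, seed = 20)
  params <- simulation_params(box_edge = 20, n_steps = n_steps,
                              seed = seed)
  binders <- binder_ensemble(spec$type_catalog, affinity = 5,
                             volume_fraction = 0.01 /
                               length(spec$type_catalog))
  list(spec = spec, binders = binders, params = params,
       replicates = replicates, n_steps = n_steps,
       sample_every = max(1L, as.integer(n_steps %/% 100L)),
       seed = seed)
}

#' Full-scale study preset
#'
#' The original-size system: 800 beads over a 2 Mb locus with ten
#' binding-site types, a 50 sigma box, equilibration of 1e8 steps and up
#' to 300 independent replicates. Provided for completeness - running it
#' takes hours per replicate and is not exercised by the test suite.
#'
#' @inheritParams desk_preset
#' @export
paper_preset <- function(replicates = 300, n_steps = 1e8, seed = 1) {
  spec <- make_binding_profile(
    n_beads = 800, n_types = 10, n_domains = 25, domain_length = 32,
    overlap_prob = 0.55, inert_frac = 0.1, seed = 20)
  params <- simulation_params(box_edge = 50, n_steps = n_steps,
                              seed = seed)
  binders <- binder_ensemble(spec$type_catalog, affinity = 5,
                             volume_fraction = 0.01 /
                               length(spec$type_catalog))
  list(spec = spec, binders = binders, params = params,
       replicates = replicates, n_steps = n_steps,
       sample_every = max(1L, as.integer(n_steps %/% 1000L)),
       seed = seed)
}

#' Simulate an ensemble of independent collapses
#'
#' Runs `replicates` fully independent trajectories (fresh SAW, fresh
#' binder placement, fresh thermal noise per replicate; seeds derived
#' deterministically from the master seed) and returns the final
#' conformation plus collapse summary of each.
#'
#' @param preset a list as returned by [desk_preset()] (or a compatible
#'   hand-built list).
#' @param progress print one line per replicate.
#' @return list of class `sbs_ensemble`: `conformations` (final frames),
#'   `collapse` (per-replicate [detect_collapse()] results), `rg_tracks`.
#' @export
simulate_ensemble <- function(preset, progress = FALSE) {
  confs <- vector("list", preset$replicates)
  tracks <- vector("list", preset$replicates)
  collapse <- vector("list", preset$replicates)
  for (r in seq_len(preset$replicates)) {
    s <- derive_seed(preset$seed, 1L, r)
    conf <- init_saw(preset$spec, preset$params, seed = s)
    conf <- place_binders(conf, preset$binders, preset$params,
                          seed = s + 1L)
    traj <- run_dynamics(conf, preset$spec, preset$binders,
                         preset$params, n_steps = preset$n_steps,
                         sample_every = preset$sample_every,
                         store = "rg", seed = s + 2L)
    confs[[r]] <- traj$final
    tracks[[r]] <- traj$rg
    collapse[[r]] <- detect_collapse(traj)
    if (progress)
      message(sprintf("replicate %d/%d: Rg %.2f -> %.2f", r,
                      preset$replicates, traj$rg[1],
                      traj$rg[length(traj$rg)]))
  }
  structure(list(conformations = confs, collapse = collapse,
                 rg_tracks = tracks, preset = preset),
            class = "sbs_ensemble")
}

#' Phase-separated conformations of an ensemble
#'
#' Nucleation of the collapse is stochastic: within a finite run a
#' fraction of replicates may remain coils. Ensemble structure analyses
#' concern the phase-separated (globular) state, so this accessor keeps
#' the conformations whose Rg track shows a collapse (relative drop of at
#' least 10%) onto a globule-sized plateau. The plateau cut-off defaults
#' to 5 sigma for the desk-scale chain (a 200-bead melt-density globule
#' has Rg near 3.5-4 sigma, while coils sit above 7 sigma); pass a value
#' appropriate to the chain length for other presets.
#'
#' @param ensemble an `sbs_ensemble` from [simulate_ensemble()].
#' @param globule_rg_max plateau Rg cut-off (sigma) separating globules
#'   from coils.
#' @return list with `conformations` (the phase-separated subset),
#'   `index` (their replicate indices), `n_total`.
#' @export
phase_separated <- function(ensemble, globule_rg_max = 5) {
  plateau <- vapply(ensemble$collapse, `[[`, numeric(1), "plateau_mean")
  drop <- vapply(ensemble$collapse, `[[`, numeric(1), "drop_fraction")
  keep <- which(drop >= 0.1 & plateau < globule_rg_max)
  list(conformations = ensemble$conformations[keep], index = keep,
       n_total = length(ensemble$conformations))
}

#' @export
print.sbs_ensemble <- function(x, ...) {
  drops <- vapply(x$collapse, `[[`, numeric(1), "drop_fraction")
  cat("SBS ensemble:", length(x$conformations), "replicates\n")
  cat(sprintf("  collapsed (drop >= 10%%): %d; mean drop %.1f%%\n",
              sum(drops >= 0.1), 100 * mean(drops)))
  invisible(x)
}
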