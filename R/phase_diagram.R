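# Sweeps over binder concentration and affinity with collapse detection,
# and midpoint-crossing threshold estimation for the coil-globule
# transition.

#' Sweep the phase diagram
#'
#' Runs independent replicates at every grid point of (volume fraction c,
#' affinity E) and summarizes each with the plateau gyration radius from
#' [detect_collapse()]. Replicates receive deterministic per-(point,
#' replicate) seeds derived from the master seed, so the whole sweep is
#' reproducible. Failed replicates (aborted dynamics) are flagged and the
#' others kept.
#'
#' @param spec a [polymer_spec()]; the classic sweep subject is the
#'   homopolymer ([homopolymer_spec()]).
#' @param grid data frame with columns `c` (total binder volume
#'   fraction, split equally across the catalog types) and `E` (affinity,
#'   kT).
#' @param params a [simulation_params()].
#' @param replicates replicates per grid point.
#' @param seed master seed.
#' @param n_steps steps per replicate.
#' @param sample_every sampling stride.
#' @return tibble of class `sbs_sweep`: one row per (point, replicate)
#'   with `c`, `E`, `replicate`, `plateau_rg`, `coil_rg`,
#'   `collapse_step`, `drop_fraction`, `failed`.
#' @export
run_sweep <- function(spec, grid, params, replicates = 3,
                      seed = params$seed, n_steps = params$n_steps,
                      sample_every = max(1L, n_steps %/% 50L)) {
  stopifnot(nrow(grid) >= 1, replicates >= 1,
            all(c("c", "E") %in% names(grid)))
  types <- spec$type_catalog
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cval <- grid$c[g]
    eval_ <- grid$E[g]
    binders <- binder_ensemble(types, affinity = eval_,
                               volume_fraction = cval / length(types))
    for (r in seq_len(replicates)) {
      s <- derive_seed(seed, g, r)
      row <- tryCatch({
        conf <- init_saw(spec, params, seed = s)
        conf <- place_binders(conf, binders, params, seed = s + 1L)
        traj <- run_dynamics(conf, spec, binders, params,
                             n_steps = n_steps,
                             sample_every = sample_every, store = "rg",
                             seed = s + 2L)
        cs <- detect_collapse(traj)
        data.frame(c = cval, E = eval_, replicate = r,
                   plateau_rg = cs$plateau_mean, coil_rg = cs$coil_mean,
                   collapse_step = as.numeric(cs$collapse_step),
                   drop_fraction = cs$drop_fraction,
                   failed = traj$aborted)
      }, error = function(e) {
        data.frame(c = cval, E = eval_, replicate = r,
                   plateau_rg = NA_real_, coil_rg = NA_real_,
                   collapse_step = NA_real_, drop_fraction = NA_real_,
                   failed = TRUE)
      })
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  class(out) <- c("sbs_sweep", class(out))
  out
}

#' Summarize a sweep per grid point
#'
#' @param sweep an `sbs_sweep`.
#' @return tibble with per-(c, E) mean plateau Rg, its standard error,
#'   replicate count and failure count.
#' @export
summarize_sweep <- function(sweep) {
  ok <- sweep[!sweep$failed, ]
  agg <- stats::aggregate(plateau_rg ~ c + E, data = ok, FUN = mean)
  sem <- stats::aggregate(plateau_rg ~ c + E, data = ok,
                          FUN = function(v)
                            stats::sd(v) / sqrt(length(v)))
  nrep <- stats::aggregate(plateau_rg ~ c + E, data = ok, FUN = length)
  names(agg)[3] <- "plateau_rg_mean"
  agg$plateau_rg_se <- sem$plateau_rg
  agg$n <- nrep$plateau_rg
  tibble::as_tibble(agg)
}

#' Estimate the collapse threshold along a one-parameter curve
#'
#' Given plateau Rg as a function of a single control parameter
#' (concentration or affinity), the threshold is the parameter value at
#' which the monotone-interpolated curve crosses the midpoint between the
#' coil plateau (mean over the low-parameter side) and the globule
#' plateau (mean over the high-parameter side). Interpolation is linear
#' in log-parameter when all grid values are positive (so a step between
#' adjacent grid points yields their geometric mean), linear otherwise.
#'
#' @param param numeric grid (sorted ascending), length >= 4.
#' @param rg plateau Rg at each grid value.
#' @param edge number of points averaged on each side for the plateaus.
#' @return threshold parameter value.
#' @export
estimate_threshold <- function(param, rg, edge = 2) {
  stopifnot(length(param) == length(rg), length(param) >= 4,
            !is.unsorted(param))
  coil <- mean(rg[seq_len(edge)])
  glob <- mean(rg[seq.int(length(rg) - edge + 1, length(rg))])
  hi <- max(coil, glob)
  lo <- min(coil, glob)
  if (hi <= 0 || (hi - lo) / hi < 0.1)
    stop("curve shows no collapse (relative drop < 10%); no threshold")
  midpoint <- (coil + glob) / 2
  use_log <- all(param > 0)
  xs <- if (use_log) log(param) else param
  # first bracket where the curve crosses the midpoint
  below <- rg <= midpoint
  k <- which(below[-1] != below[-length(below)])[1]
  if (is.na(k)) stop("curve does not cross the plateau midpoint")
  x1 <- xs[k]
  x2 <- xs[k + 1]
  y1 <- rg[k]
  y2 <- rg[k + 1]
  xc <- if (y2 == y1) (x1 + x2) / 2 else
    x1 + (midpoint - y1) * (x2 - x1) / (y2 - y1)
  if (use_log) exp(xc) else xc
}

# deterministic per-(point, replicate) seeds below 2^31
derive_seed <- function(master, point, replicate) {
  as.integer((as.double(master) * 7919 + point * 104729 +
                replicate * 1299709) %% 2147483629)
}
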