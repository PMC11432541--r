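# Domain types for the SBS system: the polymer specification (which bead
# carries which binding-site types), the binder ensemble, and the
# simulation parameter set.

#' Construct a polymer specification
#'
#' A polymer spec records, for each bead of the coarse-grained chain, the
#' set of binding-site type labels it exposes. A bead may carry several
#' labels (overlapping binding domains) or none (inert bead). Genomic
#' bookkeeping is carried by a chromosome name, a start coordinate and the
#' genomic content per bead.
#'
#' @param bead_types list with one character vector of type labels per
#'   bead; `character(0)` marks an inert bead. A plain character vector of
#'   comma-separated labels is also accepted.
#' @param type_catalog ordered character vector of all distinct labels;
#'   defaults to the sorted union of the labels used.
#' @param chrom chromosome name used in genomic bookkeeping.
#' @param start_bp 0-based genomic start of bead 0.
#' @param bp_per_bead genomic content per bead in bp (default 2500 bp,
#'   i.e. a 2 Mb locus at 800 beads).
#' @return an object of class `sbs_polymer_spec`.
#' @examples
#' spec <- polymer_spec(list(c("A"), c("A", "B"), character(0), "B"))
#' spec$n_beads
#' @export
polymer_spec <- function(bead_types, type_catalog = NULL, chrom = "chrS",
                         start_bp = 0, bp_per_bead = 2500) {
  if (is.character(bead_types)) {
    bead_types <- lapply(strsplit(bead_types, ","), function(x) {
      x <- trimws(x)
      x[nzchar(x)]
    })
  }
  stopifnot(is.list(bead_types))
  bead_types <- lapply(bead_types, as.character)
  if (is.null(type_catalog)) {
    type_catalog <- sort(unique(unlist(bead_types)))
  }
  spec <- structure(
    list(n_beads = length(bead_types), bead_types = bead_types,
         type_catalog = as.character(type_catalog), chrom = chrom,
         start_bp = as.numeric(start_bp),
         bp_per_bead = as.numeric(bp_per_bead)),
    class = "sbs_polymer_spec")
  problems <- validate_polymer_spec(spec)
  if (length(problems)) stop(paste(problems, collapse = "; "))
  spec
}

#' Homopolymer specification
#'
#' All beads carry the same single binding-site type, the classic setting
#' of the coil-globule transition.
#'
#' @param n_beads chain length.
#' @param type the single type label.
#' @inheritParams polymer_spec
#' @export
homopolymer_spec <- function(n_beads, type = "A", chrom = "chrS",
                             start_bp = 0, bp_per_bead = 2500) {
  polymer_spec(rep(list(type), n_beads), type_catalog = type,
               chrom = chrom, start_bp = start_bp,
               bp_per_bead = bp_per_bead)
}

# character vector of invariant violations; empty when valid
validate_polymer_spec <- function(spec) {
  out <- character(0)
  if (spec$n_beads < 2) out <- c(out, "polymer must have at least 2 beads")
  if (anyDuplicated(spec$type_catalog))
    out <- c(out, "type catalog contains duplicate labels")
  if (spec$bp_per_bead <= 0) out <- c(out, "bp_per_bead must be positive")
  unknown <- setdiff(unique(unlist(spec$bead_types)), spec$type_catalog)
  if (length(unknown))
    out <- c(out, paste0("bead label(s) not in catalog: ",
                         paste(unknown, collapse = ", ")))
  out
}

#' @export
print.sbs_polymer_spec <- function(x, ...) {
  n_inert <- sum(lengths(x$bead_types) == 0)
  n_multi <- sum(lengths(x$bead_types) > 1)
  cat("SBS polymer spec: ", x$n_beads, " beads, ",
      length(x$type_catalog), " binding-site type(s)\n", sep = "")
  cat("  catalog: ", paste(x$type_catalog, collapse = ", "), "\n", sep = "")
  cat("  inert beads: ", n_inert, "; multi-label beads: ", n_multi, "\n",
      sep = "")
  cat("  anchor: ", x$chrom, ":", format(x$start_bp, scientific = FALSE),
      " @ ", x$bp_per_bead, " bp/bead\n", sep = "")
  invisible(x)
}

#' Define the binder ensemble
#'
#' One row per binder type: how many binders of that type diffuse in the
#' box (or, equivalently, their volume fraction) and the affinity of the
#' attractive interaction with cognate beads, in units of kT.
#'
#' Counts and volume fractions are mutually derivable given the box
#' volume; leave one of them `NA` and call [resolve_binder_counts()] (done
#' automatically by the simulation front-ends). The volume fraction of a
#' type with `count` binders in a box of edge L is
#' `(pi/6) * count / L^3` (sphere volume over box volume, diameter 1 sigma).
#'
#' @param types character vector of type labels.
#' @param affinity numeric vector (recycled) of affinities in kT.
#' @param count integer vector (recycled) of binder counts, or `NA`.
#' @param volume_fraction numeric vector (recycled), or `NA`.
#' @return an object of class `sbs_binders` (a data frame).
#' @export
binder_ensemble <- function(types, affinity, count = NA,
                            volume_fraction = NA) {
  types <- as.character(types)
  df <- data.frame(type = types,
                   affinity = rep_len(as.numeric(affinity), length(types)),
                   count = rep_len(as.numeric(count), length(types)),
                   volume_fraction = rep_len(as.numeric(volume_fraction),
                                             length(types)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$type)) stop("duplicate binder types")
  if (any(!is.na(df$count) & df$count < 0)) stop("negative binder count")
  if (any(df$affinity < 0)) stop("negative affinity")
  class(df) <- c("sbs_binders", "data.frame")
  df
}

#' Resolve binder counts and volume fractions
#'
#' Fills whichever of `count`/`volume_fraction` is missing, using
#' `count = round(c * L^3 / (pi/6))` and its inverse.
#'
#' @param binders an [binder_ensemble()] object.
#' @param params a [simulation_params()] object (supplies the box edge).
#' @return the binder ensemble with both columns filled.
#' @export
resolve_binder_counts <- function(binders, params) {
  L3 <- params$box_edge^3
  vol1 <- pi * params$sigma^3 / 6
  miss_count <- is.na(binders$count)
  binders$count[miss_count] <-
    round(binders$volume_fraction[miss_count] * L3 / vol1)
  binders$volume_fraction <- binders$count * vol1 / L3
  if (any(is.na(binders$count)))
    stop("binder ensemble needs count or volume_fraction per type")
  binders
}

#' Simulation parameter set
#'
#' Collects the Langevin/velocity-Verlet parameters and the interaction
#' constants of the SBS force field. Defaults follow standard
#' coarse-grained polymer practice: bead/binder diameter sigma = 1, mass
#' m = 1, temperature T = 1 (kT = 1), friction 0.5, FENE bonds with
#' maximum extension 1.6 sigma and spring constant 30 kT/sigma^2, WCA
#' excluded volume cut at 2^(1/6) sigma, cognate attraction cut at
#' 1.5 sigma, and a cubic periodic box of edge 50 sigma.
#'
#' @param box_edge cubic box edge, sigma units.
#' @param dt integration timestep, model time units.
#' @param friction Langevin friction coefficient (inverse time).
#' @param temperature dimensionless temperature (kB = 1).
#' @param n_steps default number of integration steps.
#' @param seed default integer seed.
#' @param sigma bead/binder diameter (model length unit).
#' @param mass bead/binder mass (model mass unit).
#' @param fene_r0 FENE maximum bond extension, sigma.
#' @param fene_k FENE spring constant, kT/sigma^2.
#' @param r_rep WCA repulsive cut-off, sigma.
#' @param r_att cognate attraction cut-off, sigma.
#' @param skin neighbour-list skin, sigma.
#' @return an object of class `sbs_params`.
#' @export
simulation_params <- function(box_edge = 50, dt = 0.012, friction = 0.5,
                              temperature = 1, n_steps = 1e5, seed = 1,
                              sigma = 1, mass = 1, fene_r0 = 1.6,
                              fene_k = 30, r_rep = 2^(1 / 6), r_att = 1.5,
                              skin = 0.5) {
  p <- structure(
    list(box_edge = box_edge, dt = dt, friction = friction,
         temperature = temperature, n_steps = as.integer(n_steps),
         seed = as.integer(seed), sigma = sigma, mass = mass,
         fene_r0 = fene_r0, fene_k = fene_k, r_rep = r_rep, r_att = r_att,
         skin = skin),
    class = "sbs_params")
  problems <- validate_params(p)
  if (length(problems)) stop(paste(problems, collapse = "; "))
  p
}

validate_params <- function(p) {
  out <- character(0)
  if (p$dt <= 0) out <- c(out, "timestep must be positive")
  if (p$fene_r0 <= p$sigma) out <- c(out, "FENE R0 must exceed sigma")
  if (p$box_edge <= 0) out <- c(out, "box edge must be positive")
  out
}

#' @export
print.sbs_params <- function(x, ...) {
  cat("SBS simulation parameters\n")
  cat(sprintf("  box %g sigma, dt %g, friction %g, T %g\n", x$box_edge,
              x$dt, x$friction, x$temperature))
  cat(sprintf("  FENE R0 %g, K %g; WCA cut %.4f; attraction cut %g\n",
              x$fene_r0, x$fene_k, x$r_rep, x$r_att))
  invisible(x)
}

#' Validate a full SBS system
#'
#' Report-only diagnostics: returns a data frame of violated invariants
#' and soft warnings (empty when everything is consistent). Binder counts
#' are resolved from volume fractions as a side product and attached as
#' the `"binders"` attribute.
#'
#' @param spec a [polymer_spec()].
#' @param binders a [binder_ensemble()].
#' @param params a [simulation_params()].
#' @param affinity_range soft range of affinities (kT) outside which a
#'   warning row is emitted.
#' @return data frame with columns `level` ("error"/"warning"), `what`,
#'   `message`; attribute `"binders"` carries the resolved ensemble.
#' @export
validate_system <- function(spec, binders, params,
                            affinity_range = c(0, 8)) {
  rows <- list()
  add <- function(level, what, message)
    rows[[length(rows) + 1]] <<- data.frame(level = level, what = what,
                                            message = message)
  for (p in validate_polymer_spec(spec)) add("error", "polymer", p)
  for (p in validate_params(params)) add("error", "params", p)

  half <- params$box_edge / 2
  if (params$r_att >= half || params$r_rep >= half)
    add("error", "cutoffs",
        sprintf("interaction cut-off >= box_edge/2 (%g)", half))
  unknown <- setdiff(binders$type, spec$type_catalog)
  if (length(unknown))
    add("error", "binders", paste0("binder type(s) not in catalog: ",
                                   paste(unknown, collapse = ", ")))
  out_of_range <- binders$affinity < affinity_range[1] |
    binders$affinity > affinity_range[2]
  if (any(out_of_range))
    add("warning", "binders",
        sprintf("affinity outside [%g, %g] kT for type(s): %s",
                affinity_range[1], affinity_range[2],
                paste(binders$type[out_of_range], collapse = ", ")))
  resolved <- tryCatch(resolve_binder_counts(binders, params),
                       error = function(e) {
                         add("error", "binders", conditionMessage(e))
                         binders
                       })
  ctot <- sum(resolved$volume_fraction, na.rm = TRUE)
  if (!is.na(ctot) && ctot >= 0.5)
    add("error", "binders",
        sprintf("total binder volume fraction %.3f >= 0.5", ctot))
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(level = character(0), what = character(0),
               message = character(0))
  attr(report, "binders") <- resolved
  report
}

# ----------------------------------------------------------------- I/O ----

#' Read a polymer spec file
#'
#' The on-disk format is a TSV with columns `bead_index` (0-based),
#' `chrom`, `start_bp`, `types` (comma-separated labels, empty for inert
#' beads), preceded by a `#types:` comment declaring the catalog.
#'
#' @param path file path.
#' @return an `sbs_polymer_spec`.
#' @export
load_polymer_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  cat_line <- grep("^#types:", lines, value = TRUE)
  if (!length(cat_line)) stop("missing '#types:' catalog header in ", path)
  catalog <- trimws(strsplit(sub("^#types:", "", cat_line[1]), ",")[[1]])
  catalog <- catalog[nzchar(catalog)]
  body <- lines[!grepl("^#", lines)]
  df <- tryCatch(
    read.table(text = body, header = TRUE, sep = "\t",
               colClasses = c("integer", "character", "numeric",
                              "character"), na.strings = NULL),
    error = function(e) stop("malformed polymer spec file: ",
                             conditionMessage(e)))
  need <- c("bead_index", "chrom", "start_bp", "types")
  if (!all(need %in% names(df)))
    stop("polymer spec file must have columns: ",
         paste(need, collapse = ", "))
  df <- df[order(df$bead_index), ]
  if (!identical(df$bead_index, seq_len(nrow(df)) - 1L)) {
    bad <- which(df$bead_index != seq_len(nrow(df)) - 1L)[1]
    stop("bead_index not contiguous from 0 at file row ", bad)
  }
  bead_types <- lapply(strsplit(df$types, ","), function(x) {
    x <- trimws(x)
    x[nzchar(x)]
  })
  # beads past the end of strsplit on "" give character(0) already
  bp <- if (nrow(df) >= 2) df$start_bp[2] - df$start_bp[1] else 2500
  polymer_spec(bead_types, type_catalog = catalog, chrom = df$chrom[1],
               start_bp = df$start_bp[1], bp_per_bead = bp)
}

#' Write a polymer spec file
#'
#' @param spec an `sbs_polymer_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [load_polymer_spec()] for the format; the round trip is the
#'   identity.
#' @export
save_polymer_spec <- function(spec, path) {
  problems <- validate_polymer_spec(spec)
  if (length(problems)) stop(paste(problems, collapse = "; "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#types: ", paste(spec$type_catalog, collapse = ",")),
             con)
  df <- data.frame(
    bead_index = seq_len(spec$n_beads) - 1L,
    chrom = spec$chrom,
    start_bp = spec$start_bp + (seq_len(spec$n_beads) - 1) *
      spec$bp_per_bead,
    types = vapply(spec$bead_types, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

# bitmask encoding of bead label sets against the catalog (<= 30 types)
type_masks <- function(spec) {
  k <- length(spec$type_catalog)
  if (k > 30) stop("at most 30 binding-site types are supported")
  bit <- stats::setNames(2^(seq_len(k) - 1), spec$type_catalog)
  vapply(spec$bead_types,
         function(l) as.integer(sum(bit[l])), integer(1))
}

binder_type_masks <- function(types, spec) {
  k <- length(spec$type_catalog)
  bit <- stats::setNames(2^(seq_len(k) - 1), spec$type_catalog)
  as.integer(bit[types])
}
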