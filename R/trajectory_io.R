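# Trajectory input/output: extended XYZ writing/reading and LAMMPS-style
# text dump reading for interoperability with externally generated runs.

#' Write a trajectory (or single conformation) as extended XYZ
#'
#' One block per frame: atom count, a comment line carrying the step and
#' the box edge, then `species x y z` rows. Beads are written as `B<i>`
#' species by bead index order (species `B`), binders as their type
#' label.
#'
#' @param x an `sbs_trajectory` or `sbs_conformation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_frame <- function(coords, species, step, box) {
    writeLines(as.character(nrow(coords)), con)
    writeLines(sprintf("step=%d box=%g", step, box), con)
    writeLines(sprintf("%s %.8g %.8g %.8g", species, coords[, 1],
                       coords[, 2], coords[, 3]), con)
  }
  if (inherits(x, "sbs_conformation")) {
    coords <- rbind(x$bead_coords, x$binder_coords)
    species <- c(rep("P", nrow(x$bead_coords)),
                 if (!is.null(x$binder_types)) x$binder_types)
    write_frame(coords, species, 0L, x$box_edge)
  } else if (inherits(x, "sbs_trajectory")) {
    if (!length(x$frames)) stop("trajectory holds no stored frames")
    for (k in seq_along(x$frames)) {
      fr <- x$frames[[k]]
      species <- c(rep("P", min(nrow(fr), x$n_beads)),
                   if (nrow(fr) > x$n_beads)
                     x$final$binder_types)
      write_frame(fr, species, x$steps[k], x$final$box_edge)
    }
  } else stop("x must be an sbs_trajectory or sbs_conformation")
  invisible(path)
}

#' Read an extended XYZ trajectory
#'
#' @param path file path.
#' @return list of frames; each frame is a list with `coords` (matrix),
#'   `species`, `step`, `box_edge`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop("malformed XYZ at line ", i)
    comment <- lines[i + 1]
    step <- as.integer(sub(".*step=([0-9]+).*", "\\1", comment))
    box <- as.numeric(sub(".*box=([0-9.eE+-]+).*", "\\1", comment))
    block <- lines[i + 1 + seq_len(n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]),
                       numeric(3)))
    species <- vapply(parts, `[`, "", 1)
    frames[[length(frames) + 1]] <-
      list(coords = coords, species = species, step = step,
           box_edge = box)
    i <- i + 2 + n
  }
  frames
}

#' Read a LAMMPS-style text dump
#'
#' Accepts the standard `ITEM:`-delimited text dump with per-atom columns
#' including `id`, `type` and either unwrapped (`xu yu zu`) or wrapped
#' (`x y z`) coordinates. Atoms are returned sorted by id.
#'
#' @param path file path.
#' @return list of frames; each frame has `coords`, `type`, `step`,
#'   `box_edge`.
#' @export
read_lammps_dump <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "ITEM: TIMESTEP"))
      stop("malformed dump at line ", i)
    step <- as.integer(lines[i + 1])
    stopifnot(startsWith(lines[i + 2], "ITEM: NUMBER OF ATOMS"))
    n <- as.integer(lines[i + 3])
    stopifnot(startsWith(lines[i + 4], "ITEM: BOX BOUNDS"))
    b1 <- as.numeric(strsplit(trimws(lines[i + 5]), "[[:space:]]+")[[1]])
    box <- b1[2] - b1[1]
    header <- strsplit(sub("^ITEM: ATOMS ", "", lines[i + 8]),
                       "[[:space:]]+")[[1]]
    block <- lines[i + 8 + seq_len(n)]
    dat <- read.table(text = block, col.names = header)
    xcol <- intersect(c("xu", "x"), header)[1]
    ycol <- intersect(c("yu", "y"), header)[1]
    zcol <- intersect(c("zu", "z"), header)[1]
    if (anyNA(c(xcol, ycol, zcol)))
      stop("dump lacks coordinate columns (x/y/z or xu/yu/zu)")
    dat <- dat[order(dat$id), ]
    coords <- as.matrix(dat[, c(xcol, ycol, zcol)])
    dimnames(coords) <- NULL
    frames[[length(frames) + 1]] <- list(
      coords = coords,
      type = dat$type, step = step, box_edge = box)
    i <- i + 9 + n
  }
  frames
}
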