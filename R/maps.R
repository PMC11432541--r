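# Contact maps, ensemble averaging, genomic binning, contact-probability
# curves and the map-comparison statistics (Pearson r, genomic-distance
# corrected r', Spearman r_s).

new_contact_map <- function(matrix, threshold = NA_real_,
                            resolution_bp = NA_real_) {
  structure(list(n = nrow(matrix), matrix = matrix, threshold = threshold,
                 resolution_bp = resolution_bp),
            class = "sbs_contact_map")
}

map_matrix <- function(x) {
  if (inherits(x, "sbs_contact_map")) x$matrix else as.matrix(x)
}

#' @export
print.sbs_contact_map <- function(x, ...) {
  cat("SBS contact map: ", x$n, " x ", x$n,
      if (!is.na(x$threshold)) paste0(", threshold ", x$threshold,
                                      " sigma"),
      if (!is.na(x$resolution_bp)) paste0(", ", x$resolution_bp,
                                          " bp/bin"), "\n", sep = "")
  invisible(x)
}

#' Single-molecule contact map
#'
#' Entry (i, j) is 1 when beads i and j are closer than the distance
#' threshold (strict inequality), 0 otherwise; the diagonal is fixed at 1
#' by convention and excluded from all comparison statistics. The default
#' threshold of 3.5 sigma sits midway in the commonly explored 2-5 sigma
#' range (roughly 150-350 nm at the calibrated sigma).
#'
#' @param conf an `sbs_conformation` or an N x 3 coordinate matrix
#'   (unwrapped).
#' @param threshold contact threshold in sigma.
#' @param resolution_bp genomic resolution recorded on the map.
#' @return an `sbs_contact_map` with a binary matrix.
#' @export
contact_map <- function(conf, threshold = 3.5, resolution_bp = 2500) {
  stopifnot(threshold > 0)
  coords <- if (inherits(conf, "sbs_conformation")) conf$bead_coords else
    as.matrix(conf)
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  m <- (d < threshold) * 1
  diag(m) <- 1
  new_contact_map(m, threshold = threshold, resolution_bp = resolution_bp)
}

#' Ensemble mean of contact maps
#'
#' Entrywise mean of single-molecule binary maps, giving a contact
#' frequency matrix comparable to a bulk contact experiment.
#'
#' @param maps list of `sbs_contact_map`s (or matrices) of equal size.
#' @return an `sbs_contact_map` with values in [0, 1].
#' @export
ensemble_mean <- function(maps) {
  stopifnot(length(maps) >= 1)
  mats <- lapply(maps, map_matrix)
  n <- nrow(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == n), TRUE)))
    stop("contact maps differ in shape")
  acc <- Reduce(`+`, mats) / length(mats)
  thr <- unique(vapply(maps, function(m)
    if (inherits(m, "sbs_contact_map")) m$threshold else NA_real_,
    numeric(1)))
  res <- unique(vapply(maps, function(m)
    if (inherits(m, "sbs_contact_map")) m$resolution_bp else NA_real_,
    numeric(1)))
  new_contact_map(acc, threshold = if (length(thr) == 1) thr else
    NA_real_, resolution_bp = if (length(res) == 1) res else NA_real_)
}

#' Bin a matrix to a coarser resolution
#'
#' Block mean over `factor` x `factor` tiles; e.g. an 800-bead map binned
#' by a factor 10 gives 80 bins of 25 kb at 2.5 kb/bead.
#'
#' @param map an `sbs_contact_map` or matrix whose size is divisible by
#'   `factor`.
#' @param factor integer binning factor.
#' @return binned map of the same class as the input.
#' @export
bin_matrix <- function(map, factor) {
  m <- map_matrix(map)
  n <- nrow(m)
  factor <- as.integer(factor)
  if (factor < 1 || n %% factor != 0)
    stop("binning factor must divide the matrix size (", n, ")")
  if (factor == 1) return(map)
  nb <- n %/% factor
  grp <- rep(seq_len(nb), each = factor)
  # two-pass block mean; NAs propagate (masked bins stay masked)
  col_binned <- t(rowsum(t(m), grp, reorder = FALSE)) / factor
  binned <- rowsum(col_binned, grp, reorder = FALSE) / factor
  dimnames(binned) <- NULL
  if (inherits(map, "sbs_contact_map"))
    new_contact_map(binned, threshold = map$threshold,
                    resolution_bp = map$resolution_bp * factor)
  else binned
}

#' Contact probability versus genomic separation
#'
#' `Pc(s)` is the mean of the map entries at separation `|i - j| = s`,
#' for s = 1 .. n-1.
#'
#' @param map an `sbs_contact_map` or frequency matrix.
#' @return data frame with columns `s` and `pc`, class `sbs_contact_curve`.
#' @export
contact_probability <- function(map) {
  m <- map_matrix(map)
  n <- nrow(m)
  stopifnot(n >= 2)
  sep <- abs(row(m) - col(m))
  means <- tapply(m, sep, mean, na.rm = TRUE)
  s <- as.integer(names(means))
  keep <- s >= 1
  out <- data.frame(s = s[keep], pc = as.numeric(means[keep]))
  class(out) <- c("sbs_contact_curve", "data.frame")
  out
}

# upper-triangle off-diagonal entries of paired matrices, dropping pairs
# where either entry is NA (masked bins)
paired_upper <- function(A, B) {
  A <- map_matrix(A)
  B <- map_matrix(B)
  if (!all(dim(A) == dim(B))) stop("matrices differ in shape")
  ut <- upper.tri(A, diag = FALSE)
  a <- A[ut]
  b <- B[ut]
  keep <- is.finite(a) & is.finite(b)
  list(a = a[keep], b = b[keep])
}

undefined_cor <- function(reason) {
  structure(NA_real_, undefined = TRUE, reason = reason)
}

#' Pearson correlation between two maps
#'
#' Computed over the upper-triangle off-diagonal entries; masked (NA)
#' bins are dropped pairwise. A zero-variance input yields `NA` flagged
#' with the `undefined` attribute rather than a silent zero.
#'
#' @param A,B contact maps or matrices of equal size.
#' @return correlation in [-1, 1], or flagged `NA`.
#' @export
pearson_map <- function(A, B) {
  p <- paired_upper(A, B)
  if (length(p$a) < 2 || stats::sd(p$a) == 0 || stats::sd(p$b) == 0)
    return(undefined_cor("zero variance on compared entries"))
  stats::cor(p$a, p$b)
}

#' Genomic-distance corrected Pearson correlation (r')
#'
#' Within each matrix, the mean of its entries at every genomic
#' separation `|i - j|` is subtracted (each matrix supplies its own
#' expected-by-distance profile); the Pearson correlation of the residual
#' matrices then measures similarity of the distance-independent
#' structure. A randomly folded control chain scores close to zero
#' against any structured map, and matrices that are pure functions of
#' `|i - j|` have vanishing residuals and are flagged undefined.
#'
#' @param A,B contact maps, distance maps or plain matrices of equal
#'   size.
#' @return r' in [-1, 1], or `NA` flagged `undefined`.
#' @export
distance_corrected_pearson <- function(A, B) {
  ra <- residualize_by_distance(map_matrix(A))
  rb <- residualize_by_distance(map_matrix(B))
  p <- paired_upper(ra, rb)
  if (length(p$a) < 2 || stats::sd(p$a) < 1e-12 ||
      stats::sd(p$b) < 1e-12)
    return(undefined_cor(
      "residuals have zero variance (matrix depends only on |i-j|)"))
  stats::cor(p$a, p$b)
}

# subtract the per-|i-j| mean from every entry (NAs ignored in the means)
residualize_by_distance <- function(m) {
  sep <- abs(row(m) - col(m))
  mu <- tapply(m, sep, mean, na.rm = TRUE)
  m - matrix(as.numeric(mu[as.character(sep)]), nrow(m), ncol(m))
}

#' Spearman correlation between two maps
#'
#' Rank transform (mean ranks on ties) of the upper-triangle off-diagonal
#' entries followed by Pearson correlation of the ranks; invariant under
#' monotone transformations of either map.
#'
#' @inheritParams pearson_map
#' @return r_s in [-1, 1], or flagged `NA`.
#' @export
spearman_map <- function(A, B) {
  p <- paired_upper(A, B)
  ra <- rank(p$a)
  rb <- rank(p$b)
  if (length(ra) < 2 || stats::sd(ra) == 0 || stats::sd(rb) == 0)
    return(undefined_cor("zero rank variance"))
  stats::cor(ra, rb)
}

#' Read a dense contact matrix from TSV
#'
#' Accepts an optional `#resolution_bp=` comment header and optional
#' bin labels (row/column names). Asymmetric input is symmetrized by
#' averaging with its transpose (with a warning); NA entries are kept as
#' masked bins.
#'
#' @param path file path.
#' @return an `sbs_contact_map`.
#' @export
read_contact_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  res_bp <- NA_real_
  res_line <- grep("^#resolution_bp=", lines, value = TRUE)
  if (length(res_line))
    res_bp <- as.numeric(sub("^#resolution_bp=", "", res_line[1]))
  body <- lines[!grepl("^#", lines)]
  first <- strsplit(body[1], "\t")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  df <- read.table(text = body, header = has_header, sep = "\t",
                   row.names = if (has_header) 1 else NULL)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("contact matrix must be square, got ",
                               nrow(m), " x ", ncol(m))
  dimnames(m) <- NULL
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12,
                        check.attributes = FALSE))) {
    warning("asymmetric input symmetrized by averaging with transpose")
    m <- (m + t(m)) / 2
  }
  new_contact_map(m, resolution_bp = res_bp)
}

#' Write a dense contact matrix as TSV
#'
#' @param map an `sbs_contact_map` or matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(map, path) {
  m <- map_matrix(map)
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(map, "sbs_contact_map") && !is.na(map$resolution_bp))
    writeLines(paste0("#resolution_bp=",
                      format(map$resolution_bp, scientific = FALSE)), con)
  write.table(m, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
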