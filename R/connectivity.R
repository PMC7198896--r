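#' Seed-by-target connectivity matrix
#'
#' Streamline counts from probabilistic tractography: one row per seed
#' voxel (aligned with the canonical seed coordinate order), one column
#' per target voxel in raster order over the target grid. Whether the
#' producer applied distance correction and a curvature threshold is
#' recorded as metadata; this package does not re-implement streamlining.
#'
#' @param counts non-negative integer matrix, seeds x targets.
#' @param seeds a [voxel_coords()] list with one entry per row, or `NULL`.
#' @param target_shape integer length-3 extent of the target grid;
#'   defaults to `c(ncol(counts), 1, 1)` for an abstract target space.
#' @param target_spacing mm per target-grid axis.
#' @param n_samples streamlines sampled per seed voxel (default 10000).
#' @param distance_corrected,curvature_thresholded logical metadata flags.
#' @return Object of class `cbp_connectivity`.
#' @export
connectivity_matrix <- function(counts, seeds = NULL, target_shape = NULL,
                                target_spacing = c(1, 1, 1),
                                n_samples = 10000L,
                                distance_corrected = FALSE,
                                curvature_thresholded = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("streamline counts must be non-negative")
  if (is.null(target_shape)) target_shape <- c(ncol(counts), 1L, 1L)
  target_shape <- as.integer(target_shape)
  stopifnot(length(target_shape) == 3L, prod(target_shape) == ncol(counts))
  if (!is.null(seeds)) {
    stopifnot(inherits(seeds, "cbp_coords"), nrow(seeds$coords) == nrow(counts))
  }
  if (n_samples <= 0) stop("n_samples must be positive")
  structure(list(counts = counts, seeds = seeds,
                 target_shape = target_shape,
                 target_spacing = as.numeric(target_spacing),
                 n_samples = as.integer(n_samples),
                 distance_corrected = distance_corrected,
                 curvature_thresholded = curvature_thresholded),
            class = "cbp_connectivity")
}

#' @export
print.cbp_connectivity <- function(x, ...) {
  cat("<cbp_connectivity> ", nrow(x$counts), " seeds x ", ncol(x$counts),
      " targets, n_samples=", x$n_samples, "\n", sep = "")
  invisible(x)
}

#' Discard low-count connections
#'
#' Cells with fewer streamlines than `count_threshold` are set to 0,
#' removing spurious single-streamline connections while keeping true
#' ones. Idempotent. The default threshold of 2 is a toolkit default (see
#' the methods vignette); 0 disables thresholding.
#'
#' @param cm a [connectivity_matrix()].
#' @param count_threshold non-negative integer.
#' @return A thresholded [connectivity_matrix()].
#' @export
threshold_counts <- function(cm, count_threshold = 2L) {
  stopifnot(inherits(cm, "cbp_connectivity"), count_threshold >= 0)
  cm$counts[cm$counts < count_threshold] <- 0
  cm
}

#' Convert streamline counts to connection probabilities
#'
#' Each count is divided by the total number of streamlines sampled from
#' the seed voxel.
#'
#' @param cm a [connectivity_matrix()].
#' @return Numeric matrix of connection probabilities (same shape as the
#'   counts).
#' @export
to_probability <- function(cm) {
  stopifnot(inherits(cm, "cbp_connectivity"))
  if (cm$n_samples <= 0) stop("n_samples must be positive")
  cm$counts / cm$n_samples
}

#' Down-sample the target grid of a connectivity matrix
#'
#' Target voxels are grouped into axis-aligned bins of edge length
#' `downsample_mm` (an integer number of native voxels per axis, floored;
#' partial bins at the volume edges are kept). Each bin's count is the
#' sum of its member voxels' counts, so every seed row's total count is
#' conserved exactly. The seed axis is unchanged.
#'
#' @param cm a [connectivity_matrix()].
#' @param downsample_mm bin edge length in mm, at least the native
#'   target spacing (default 3).
#' @return A [connectivity_matrix()] on the coarser target grid.
#' @export
downsample_targets <- function(cm, downsample_mm = 3) {
  stopifnot(inherits(cm, "cbp_connectivity"))
  if (any(downsample_mm < cm$target_spacing))
    stop("downsample_mm must be at least the native target spacing")
  f <- pmax(1L, as.integer(floor(downsample_mm / cm$target_spacing)))
  shp <- cm$target_shape
  new_shape <- as.integer(ceiling(shp / f))
  # raster-order voxel index -> raster-order bin index
  vox <- arrayInd(seq_len(prod(shp)), shp) - 1L
  bin <- vox %/% matrix(f, nrow(vox), 3, byrow = TRUE)
  bin_id <- bin[, 1] + new_shape[1] * (bin[, 2] + new_shape[2] * bin[, 3]) + 1L
  n_bins <- prod(new_shape)
  group <- factor(bin_id, levels = seq_len(n_bins))
  new_counts <- t(apply(cm$counts, 1, function(row)
    as.vector(rowsum(row, group, reorder = FALSE))))
  if (nrow(cm$counts) == 1L) new_counts <- matrix(new_counts, nrow = 1)
  connectivity_matrix(new_counts, seeds = cm$seeds, target_shape = new_shape,
                      target_spacing = cm$target_spacing * f,
                      n_samples = cm$n_samples,
                      distance_corrected = cm$distance_corrected,
                      curvature_thresholded = cm$curvature_thresholded)
}

#' Seed-by-seed similarity matrix
#'
#' @param values symmetric numeric matrix in [-1, 1] with unit diagonal.
#' @return Object of class `cbp_similarity`.
#' @export
similarity_matrix <- function(values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-12)
    stop("similarity matrix must be symmetric")
  values <- (values + t(values)) / 2
  diag(values) <- 1
  structure(list(values = values), class = "cbp_similarity")
}

#' @export
print.cbp_similarity <- function(x, ...) {
  cat("<cbp_similarity> ", nrow(x$values), " x ", ncol(x$values), " seeds\n",
      sep = "")
  invisible(x)
}

#' Cross-correlation of connectivity profiles
#'
#' Pearson correlation between every pair of seed rows. Because Pearson
#' correlation is invariant to positive row rescaling, counts and
#' connection probabilities give the identical matrix.
#'
#' @param x a [connectivity_matrix()] or a plain seeds x targets matrix
#'   with at least 2 rows.
#' @param drop_constant if `TRUE`, seed rows with zero variance are
#'   dropped with a warning instead of raising an error; the kept row
#'   indices are attached as attribute `"kept"`.
#' @return A [similarity_matrix()]; if rows were dropped, with a `kept`
#'   attribute on the `values` matrix.
#' @export
cross_correlation <- function(x, drop_constant = FALSE) {
  m <- if (inherits(x, "cbp_connectivity")) x$counts else as.matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 seed rows")
  v <- apply(m, 1, stats::var)
  const <- which(v == 0)
  kept <- seq_len(nrow(m))
  if (length(const)) {
    if (!drop_constant)
      stop("constant connectivity profile (zero variance) at seed row(s) ",
           paste(utils::head(const, 5), collapse = ", "),
           "; correlation undefined")
    warning("dropping ", length(const), " constant seed row(s): ",
            paste(utils::head(const, 5), collapse = ", "))
    kept <- setdiff(kept, const)
    m <- m[kept, , drop = FALSE]
    if (nrow(m) < 2L) stop("fewer than 2 non-constant seed rows remain")
  }
  s <- stats::cor(t(m))
  out <- similarity_matrix(s)
  attr(out$values, "kept") <- kept
  out
}

#' Write a connectivity matrix as text triplets
#'
#' Sparse plain-text form: one line per nonzero cell,
#' `seed_index target_index count` (1-based indices), preceded by a
#' comment header recording the matrix extent and `n_samples`.
#'
#' @param cm a [connectivity_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_connectivity_triplets <- function(cm, path) {
  stopifnot(inherits(cm, "cbp_connectivity"))
  nz <- which(cm$counts != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# n_seeds", nrow(cm$counts)),
    paste("# target_shape", paste(cm$target_shape, collapse = " ")),
    paste("# target_spacing", paste(cm$target_spacing, collapse = " ")),
    paste("# n_samples", cm$n_samples)), con)
  if (nrow(nz))
    writeLines(paste(nz[, 1], nz[, 2], cm$counts[nz]), con)
  invisible(path)
}

#' Read a connectivity matrix from text triplets
#'
#' @param path file written by [write_connectivity_triplets()].
#' @param seeds optional [voxel_coords()] to attach.
#' @return A [connectivity_matrix()].
#' @export
read_connectivity_triplets <- function(path, seeds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (!length(ln)) stop("missing header line: ", key)
    as.numeric(strsplit(sub(paste0("^# ", key, " "), "", ln[1]), " ")[[1]])
  }
  n_seeds <- as.integer(get("n_seeds"))
  target_shape <- as.integer(get("target_shape"))
  spacing <- get("target_spacing")
  n_samples <- as.integer(get("n_samples"))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  counts <- matrix(0, n_seeds, prod(target_shape))
  if (length(body)) {
    trip <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                   ncol = 3, byrow = TRUE)
    counts[cbind(trip[, 1], trip[, 2])] <- trip[, 3]
  }
  connectivity_matrix(counts, seeds = seeds, target_shape = target_shape,
                      target_spacing = spacing, n_samples = n_samples)
}
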