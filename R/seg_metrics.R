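#' Voxel-overlap metrics between a segmentation and a reference
#'
#' Dice similarity coefficient, specificity and sensitivity of a binary
#' segmentation against a binary reference (the reference is taken as
#' truth). DSC = 2|S n R| / (|S| + |R|); sensitivity = TP/(TP+FN);
#' specificity = TN/(TN+FP).
#'
#' @param seg,ref binary 3D arrays (or [label_volume()]s) of equal shape;
#'   `ref` must have at least one foreground voxel.
#' @return Named list with `dsc`, `specificity`, `sensitivity`.
#' @export
overlap_metrics <- function(seg, ref) {
  seg <- .as_binary_array(seg, "seg")
  ref <- .as_binary_array(ref, "ref")
  if (!identical(dim(seg), dim(ref))) stop("shape mismatch between seg and ref")
  nref <- sum(ref)
  if (nref == 0) stop("empty reference mask: DSC undefined")
  tp <- sum(seg & ref)
  fp <- sum(seg & !ref)
  fn <- sum(!seg & ref)
  tn <- sum(!seg & !ref)
  list(dsc = 2 * tp / (sum(seg) + nref),
       specificity = tn / (tn + fp),
       sensitivity = tp / (tp + fn))
}

.as_binary_array <- function(x, what) {
  if (inherits(x, "cbp_label_volume")) x <- x$data
  x <- as.array(x)
  if (!all(x %in% c(0, 1, FALSE, TRUE)))
    stop(what, " must be a binary mask")
  array(as.logical(x), dim = dim(x))
}

# Boundary voxels: foreground with at least one background 6-neighbor
# (voxels on the array edge count the outside as background).
.boundary_voxels <- function(mask) {
  d <- dim(mask)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  inner <- padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb_all <- padded[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
            padded[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
            padded[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
            padded[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
            padded[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
            padded[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  which(inner & !nb_all, arr.ind = TRUE)
}

#' Symmetric surface distances between two binary masks
#'
#' Boundary voxels are foreground voxels with at least one background
#' face-neighbor (6-connectivity). Distances between boundary-voxel
#' centers are Euclidean in physical mm via the per-axis spacing;
#' anisotropic spacing is supported. MASD is the average of the two
#' directed mean boundary distances; the maximum surface distance is the
#' largest directed boundary distance in either direction.
#'
#' @param seg,ref non-empty binary 3D arrays (or [label_volume()]s) of
#'   equal shape.
#' @param spacing_mm numeric length-3 voxel spacing in mm (default 1 mm
#'   isotropic).
#' @return Named list with `masd_mm` and `max_surface_distance_mm`.
#' @export
surface_distances <- function(seg, ref, spacing_mm = c(1, 1, 1)) {
  seg <- .as_binary_array(seg, "seg")
  ref <- .as_binary_array(ref, "ref")
  if (!identical(dim(seg), dim(ref))) stop("shape mismatch between seg and ref")
  if (sum(seg) == 0 || sum(ref) == 0) stop("empty mask: surface undefined")
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  bs <- .boundary_voxels(seg)
  br <- .boundary_voxels(ref)
  ps <- sweep(bs, 2, spacing_mm, `*`)
  pr <- sweep(br, 2, spacing_mm, `*`)
  # nearest-neighbor distances from each point set to the other; per-axis
  # outer differences keep full precision (no |a|^2+|b|^2-2ab cancellation)
  d2 <- outer(ps[, 1], pr[, 1], `-`)^2 + outer(ps[, 2], pr[, 2], `-`)^2 +
        outer(ps[, 3], pr[, 3], `-`)^2
  d_s2r <- sqrt(apply(d2, 1, min))
  d_r2s <- sqrt(apply(d2, 2, min))
  list(masd_mm = (mean(d_s2r) + mean(d_r2s)) / 2,
       max_surface_distance_mm = max(c(d_s2r, d_r2s)))
}

#' Relative volume difference in percent
#'
#' `|V_seg - V_ref| / V_ref * 100`, with the reference (manual)
#' segmentation as denominator.
#'
#' @param seg binary segmentation mask.
#' @param ref non-empty binary reference mask.
#' @return Non-negative percent.
#' @export
relative_volume_difference <- function(seg, ref) {
  seg <- .as_binary_array(seg, "seg")
  ref <- .as_binary_array(ref, "ref")
  vref <- sum(ref)
  if (vref == 0) stop("empty reference mask: RVD undefined")
  abs(sum(seg) - vref) / vref * 100
}

#' Full segmentation-accuracy score
#'
#' Combines [overlap_metrics()], [surface_distances()] and
#' [relative_volume_difference()] into one row of the standard evaluation
#' table.
#'
#' @inheritParams surface_distances
#' @return Named list with `dsc`, `specificity`, `sensitivity`, `masd_mm`,
#'   `max_surface_distance_mm`, `rvd_percent`.
#' @export
seg_score <- function(seg, ref, spacing_mm = c(1, 1, 1)) {
  ov <- overlap_metrics(seg, ref)
  sd_ <- surface_distances(seg, ref, spacing_mm)
  c(ov, sd_, list(rvd_percent = relative_volume_difference(seg, ref)))
}

#' Write a per-subject metric table as TSV
#'
#' @param table data.frame of segmentation scores, one row per subject.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
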