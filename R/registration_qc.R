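#' Image-similarity metrics for registration quality control
#'
#' The three similarity measurements applied to an externally registered
#' image pair: mean square difference (MSD), Pearson cross-correlation
#' (CC), and mutual information (MI) of the joint intensity histogram, in
#' bits. All are computed within a mask.
#'
#' @param image_a,image_b 3D numeric arrays of equal shape.
#' @param mask logical/binary array selecting the voxels to compare; the
#'   whole volume if `NULL`.
#' @param n_bins number of equal-width histogram bins per image
#'   (default 32), over each image's min-max range within the mask.
#' @return Named list `msd`, `cc`, `mi_bits`.
#' @export
similarity_metrics <- function(image_a, image_b, mask = NULL, n_bins = 32L) {
  a <- as.array(image_a); b <- as.array(image_b)
  if (!identical(dim(a), dim(b))) stop("shape mismatch between images")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  mask <- .as_binary_array(mask, "mask")
  if (!identical(dim(mask), dim(a))) stop("mask shape mismatch")
  x <- a[mask]; y <- b[mask]
  if (!length(x)) stop("empty mask")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("cross-correlation undefined: constant image within mask")
  msd <- mean((x - y)^2)
  cc <- stats::cor(x, y)
  mi <- .mutual_information_bits(x, y, n_bins)
  list(msd = msd, cc = cc, mi_bits = mi)
}

.hist_bin <- function(v, n_bins) {
  rng <- range(v)
  if (diff(rng) == 0) return(rep(1L, length(v)))
  b <- floor((v - rng[1]) / diff(rng) * n_bins) + 1L
  pmin(b, n_bins)
}

.entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

.mutual_information_bits <- function(x, y, n_bins) {
  bx <- .hist_bin(x, n_bins); by <- .hist_bin(y, n_bins)
  joint <- table(factor(bx, levels = 1:n_bins), factor(by, levels = 1:n_bins))
  pj <- joint / sum(joint)
  hx <- .entropy_bits(rowSums(pj))
  hy <- .entropy_bits(colSums(pj))
  hxy <- .entropy_bits(as.vector(pj))
  max(hx + hy - hxy, 0)
}

#' Default registration-QC thresholds
#'
#' Experience-based defaults: CC must be at least 0.85, MI at least 0.5
#' bits, and MSD at most (0.1 x intensity range)^2, where the range is
#' that of the first image within the mask. These are toolkit defaults,
#' configurable per study.
#'
#' @param intensity_range numeric: intensity range used to scale the MSD
#'   cutoff (default 1).
#' @return Named list `msd_max`, `cc_min`, `mi_min_bits`.
#' @export
qc_thresholds <- function(intensity_range = 1) {
  list(msd_max = (0.1 * intensity_range)^2, cc_min = 0.85, mi_min_bits = 0.5)
}

#' Check registration similarity metrics against thresholds
#'
#' Each metric gets an independent pass flag (MSD passes when at or below
#' its cutoff, CC and MI when at or above theirs). A failing metric emits
#' a warning requesting human inspection and marks the subject for
#' review; the check never aborts a pipeline run.
#'
#' @param metrics list with `msd`, `cc`, `mi_bits` (from
#'   [similarity_metrics()]).
#' @param thresholds list from [qc_thresholds()].
#' @param subject optional subject identifier used in the warning.
#' @return List of class `cbp_qc_report`: the metrics, `passed` (named
#'   logical vector), `thresholds`, `needs_inspection`, `warnings`
#'   (character).
#' @export
qc_check <- function(metrics, thresholds = qc_thresholds(), subject = NULL) {
  stopifnot(all(c("msd", "cc", "mi_bits") %in% names(metrics)))
  stopifnot(all(vapply(thresholds, is.finite, logical(1))))
  passed <- c(msd = metrics$msd <= thresholds$msd_max,
              cc = metrics$cc >= thresholds$cc_min,
              mi = metrics$mi_bits >= thresholds$mi_min_bits)
  warns <- character(0)
  for (m in names(passed)[!passed]) {
    msg <- paste0("registration QC: metric '", m, "' failed",
                  if (!is.null(subject)) paste0(" for subject ", subject),
                  "; human inspection requested")
    warns <- c(warns, msg)
    warning(msg, call. = FALSE)
  }
  structure(list(msd = metrics$msd, cc = metrics$cc, mi_bits = metrics$mi_bits,
                 passed = passed, thresholds = thresholds,
                 needs_inspection = any(!passed), warnings = warns),
            class = "cbp_qc_report")
}

#' @export
print.cbp_qc_report <- function(x, ...) {
  cat("<cbp_qc_report> msd=", signif(x$msd, 4), " cc=", signif(x$cc, 4),
      " mi=", signif(x$mi_bits, 4), " bits; ",
      if (x$needs_inspection) "NEEDS INSPECTION" else "all passed", "\n",
      sep = "")
  invisible(x)
}
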