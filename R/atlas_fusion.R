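#' Configuration for joint label fusion
#'
#' Free parameters of the patch-based joint-label-fusion weighting. The
#' patch radius sets the cube (2r+1)^3 over which atlas-vs-target
#' intensity errors are accumulated; `beta` is the exponent applied to the
#' absolute intensity differences; `ridge` regularizes the pairwise error
#' matrix before inversion; `tie_rule` resolves exact vote ties in
#' majority voting.
#'
#' @param patch_radius non-negative integer, voxels per axis (default 2).
#' @param search_radius non-negative integer local-search radius
#'   (default 0: no local search).
#' @param beta positive exponent on absolute intensity differences
#'   (default 2).
#' @param ridge small positive regularizer (default 1e-6).
#' @param tie_rule `"background"` or `"foreground"`.
#' @return A list of class `cbp_fusion_config`.
#' @export
fusion_config <- function(patch_radius = 2L, search_radius = 0L, beta = 2,
                          ridge = 1e-6,
                          tie_rule = c("background", "foreground")) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(patch_radius >= 0, search_radius >= 0, beta > 0, ridge > 0)
  structure(list(patch_radius = as.integer(patch_radius),
                 search_radius = as.integer(search_radius),
                 beta = beta, ridge = ridge, tie_rule = tie_rule),
            class = "cbp_fusion_config")
}

.check_same_shape <- function(vols) {
  dims <- lapply(vols, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("shape mismatch among volumes")
  invisible(dims[[1]])
}

.label_stack <- function(atlas_labels) {
  lab <- lapply(atlas_labels, .as_binary_array, what = "atlas label")
  .check_same_shape(lab)
  lab
}

#' Boundary-uncertainty mask of a set of atlas segmentations
#'
#' The region where mapped atlas segmentations disagree: the union of all
#' atlas masks minus their intersection. Label fusion only needs to be
#' computed here; everywhere else the atlases are unanimous.
#'
#' @param atlas_labels list of binary 3D arrays (or [label_volume()]s) of
#'   a common shape.
#' @return Logical 3D array, `TRUE` where at least one but not all
#'   atlases label the voxel foreground.
#' @export
boundary_uncertainty_mask <- function(atlas_labels) {
  lab <- .label_stack(atlas_labels)
  u <- Reduce(`|`, lab)
  i <- Reduce(`&`, lab)
  u & !i
}

#' Majority-voting label fusion
#'
#' Inside the uncertainty mask a voxel is labeled foreground iff strictly
#' more than half of the atlases vote foreground; exact ties go to
#' `tie_rule`. Outside the mask the (unanimous) atlas label is copied
#' unchanged.
#'
#' @inheritParams boundary_uncertainty_mask
#' @param uncertainty_mask logical array from
#'   [boundary_uncertainty_mask()]; computed internally if `NULL`.
#' @param tie_rule `"background"` (default) or `"foreground"`.
#' @return Integer 3D array of fused labels (0/1).
#' @export
majority_vote <- function(atlas_labels, uncertainty_mask = NULL,
                          tie_rule = c("background", "foreground")) {
  tie_rule <- match.arg(tie_rule)
  lab <- .label_stack(atlas_labels)
  if (is.null(uncertainty_mask)) uncertainty_mask <- boundary_uncertainty_mask(lab)
  if (!identical(dim(uncertainty_mask), dim(lab[[1]])))
    stop("shape mismatch between mask and atlas labels")
  n <- length(lab)
  votes <- Reduce(`+`, lapply(lab, function(x) array(as.integer(x), dim(x))))
  fused <- array(as.integer(lab[[1]]), dim(lab[[1]]))  # unanimous copy outside
  win <- votes * 2L > n
  tie <- votes * 2L == n
  fused[uncertainty_mask] <- as.integer(win[uncertainty_mask] |
    (tie[uncertainty_mask] & tie_rule == "foreground"))
  fused
}

# Sum over a cubic window of half-width r, per axis, via running sums.
.box_sum <- function(arr, r) {
  if (r == 0L) return(arr)
  d <- dim(arr)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    da <- dim(a)
    m <- matrix(a, nrow = da[1])
    cs <- rbind(0, apply(m, 2, cumsum))
    i <- seq_len(da[1])
    hi <- pmin(i + r, da[1]) + 1L
    lo <- pmax(i - r, 1L)
    m2 <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
    arr <- aperm(array(m2, da), order(perm))
  }
  arr
}

#' Joint label fusion
#'
#' Weighted-vote label fusion in which atlas weights account for
#' correlated atlas errors. At each voxel inside the uncertainty mask,
#' the pairwise error matrix is the patchwise product of target-vs-atlas
#' intensity differences,
#' `M[i, j] = sum_patch |T - I_i|^beta * |T - I_j|^beta`,
#' and the weights solve `w = (M + ridge I)^-1 1`, normalized to sum to 1.
#' Negative solved weights are clipped to 0 and the vector renormalized,
#' so weights are always a probability vector. The fused label is
#' foreground iff the weighted vote is at least 0.5. Outside the mask the
#' unanimous atlas label is copied. If the regularized system is still
#' numerically singular the voxel falls back to uniform weights with a
#' warning.
#'
#' @param atlas_set list with elements `atlases` (list of
#'   `list(intensity, label)` pairs on the target grid) and
#'   `target_intensity` (3D array).
#' @param uncertainty_mask logical array; computed from the atlas labels
#'   if `NULL`.
#' @param config a [fusion_config()].
#' @return Integer 3D array of fused labels (0/1).
#' @export
joint_label_fusion <- function(atlas_set, uncertainty_mask = NULL,
                               config = fusion_config()) {
  stopifnot(is.list(atlas_set$atlases), length(atlas_set$atlases) >= 1L)
  target <- as.array(atlas_set$target_intensity)
  lab <- .label_stack(lapply(atlas_set$atlases, `[[`, "label"))
  ints <- lapply(atlas_set$atlases, function(a) as.array(a$intensity))
  .check_same_shape(c(ints, list(target)))
  if (!identical(dim(target), dim(lab[[1]])))
    stop("shape mismatch between intensities and labels")
  n <- length(lab)
  if (is.null(uncertainty_mask)) uncertainty_mask <- boundary_uncertainty_mask(lab)
  fused <- array(as.integer(lab[[1]]), dim(lab[[1]]))
  vox <- which(uncertainty_mask)
  if (!length(vox)) return(fused)
  if (n == 1L) return(array(as.integer(lab[[1]]), dim(lab[[1]])))

  D <- lapply(ints, function(I) abs(target - I)^config$beta)
  # patchwise joint error estimates, one volume per atlas pair
  M <- array(0, c(length(vox), n, n))
  for (i in seq_len(n)) for (j in i:n) {
    mij <- .box_sum(D[[i]] * D[[j]], config$patch_radius)[vox]
    M[, i, j] <- mij
    M[, j, i] <- mij
  }
  labmat <- vapply(lab, function(x) as.numeric(x[vox]), numeric(length(vox)))
  ones <- rep(1, n)
  votes <- numeric(length(vox))
  n_singular <- 0L
  for (v in seq_along(vox)) {
    Mv <- M[v, , ] + diag(config$ridge, n)
    w <- tryCatch(solve(Mv, ones), error = function(e) NULL)
    if (is.null(w) || any(!is.finite(w)) || sum(w) == 0) {
      n_singular <- n_singular + 1L
      w <- ones / n
    } else {
      w <- w / sum(w)
      if (any(w < 0)) {            # clip-and-renormalize policy
        w[w < 0] <- 0
        w <- w / sum(w)
      }
    }
    votes[v] <- sum(w * labmat[v, ])
  }
  if (n_singular > 0L)
    warning("joint label fusion: ", n_singular,
            " voxels fell back to uniform weights (singular system)")
  fused[vox] <- as.integer(votes >= 0.5)
  fused
}

#' Leave-one-out multi-atlas fusion protocol
#'
#' For each subject in a cohort of (intensity, manual label) pairs, the
#' remaining subjects serve as atlases (mapped by `map_atlas`; the
#' default identity mapping assumes a pre-aligned cohort, as produced by
#' the synthetic phantom generator). Their labels are fused by majority
#' voting or joint label fusion and scored against the left-out subject's
#' own manual label.
#'
#' @param cohort list of at least 3 `list(intensity, label)` pairs on a
#'   common grid.
#' @param fuse `"mv"` or `"jlf"`.
#' @param config a [fusion_config()].
#' @param spacing_mm voxel spacing for the surface-distance metrics.
#' @param map_atlas function `(atlas, target_intensity) -> atlas`
#'   registering an atlas into the target's space; default identity.
#' @return List with `segmentations` (per-subject fused masks) and
#'   `metrics` (data.frame: subject, dsc, specificity, sensitivity,
#'   masd_mm, max_surface_distance_mm, rvd_percent).
#' @export
loo_fusion_protocol <- function(cohort, fuse = c("mv", "jlf"),
                                config = fusion_config(),
                                spacing_mm = c(1, 1, 1),
                                map_atlas = NULL) {
  fuse <- match.arg(fuse)
  if (length(cohort) < 3L)
    stop("leave-one-out fusion needs a cohort of at least 3 subjects")
  if (is.null(map_atlas)) map_atlas <- function(atlas, target) atlas
  segs <- vector("list", length(cohort))
  rows <- vector("list", length(cohort))
  for (s in seq_along(cohort)) {
    target <- cohort[[s]]
    atl <- lapply(cohort[-s], map_atlas, target = target$intensity)
    labs <- lapply(atl, `[[`, "label")
    mask <- boundary_uncertainty_mask(labs)
    fused <- if (fuse == "mv") {
      majority_vote(labs, mask, tie_rule = config$tie_rule)
    } else {
      joint_label_fusion(list(atlases = atl, target_intensity = target$intensity),
                         mask, config)
    }
    segs[[s]] <- fused
    sc <- seg_score(fused, target$label, spacing_mm)
    rows[[s]] <- data.frame(subject = s, as.data.frame(sc))
  }
  list(segmentations = segs, metrics = do.call(rbind, rows))
}
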