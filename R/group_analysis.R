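# Jonker-style Hungarian algorithm for the square linear assignment
# problem (minimization). Returns ans[i] = column assigned to row i.
# Deterministic: cost ties resolve to the lowest column index.
.solve_lsap_min <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n)
  v <- numeric(n + 1)     # v[1] belongs to the virtual column 0
  p <- integer(n + 1)     # p[j+1]: row currently assigned to column j
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    way <- integer(n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0L) ans[p[j + 1]] <- j
  ans
}

#' Group-level similarity matrix
#'
#' Element-wise mean of per-subject seed similarity matrices on a common
#' template-space voxel set, with entries below `threshold` set to 0 and
#' the diagonal restored to 1.
#'
#' @param per_subject_sims list of at least 2 [similarity_matrix()]s of
#'   identical dimension and voxel order.
#' @param threshold entries of the mean matrix strictly below this are
#'   zeroed (default 0: plain mean).
#' @return A [similarity_matrix()].
#' @export
group_similarity <- function(per_subject_sims, threshold = 0) {
  stopifnot(length(per_subject_sims) >= 2L)
  vals <- lapply(per_subject_sims, function(s) {
    stopifnot(inherits(s, "cbp_similarity")); s$values
  })
  dims <- vapply(vals, nrow, integer(1))
  if (length(unique(dims)) != 1L)
    stop("misaligned voxel sets: similarity matrices differ in size")
  m <- Reduce(`+`, vals) / length(vals)
  m[m < threshold] <- 0
  diag(m) <- 1
  similarity_matrix(m)
}

# Overlap contingency: rows = clusters of p, cols = clusters of ref,
# counted over the common voxel support.
.overlap_table <- function(p, reference) {
  if (is.null(p$seeds) || is.null(reference$seeds)) {
    if (length(p$labels) != length(reference$labels))
      stop("parcellations without coordinates must share seed order")
    lab_p <- p$labels; lab_r <- reference$labels
  } else {
    shp <- p$seeds$reference_shape
    if (!identical(shp, reference$seeds$reference_shape))
      stop("parcellations live in different grids")
    ip <- .coords_to_index(p$seeds$coords, shp)
    ir <- .coords_to_index(reference$seeds$coords, shp)
    common <- intersect(ip, ir)
    lab_p <- p$labels[match(common, ip)]
    lab_r <- reference$labels[match(common, ir)]
  }
  tab <- matrix(0L, p$k, reference$k)
  if (length(lab_p))
    for (idx in seq_along(lab_p))
      tab[lab_p[idx], lab_r[idx]] <- tab[lab_p[idx], lab_r[idx]] + 1L
  tab
}

#' Harmonize cluster labels against a reference parcellation
#'
#' One-to-one relabeling of the subject's clusters that maximizes the
#' total voxel overlap with the reference, solved as a linear assignment
#' (Hungarian algorithm). Voxel membership is unchanged; only cluster
#' names move. Ties (including zero overlap) resolve deterministically to
#' the lowest-index matching.
#'
#' @param subject,reference [parcellation()]s with the same k and
#'   overlapping voxel support.
#' @return The subject parcellation with relabeled clusters, flagged
#'   `harmonized`; the applied permutation (new label per old cluster) is
#'   attached as attribute `"permutation"`.
#' @export
harmonize_labels <- function(subject, reference) {
  stopifnot(inherits(subject, "cbp_parcellation"),
            inherits(reference, "cbp_parcellation"))
  if (subject$k != reference$k)
    stop("k mismatch: subject has ", subject$k, ", reference has ",
         reference$k)
  if (subject$k == 1L) {
    subject$harmonized <- TRUE
    attr(subject, "permutation") <- 1L
    return(subject)
  }
  ov <- .overlap_table(subject, reference)
  perm <- .solve_lsap_min(max(ov) - ov)
  out <- parcellation(subject$seeds, perm[subject$labels], subject$k,
                      space_tag = subject$space_tag, harmonized = TRUE)
  attr(out, "permutation") <- perm
  attr(out, "total_overlap") <- sum(ov[cbind(seq_len(subject$k), perm)])
  out
}

#' Mirror a parcellation across a midline plane
#'
#' Reflects the voxel coordinates along one axis of the reference grid
#' (`x -> shape - 1 - x`), leaving labels unchanged. Used to compare or
#' harmonize homologous regions of the two hemispheres.
#'
#' @param p a [parcellation()] with seed coordinates.
#' @param axis axis to flip (1 = x, the usual left-right axis).
#' @return The mirrored [parcellation()].
#' @export
mirror_parcellation <- function(p, axis = 1L) {
  stopifnot(inherits(p, "cbp_parcellation"), !is.null(p$seeds))
  coords <- p$seeds$coords
  coords[, axis] <- p$seeds$reference_shape[axis] - 1L - coords[, axis]
  ord <- order(coords[, 3], coords[, 2], coords[, 1])
  parcellation(voxel_coords(coords[ord, , drop = FALSE],
                            p$seeds$reference_shape),
               p$labels[ord], p$k, space_tag = p$space_tag,
               harmonized = p$harmonized)
}

#' Enforce label consistency across hemispheres
#'
#' Relabels the right-hemisphere group reference by harmonizing it
#' against the mirrored left reference, then harmonizes every subject of
#' each side to its side's reference, so homologous clusters carry the
#' same label bilaterally.
#'
#' @param left,right lists with elements `reference` (a [parcellation()])
#'   and `subjects` (list of [parcellation()]s), one per hemisphere, with
#'   a common k.
#' @param flip_axis midline axis for [mirror_parcellation()] (default 1).
#' @return List with relabeled `left` and `right` cohorts.
#' @export
enforce_hemispheric_consistency <- function(left, right, flip_axis = 1L) {
  stopifnot(inherits(left$reference, "cbp_parcellation"),
            inherits(right$reference, "cbp_parcellation"))
  if (left$reference$k != right$reference$k)
    stop("k mismatch between hemispheres")
  mirrored_left <- mirror_parcellation(left$reference, flip_axis)
  right$reference <- harmonize_labels(right$reference, mirrored_left)
  left$reference$harmonized <- TRUE
  left$subjects <- lapply(left$subjects, harmonize_labels, reference = left$reference)
  right$subjects <- lapply(right$subjects, harmonize_labels,
                           reference = right$reference)
  list(left = left, right = right)
}

#' Voxelwise cluster-frequency maps across subjects
#'
#' For every voxel in the union of the subjects' template-space seed
#' sets, the fraction of subjects assigning it to each cluster, plus the
#' fraction of subjects whose ROI excludes it. At every voxel the cluster
#' frequencies and the missing fraction sum to 1 exactly.
#'
#' @param cohort list of harmonized [parcellation()]s with a common k and
#'   a common reference grid.
#' @param require_harmonized error (default) if a multi-subject cohort
#'   contains parcellations not flagged as harmonized.
#' @return Object of class `cbp_cohort_maps`: `voxels` ([voxel_coords()]
#'   over the union), `freq` (voxels x k matrix), `missing_fraction`,
#'   `k`, `n_subjects`.
#' @export
probabilistic_maps <- function(cohort, require_harmonized = TRUE) {
  stopifnot(length(cohort) >= 1L,
            all(vapply(cohort, inherits, logical(1), "cbp_parcellation")))
  k <- cohort[[1]]$k
  if (!all(vapply(cohort, `[[`, integer(1), "k") == k))
    stop("all subjects must share one k")
  if (length(cohort) > 1L && require_harmonized &&
      !all(vapply(cohort, `[[`, logical(1), "harmonized")))
    stop("cohort contains unharmonized parcellations; ",
         "run harmonize_labels() first")
  shp <- cohort[[1]]$seeds$reference_shape
  idx_list <- lapply(cohort, function(p) {
    if (!identical(p$seeds$reference_shape, shp))
      stop("subjects live in different grids")
    .coords_to_index(p$seeds$coords, shp)
  })
  union_idx <- sort(unique(unlist(idx_list)))
  n <- length(cohort)
  counts <- matrix(0L, length(union_idx), k)
  present <- integer(length(union_idx))
  for (s in seq_len(n)) {
    pos <- match(idx_list[[s]], union_idx)
    present[pos] <- present[pos] + 1L
    counts[cbind(pos, cohort[[s]]$labels)] <-
      counts[cbind(pos, cohort[[s]]$labels)] + 1L
  }
  vox <- arrayInd(union_idx, shp) - 1L
  colnames(vox) <- c("x", "y", "z")
  structure(list(voxels = voxel_coords(vox, shp),
                 freq = counts / n,
                 missing_fraction = (n - present) / n,
                 k = k, n_subjects = n),
            class = "cbp_cohort_maps")
}

#' @export
print.cbp_cohort_maps <- function(x, ...) {
  cat("<cbp_cohort_maps> ", nrow(x$freq), " voxels, k=", x$k, ", ",
      x$n_subjects, " subjects\n", sep = "")
  invisible(x)
}

#' Maximum probability map
#'
#' Assigns every ROI voxel to the cluster most subjects assign it to.
#' Under the default rule a voxel keeps a label only when its winning
#' cluster frequency strictly exceeds its missing fraction (the voxel is
#' more likely to belong to that cluster than to no cluster); otherwise
#' it is background. Frequency ties break to the lowest cluster index.
#'
#' @param maps a `cbp_cohort_maps` from [probabilistic_maps()].
#' @param rule `"exceed_missing"` (default) or `"always"` (every union
#'   voxel gets its argmax label).
#' @param spacing voxel spacing for the output volume.
#' @return A [label_volume()] with the winning probability per voxel
#'   attached as attribute `"winning_prob"` (array).
#' @export
maximum_probability_map <- function(maps, rule = c("exceed_missing", "always"),
                                    spacing = c(1, 1, 1)) {
  rule <- match.arg(rule)
  stopifnot(inherits(maps, "cbp_cohort_maps"))
  win_lab <- max.col(maps$freq, ties.method = "first")
  win_p <- maps$freq[cbind(seq_len(nrow(maps$freq)), win_lab)]
  if (rule == "exceed_missing")
    win_lab[win_p <= maps$missing_fraction] <- 0L
  shp <- maps$voxels$reference_shape
  arr <- array(0L, shp)
  idx <- .coords_to_index(maps$voxels$coords, shp)
  arr[idx] <- win_lab
  out <- label_volume(arr, spacing = spacing, space_tag = "template")
  wp <- array(0, shp)
  wp[idx] <- win_p
  attr(out, "winning_prob") <- wp
  out
}

# Per-label counts among the 6 face neighbors of every voxel.
.neighbor_label_counts <- function(arr, k) {
  d <- dim(arr)
  padded <- array(0L, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  shifts <- list(
    padded[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)],
    padded[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)],
    padded[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)],
    padded[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)],
    padded[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]],
    padded[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)])
  counts <- array(0L, c(length(arr), k))
  for (s in shifts) {
    v <- as.vector(s)
    fg <- v > 0L
    counts[cbind(which(fg), v[fg])] <- counts[cbind(which(fg), v[fg])] + 1L
  }
  counts
}

#' Smooth a maximum probability map by neighbor voting
#'
#' Synchronous relabeling passes: a foreground voxel whose label differs
#' from the strict majority label of its six face neighbors (background
#' neighbors do not vote; voxels with fewer than 2 foreground neighbors
#' are left alone) takes that majority label. Iterates to a fixed point
#' or `max_iters`. Background is never expanded or shrunk, so the
#' foreground voxel count is conserved.
#'
#' @param mpm a [label_volume()].
#' @param max_iters maximum number of synchronous passes (default 10).
#' @return The smoothed [label_volume()]; the number of passes performed
#'   is attached as attribute `"iterations"`.
#' @export
smooth_mpm <- function(mpm, max_iters = 10L) {
  stopifnot(inherits(mpm, "cbp_label_volume"))
  arr <- mpm$data
  k <- max(arr)
  if (k == 0L) return(mpm)
  iters <- 0L
  repeat {
    if (iters >= max_iters) break
    counts <- .neighbor_label_counts(arr, k)
    nf <- rowSums(counts)
    maj_lab <- max.col(counts, ties.method = "first")
    maj_n <- counts[cbind(seq_len(nrow(counts)), maj_lab)]
    cur <- as.vector(arr)
    change <- cur > 0L & nf >= 2L & maj_n * 2L > nf & maj_lab != cur
    if (!any(change)) break
    cur[change] <- maj_lab[change]
    arr <- array(cur, dim(arr))
    iters <- iters + 1L
  }
  out <- mpm
  out$data <- array(as.integer(arr), dim(arr))
  attr(out, "iterations") <- iters
  out
}

#' Group-level parcellation pipeline for one k
#'
#' The group reference is a spectral parcellation of the (thresholded)
#' group similarity matrix; every subject is parcellated at the same k,
#' harmonized to the reference by maximum-overlap assignment, and the
#' cohort's probabilistic maps, maximum probability map and smoothed MPM
#' are derived.
#'
#' @param per_subject_sims list of per-subject [similarity_matrix()]s on
#'   a common template-space voxel set.
#' @param seeds the common [voxel_coords()] seed list.
#' @param k number of clusters.
#' @param threshold group-matrix threshold (default 0).
#' @param seed_rng RNG seed for the clustering stages.
#' @param subject_parcellations optional precomputed list of per-subject
#'   [parcellation()]s at this k (skips the per-subject clustering).
#' @param smooth_iters passes for [smooth_mpm()].
#' @return List with `reference`, `subjects` (harmonized), `maps`,
#'   `mpm`, `mpm_smoothed`.
#' @export
group_pipeline <- function(per_subject_sims, seeds, k, threshold = 0,
                           seed_rng = 1L, subject_parcellations = NULL,
                           smooth_iters = 10L) {
  n <- length(per_subject_sims)
  if (is.null(subject_parcellations)) {
    subject_parcellations <- lapply(seq_len(n), function(s)
      spectral_parcellate(per_subject_sims[[s]], k, seed_rng = seed_rng + s,
                          seeds = seeds, space_tag = "template"))
  }
  reference <- if (n >= 2L) {
    gs <- group_similarity(per_subject_sims, threshold)
    spectral_parcellate(gs, k, seed_rng = seed_rng, seeds = seeds,
                        space_tag = "template")
  } else {
    subject_parcellations[[1]]
  }
  harmonized <- lapply(subject_parcellations, harmonize_labels,
                       reference = reference)
  maps <- probabilistic_maps(harmonized)
  mpm <- maximum_probability_map(maps)
  list(reference = reference, subjects = harmonized, maps = maps,
       mpm = mpm, mpm_smoothed = smooth_mpm(mpm, smooth_iters))
}
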