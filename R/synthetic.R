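#' Specification of a planted-cluster connectivity cohort
#'
#' Describes a synthetic cohort of seed-by-target streamline-count
#' matrices with known cluster structure: seed voxels occupy a small 3D
#' ROI split into `true_k` contiguous slabs along its longest axis; each
#' cluster has a distinct prototype connectivity profile, a probability
#' vector placing `within_cluster_profile_correlation` of its mass on
#' the cluster's own target block, `shared_fraction` on a target block
#' common to every cluster (real subregions of one ROI share a large set
#' of common pathways, which is what gives neighboring subregions their
#' positive profile correlation), and the remainder uniformly. Each seed
#' row is the prototype perturbed by multiplicative log-normal noise and
#' realized as a multinomial draw of `n_samples` streamline counts. Per
#' subject, a `subject_jitter` fraction of voxels flips to a random
#' other cluster, emulating inter-individual variability.
#'
#' @param n_subjects number of subjects (default 10).
#' @param n_seed_voxels number of seed voxels (default 300).
#' @param roi_shape ROI extent; must hold the seed voxels (default
#'   `c(12, 5, 5)`).
#' @param true_k planted number of clusters (default 4).
#' @param n_targets number of target voxels (default 300).
#' @param within_cluster_profile_correlation fraction of each prototype's
#'   probability mass on its own target block, the main driver of the
#'   realized within-cluster profile correlation (default 0.45, which
#'   under the default noise yields within-cluster count correlations
#'   around 0.85 and between-cluster correlations around 0.15).
#' @param shared_fraction fraction of every prototype's mass on the
#'   common target block (default 0.45).
#' @param noise_sd standard deviation of the log-normal profile
#'   perturbation (default 0.3).
#' @param subject_jitter fraction of voxels whose membership flips per
#'   subject, in [0, 0.5) (default 0.05).
#' @param n_samples streamlines sampled per seed voxel (default 10000).
#' @param rng_seed integer seed (default 1).
#' @return A list of class `cbp_cohort_spec`.
#' @export
planted_cohort_spec <- function(n_subjects = 10L, n_seed_voxels = 300L,
                                roi_shape = c(12L, 5L, 5L), true_k = 4L,
                                n_targets = 300L,
                                within_cluster_profile_correlation = 0.45,
                                shared_fraction = 0.45,
                                noise_sd = 0.3, subject_jitter = 0.05,
                                n_samples = 10000L, rng_seed = 1L) {
  stopifnot(true_k >= 2L, subject_jitter >= 0, subject_jitter < 0.5,
            noise_sd >= 0, n_subjects >= 1L,
            within_cluster_profile_correlation > 0, shared_fraction >= 0,
            within_cluster_profile_correlation + shared_fraction <= 1,
            prod(roi_shape) >= n_seed_voxels)
  if (true_k > n_seed_voxels) stop("more clusters than seed voxels")
  if (true_k + 1L > n_targets) stop("more clusters than target voxels")
  structure(as.list(environment()), class = "cbp_cohort_spec")
}

# Planted labels: contiguous slabs along the ROI's first axis.
.planted_labels <- function(spec) {
  shp <- spec$roi_shape
  vox <- arrayInd(seq_len(spec$n_seed_voxels), shp) - 1L
  colnames(vox) <- c("x", "y", "z")
  breaks <- seq(0, shp[1], length.out = spec$true_k + 1)
  labels <- as.integer(cut(vox[, 1], breaks, labels = FALSE,
                           include.lowest = TRUE, right = FALSE))
  labels <- pmin(pmax(labels, 1L), spec$true_k)
  list(coords = vox, labels = labels)
}

#' Generate a planted-cluster connectivity cohort
#'
#' @param spec a [planted_cohort_spec()].
#' @return List with `subjects` (per-subject [connectivity_matrix()]s),
#'   `subject_labels` (per-subject planted labels including jitter
#'   flips), `true_labels` (the jitter-free planting), `seeds`
#'   ([voxel_coords()]), `prototypes` (true_k x n_targets probability
#'   profiles), and `spec`. Deterministic given `spec$rng_seed`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cbp_cohort_spec"))
  plant <- .planted_labels(spec)
  seeds <- voxel_coords(plant$coords, spec$roi_shape)
  .with_seed(spec$rng_seed, {
    w <- spec$within_cluster_profile_correlation
    sh <- spec$shared_fraction
    # target blocks: 0 = shared pathways, 1..true_k = cluster-specific
    block <- as.integer(cut(seq_len(spec$n_targets), spec$true_k + 1L,
                            labels = FALSE)) - 1L
    proto <- t(vapply(seq_len(spec$true_k), function(c) {
      p <- rep((1 - w - sh) / spec$n_targets, spec$n_targets)
      p[block == 0L] <- p[block == 0L] + sh / sum(block == 0L)
      p[block == c] <- p[block == c] + w / sum(block == c)
      p
    }, numeric(spec$n_targets)))
    subjects <- vector("list", spec$n_subjects)
    subject_labels <- vector("list", spec$n_subjects)
    for (s in seq_len(spec$n_subjects)) {
      lab <- plant$labels
      n_flip <- round(spec$subject_jitter * length(lab))
      if (n_flip > 0) {
        flip <- sample(length(lab), n_flip)
        lab[flip] <- vapply(lab[flip], function(old)
          sample(setdiff(seq_len(spec$true_k), old), 1L), integer(1))
      }
      counts <- matrix(0L, length(lab), spec$n_targets)
      for (i in seq_along(lab)) {
        rate <- proto[lab[i], ] *
          exp(stats::rnorm(spec$n_targets, sd = spec$noise_sd))
        counts[i, ] <- as.integer(
          stats::rmultinom(1, spec$n_samples, rate / sum(rate)))
      }
      subjects[[s]] <- connectivity_matrix(counts, seeds = seeds,
                                           n_samples = spec$n_samples)
      subject_labels[[s]] <- lab
    }
    list(subjects = subjects, subject_labels = subject_labels,
         true_labels = plant$labels, seeds = seeds, prototypes = proto,
         spec = spec)
  })
}

#' Specification of a synthetic head phantom cohort
#'
#' An ellipsoidal "brain" inside a cubic grid. Every subject shares the
#' underlying shape; independent smooth boundary jitter deforms each
#' subject's own brain boundary and Gaussian noise corrupts its
#' intensities. A subject's manual-truth label is its own jittered
#' shape, and its intensity image is bright inside that shape, so
#' atlases whose shapes match a target better also match its intensities
#' better, as with real anatomy.
#'
#' @param grid_shape cubic grid extent (default `c(24, 24, 24)`).
#' @param center ellipsoid center in 0-based voxels (grid center if
#'   `NULL`).
#' @param radii ellipsoid semi-axes in voxels (default `c(8, 9, 7)`).
#' @param intensity_brain,intensity_background tissue intensities
#'   (defaults 100 and 20).
#' @param boundary_jitter_sd SD of the smooth boundary displacement, in
#'   voxels (default 1).
#' @param intensity_noise_sd SD of the additive intensity noise
#'   (default 5).
#' @param rng_seed integer seed.
#' @return A list of class `cbp_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24L, 24L, 24L), center = NULL,
                         radii = c(8, 9, 7), intensity_brain = 100,
                         intensity_background = 20,
                         boundary_jitter_sd = 1, intensity_noise_sd = 5,
                         rng_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(center)) center <- (grid_shape - 1) / 2
  stopifnot(boundary_jitter_sd >= 0, intensity_noise_sd >= 0,
            all(radii > 0))
  if (any(center - radii < 0) || any(center + radii > grid_shape - 1))
    stop("ellipsoid does not fit the grid")
  structure(list(grid_shape = grid_shape, center = center, radii = radii,
                 intensity_brain = intensity_brain,
                 intensity_background = intensity_background,
                 boundary_jitter_sd = boundary_jitter_sd,
                 intensity_noise_sd = intensity_noise_sd,
                 rng_seed = rng_seed),
            class = "cbp_phantom_spec")
}

# Smooth unit-variance Gaussian random field (box-smoothed white noise).
.smooth_field <- function(shape, smooth_radius = 2L) {
  f <- .box_sum(array(stats::rnorm(prod(shape)), shape), smooth_radius)
  s <- stats::sd(as.vector(f))
  if (s == 0) return(array(0, shape))
  f / s
}

#' Generate a cohort of head phantoms with manual-truth labels
#'
#' @param spec a [phantom_spec()].
#' @param n_subjects cohort size.
#' @return List of `n_subjects` elements `list(intensity, label)`, each
#'   on the common grid; deterministic given `spec$rng_seed`.
#' @export
generate_atlas_cohort <- function(spec, n_subjects) {
  stopifnot(inherits(spec, "cbp_phantom_spec"), n_subjects >= 1L)
  shp <- spec$grid_shape
  vox <- arrayInd(seq_len(prod(shp)), shp) - 1L
  # approximate signed distance (voxels) to the ellipsoid surface
  r <- sqrt(((vox[, 1] - spec$center[1]) / spec$radii[1])^2 +
            ((vox[, 2] - spec$center[2]) / spec$radii[2])^2 +
            ((vox[, 3] - spec$center[3]) / spec$radii[3])^2)
  dist0 <- array((r - 1) * min(spec$radii), shp)
  .with_seed(spec$rng_seed, {
    lapply(seq_len(n_subjects), function(s) {
      d <- dist0 + spec$boundary_jitter_sd * .smooth_field(shp)
      lab <- array(as.integer(d < 0), shp)
      intensity <- ifelse(lab == 1L, spec$intensity_brain,
                          spec$intensity_background) +
        stats::rnorm(length(lab), sd = spec$intensity_noise_sd)
      list(intensity = array(intensity, shp), label = lab)
    })
  })
}

#' Build a mirrored bilateral cohort from a planted cohort
#'
#' Places the planted ROI in the right half of a widened grid and its
#' mirror image in the left half, optionally scrambling the right-side
#' labels with a fixed permutation, to exercise hemispheric label
#' consistency.
#'
#' @param p a template-space [parcellation()] (e.g. a planted labeling).
#' @param scramble optional permutation of `1:k` applied to the mirrored
#'   copy's labels.
#' @return List with `left` and `right` [parcellation()]s in a common
#'   doubled grid (mirror axis 1).
#' @export
bilateral_pair <- function(p, scramble = NULL) {
  stopifnot(inherits(p, "cbp_parcellation"), !is.null(p$seeds))
  shp <- p$seeds$reference_shape
  big <- c(2L * shp[1], shp[2], shp[3])
  right_coords <- p$seeds$coords
  right_coords[, 1] <- right_coords[, 1] + shp[1]
  left_coords <- p$seeds$coords
  left_coords[, 1] <- shp[1] - 1L - left_coords[, 1]
  mk <- function(coords, labels) {
    ord <- order(coords[, 3], coords[, 2], coords[, 1])
    parcellation(voxel_coords(coords[ord, , drop = FALSE], big),
                 labels[ord], p$k, space_tag = "template")
  }
  right_labels <- if (is.null(scramble)) p$labels else scramble[p$labels]
  list(left = mk(left_coords, p$labels), right = mk(right_coords, right_labels))
}
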