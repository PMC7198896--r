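test_that("cohort generation is a pure function of its seed", {
  spec <- planted_cohort_spec(n_subjects = 2L, n_seed_voxels = 40L,
                              roi_shape = c(5L, 4L, 2L), true_k = 2L,
                              n_targets = 50L, n_samples = 1000L,
                              rng_seed = 99L)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$subjects[[1]]$counts, c2$subjects[[1]]$counts)
  expect_identical(c1$subject_labels, c2$subject_labels)
  c3 <- generate_cohort(planted_cohort_spec(n_subjects = 2L,
                                            n_seed_voxels = 40L,
                                            roi_shape = c(5L, 4L, 2L),
                                            true_k = 2L, n_targets = 50L,
                                            n_samples = 1000L, rng_seed = 100L))
  expect_false(identical(c1$subjects[[1]]$counts, c3$subjects[[1]]$counts))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(runif(1))
  invisible(generate_cohort(planted_cohort_spec(n_subjects = 1L,
                                                n_seed_voxels = 20L,
                                                roi_shape = c(5L, 2L, 2L),
                                                true_k = 2L, n_targets = 30L,
                                                n_samples = 500L)))
  expect_identical(runif(2), before[2:3])
})

test_that("counts are non-negative integers with row sums equal to n_samples", {
  coh <- small_cohort()
  for (s in coh$subjects) {
    expect_true(all(s$counts >= 0))
    expect_true(all(s$counts == round(s$counts)))
    expect_true(all(rowSums(s$counts) == s$n_samples))
  }
})

test_that("noise-free cohorts have near-perfect within-cluster correlation", {
  coh <- generate_cohort(planted_cohort_spec(
    n_subjects = 1L, n_seed_voxels = 60L, roi_shape = c(6L, 5L, 2L),
    true_k = 3L, n_targets = 90L, noise_sd = 0, subject_jitter = 0,
    n_samples = 20000L, rng_seed = 7L))
  s <- cross_correlation(coh$subjects[[1]])$values
  lab <- coh$true_labels
  same <- outer(lab, lab, `==`) & upper.tri(s)
  diff_ <- !outer(lab, lab, `==`) & upper.tri(s)
  expect_gt(min(s[same]), 0.99)
  expect_gt(mean(s[same]), mean(s[diff_]))
})

test_that("planted clusters are contiguous slabs along the first axis", {
  coh <- small_cohort()
  x <- coh$seeds$coords[, 1]
  for (c in 1:2) expect_lt(max(x[coh$true_labels == c]),
                           min(x[coh$true_labels == c + 1]) + 1)
  p <- parcellation(coh$seeds, coh$true_labels)
  expect_equal(continuity_index(p), 1)
})

test_that("subject jitter flips roughly the requested fraction of voxels", {
  coh <- small_cohort()
  frac <- vapply(coh$subject_labels, function(l)
    mean(l != coh$true_labels), numeric(1))
  expect_true(all(frac > 0))
  expect_true(all(abs(frac - 0.05) < 0.03))
})

test_that("infeasible cohort specifications are rejected", {
  expect_error(planted_cohort_spec(n_seed_voxels = 10L,
                                   roi_shape = c(2L, 2L, 2L)), "roi_shape")
  expect_error(planted_cohort_spec(true_k = 50L, n_seed_voxels = 20L,
                                   roi_shape = c(20L, 1L, 1L),
                                   n_targets = 30L), "more clusters")
  expect_error(planted_cohort_spec(subject_jitter = 0.6), "jitter")
  expect_error(planted_cohort_spec(within_cluster_profile_correlation = 0.7,
                                   shared_fraction = 0.5), "<= 1")
})

test_that("phantom cohorts are deterministic and anatomically plausible", {
  spec <- phantom_spec(rng_seed = 3L)
  c1 <- generate_atlas_cohort(spec, 3)
  c2 <- generate_atlas_cohort(spec, 3)
  expect_identical(c1[[2]]$label, c2[[2]]$label)
  expect_equal(c1[[2]]$intensity, c2[[2]]$intensity)
  # brain voxels are brighter than background on average
  lab <- c1[[1]]$label
  expect_gt(mean(c1[[1]]$intensity[lab == 1L]),
            mean(c1[[1]]$intensity[lab == 0L]) + 50)
  # subjects share the shape up to boundary jitter
  expect_gt(overlap_metrics(c1[[1]]$label, c1[[2]]$label)$dsc, 0.6)
  expect_lt(overlap_metrics(c1[[1]]$label, c1[[2]]$label)$dsc, 1)
})

test_that("an ellipsoid larger than its grid is rejected", {
  expect_error(phantom_spec(grid_shape = c(10L, 10L, 10L),
                            radii = c(8, 4, 4)), "does not fit")
})

test_that("bilateral pairs mirror geometry and optionally scramble labels", {
  coh <- small_cohort()
  p <- parcellation(coh$seeds, coh$true_labels, space_tag = "template")
  pair <- bilateral_pair(p)
  shp <- p$seeds$reference_shape
  expect_identical(pair$left$seeds$reference_shape[1], 2L * shp[1])
  # mirroring the left recovers the right's voxel set
  lm <- mirror_parcellation(pair$left)
  expect_identical(lm$seeds$coords, pair$right$seeds$coords)
  expect_identical(lm$labels, pair$right$labels)
  scr <- c(2L, 3L, 1L)
  pair2 <- bilateral_pair(p, scramble = scr)
  lm2 <- mirror_parcellation(pair2$left)
  expect_identical(scr[lm2$labels], pair2$right$labels)
})
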