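test_that("agreement indices match direct contingency-table computation", {
  set.seed(71)
  for (rep in 1:10) {
    n <- 80
    l1 <- sample(1:3, n, replace = TRUE)
    l2 <- l1; l2[sample(n, 15)] <- sample(1:3, 15, replace = TRUE)
    ag <- partition_agreement(l1, l2)
    mi <- oracle_label_mi(l1, l2)
    expect_equal(ag$nmi, 2 * mi$mi / (mi$h1 + mi$h2), tolerance = 1e-9)
    expect_equal(ag$vi, mi$h1 + mi$h2 - 2 * mi$mi, tolerance = 1e-9)
    chi2 <- suppressWarnings(
      stats::chisq.test(table(l1, l2), correct = FALSE)$statistic)
    expect_equal(ag$cramers_v, sqrt(unname(chi2) / (n * 2)), tolerance = 1e-9)
  }
})

test_that("matched-cluster Dice is computed after harmonizing labels", {
  l1 <- rep(1:2, each = 4)
  l2 <- c(2, 2, 2, 1, 1, 1, 1, 1)   # flipped names, one voxel moved
  ag <- partition_agreement(l1, l2)
  # after matching (1<->2): cluster 1 overlap 3 of (4+3), cluster 2 overlap 4 of (4+5)
  expect_equal(ag$dice, mean(c(2 * 3 / 7, 2 * 4 / 9)))
})

test_that("agreement indices hit their extremes for identical and permuted labels", {
  l <- rep(1:4, times = c(5, 7, 3, 5))
  ag <- partition_agreement(l, l)
  expect_equal(ag$dice, 1)
  expect_equal(ag$nmi, 1)
  expect_equal(ag$vi, 0)
  expect_equal(ag$cramers_v, 1)
  perm <- c(4L, 1L, 3L, 2L)
  ag2 <- partition_agreement(l, perm[l])
  expect_equal(ag2$dice, 1)
  expect_equal(ag2$nmi, 1)
})

test_that("Dice is undefined across different cluster counts, other indices not", {
  ag <- partition_agreement(rep(1:2, 10), rep(1:4, 5))
  expect_true(is.na(ag$dice))
  expect_false(is.na(ag$nmi))
})

test_that("mean silhouette matches the per-voxel loop oracle", {
  set.seed(72)
  coh <- small_cohort()
  sim <- cross_correlation(threshold_counts(coh$subjects[[1]]))
  labels <- coh$subject_labels[[1]]
  got <- silhouette_mean(sim, labels)
  want <- oracle_silhouette(1 - sim$values, labels)
  expect_equal(got, want, tolerance = 1e-9)
  expect_gt(got, 0.5)   # planted blocks are well separated
})

test_that("continuity is one for contiguous slabs and drops when clusters fragment", {
  co <- voxel_coords(cbind(0:11, 0L, 0L), c(12L, 1L, 1L))
  expect_equal(continuity_index(parcellation(co, rep(1:3, each = 4))), 1)
  # cluster 1 split 3+1 across the line, cluster 2 contiguous
  frag <- parcellation(co, c(1, 1, 1, 2, 2, 2, 2, 2, 2, 2, 2, 1))
  expect_equal(continuity_index(frag), mean(c(3 / 4, 1)))
})

test_that("hierarchy index is one exactly for a perfect split", {
  lk <- rep(1:2, each = 6)
  lk1 <- c(rep(1, 6), rep(2, 3), rep(3, 3))   # splits cluster 2
  expect_equal(hierarchy_index(lk, lk1), 1)
  lk1_bad <- c(rep(1, 5), 3, rep(2, 3), rep(3, 3))
  expect_equal(hierarchy_index(lk, lk1_bad), 11 / 12)
  expect_error(hierarchy_index(lk, lk), "one more cluster")
})

test_that("topological distance vanishes for mirror-symmetric hemispheres", {
  coh <- small_cohort()
  p <- parcellation(coh$seeds, coh$true_labels, space_tag = "template")
  pair <- bilateral_pair(p, scramble = c(2L, 3L, 1L))
  expect_equal(topological_distance(pair$left, pair$right), 0)
})

test_that("topological distance counts differing adjacency pairs", {
  shp <- c(4L, 1L, 4L)
  co <- mask_to_coords(label_volume(array(1L, shp)))
  # left: chain 1-2-3 stacked along z
  l_arr <- array(0L, shp)
  l_arr[, 1, 1:2] <- 1L; l_arr[, 1, 3] <- 2L; l_arr[, 1, 4] <- 3L
  # right: same stack, but one voxel of cluster 3 reaches down into the
  # z = 3 plane and touches cluster 1, closing the triangle 1-2-3-1
  r_arr <- l_arr
  r_arr[1, 1, 3] <- 3L
  lab_of <- function(arr) arr[co$coords + 1L]
  left <- parcellation(co, lab_of(l_arr), space_tag = "template")
  right <- parcellation(co, lab_of(r_arr), space_tag = "template")
  # adjacency sets {1-2, 2-3} vs {1-2, 2-3, 1-3}: one unordered pair differs
  expect_equal(topological_distance(left, right), 2 / (3 * 2))
})

test_that("resampled consistency curves are reproducible and well-formed", {
  coh <- small_cohort()
  sims <- cohort_similarities(coh)
  rc1 <- suppressWarnings(resample_consistency(sims, coh$seeds, K = 4,
                                               repetitions = 3, seed_rng = 8))
  rc2 <- suppressWarnings(resample_consistency(sims, coh$seeds, K = 4,
                                               repetitions = 3, seed_rng = 8))
  expect_equal(as.data.frame(rc1), as.data.frame(rc2))
  expect_setequal(unique(rc1$k), 2:4)
  expect_setequal(unique(rc1$index), c("dice", "cramers_v", "nmi", "vi"))
  raw <- attr(rc1, "raw")
  expect_identical(dim(raw), c(3L, 3L, 4L))
  expect_true(all(raw[, , "dice"] >= 0 & raw[, , "dice"] <= 1, na.rm = TRUE))
})

test_that("leave-one-out resampling caps repetitions at the cohort size", {
  coh <- small_cohort()
  sims <- cohort_similarities(coh)
  expect_message(
    rc <- suppressWarnings(resample_consistency(sims, coh$seeds, K = 3,
                                                scheme = "loo",
                                                repetitions = 10, seed_rng = 2)),
    "capping")
  expect_identical(unique(rc$repetitions), 4L)
  expect_error(resample_consistency(sims[1:3], coh$seeds, K = 3),
               "at least 4")
})
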