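test_that("Hungarian assignment attains the exhaustive-enumeration optimum", {
  set.seed(61)
  for (n in 2:5) for (rep in 1:10) {
    cost <- matrix(runif(n * n), n, n)
    got <- cbpkit:::.solve_lsap_min(cost)
    expect_identical(sort(got), seq_len(n))   # a permutation
    want <- oracle_lsap(cost)
    expect_equal(sum(cost[cbind(seq_len(n), got)]), want$min,
                 tolerance = 1e-12)
  }
})

test_that("Hungarian ties resolve to the identity on constant costs", {
  for (n in 2:5)
    expect_identical(cbpkit:::.solve_lsap_min(matrix(1, n, n)), seq_len(n))
})

test_that("harmonization undoes a known label permutation", {
  set.seed(62)
  co <- voxel_coords(cbind(0:23, 0L, 0L), c(24L, 1L, 1L))
  labels <- rep(1:4, each = 6)
  ref <- parcellation(co, labels)
  scram <- c(3L, 1L, 4L, 2L)
  subj <- parcellation(co, scram[labels])
  h <- harmonize_labels(subj, ref)
  expect_identical(h$labels, labels)
  expect_true(h$harmonized)
  expect_identical(attr(h, "total_overlap"), 24L)
  # the permutation attribute maps old cluster names to new ones
  expect_identical(attr(h, "permutation")[subj$labels], h$labels)
})

test_that("harmonization maximizes overlap under noisy membership", {
  set.seed(63)
  co <- voxel_coords(cbind(0:59, 0L, 0L), c(60L, 1L, 1L))
  labels <- rep(1:3, each = 20)
  noisy <- labels
  noisy[sample(60, 8)] <- sample(1:3, 8, replace = TRUE)
  scram <- c(2L, 3L, 1L)
  subj <- parcellation(co, scram[noisy])
  h <- harmonize_labels(subj, parcellation(co, labels))
  expect_identical(h$labels, noisy)
})

test_that("group similarity is the thresholded mean with unit diagonal", {
  s1 <- similarity_matrix(matrix(c(1, 0.6, 0.6, 1), 2, 2))
  s2 <- similarity_matrix(matrix(c(1, -0.2, -0.2, 1), 2, 2))
  g <- group_similarity(list(s1, s2))
  expect_equal(g$values[1, 2], 0.2)
  g_thr <- group_similarity(list(s1, s2), threshold = 0.3)
  expect_equal(g_thr$values[1, 2], 0)
  expect_equal(diag(g_thr$values), c(1, 1))
})

test_that("mirroring twice returns the original parcellation", {
  coh <- small_cohort()
  p <- parcellation(coh$seeds, coh$true_labels, space_tag = "template")
  m2 <- mirror_parcellation(mirror_parcellation(p))
  expect_identical(m2$seeds$coords, p$seeds$coords)
  expect_identical(m2$labels, p$labels)
})

test_that("hemispheric enforcement aligns scrambled homologous labels", {
  coh <- small_cohort()
  p <- parcellation(coh$seeds, coh$true_labels, space_tag = "template")
  pair <- bilateral_pair(p, scramble = c(3L, 1L, 2L))
  out <- enforce_hemispheric_consistency(
    list(reference = pair$left, subjects = list(pair$left)),
    list(reference = pair$right, subjects = list(pair$right)))
  lm <- mirror_parcellation(out$left$reference)
  ov <- cbpkit:::.overlap_table(out$right$reference, lm)
  expect_equal(sum(diag(ov)), length(p$labels))   # perfect diagonal overlap
})

test_that("cluster frequencies and the missing fraction sum to one", {
  co_a <- voxel_coords(cbind(0:9, 0L, 0L), c(12L, 1L, 1L))
  co_b <- voxel_coords(cbind(2:11, 0L, 0L), c(12L, 1L, 1L))
  pa <- parcellation(co_a, rep(1:2, each = 5), harmonized = TRUE)
  pb <- parcellation(co_b, rep(1:2, each = 5), harmonized = TRUE)
  maps <- probabilistic_maps(list(pa, pb))
  expect_identical(nrow(maps$freq), 12L)
  expect_equal(rowSums(maps$freq) + maps$missing_fraction, rep(1, 12))
  # voxels covered by only one subject have missing fraction one half
  expect_equal(maps$missing_fraction[1], 0.5)
  expect_error(probabilistic_maps(list(parcellation(co_a, rep(1:2, each = 5)),
                                       pb)),
               "unharmonized")
})

test_that("the MPM of a single subject reproduces that subject", {
  coh <- small_cohort()
  p <- parcellation(coh$seeds, coh$true_labels, space_tag = "template")
  maps <- probabilistic_maps(list(p))
  mpm <- maximum_probability_map(maps)
  expect_identical(mpm$data, parcellation_to_volume(p)$data)
})

test_that("voxels likelier missing than present drop to background", {
  co_a <- voxel_coords(cbind(0:4, 0L, 0L), c(8L, 1L, 1L))
  co_b <- voxel_coords(cbind(0:7, 0L, 0L), c(8L, 1L, 1L))
  pa <- parcellation(co_a, c(1, 1, 1, 2, 2), harmonized = TRUE)
  pb <- parcellation(co_b, c(1, 1, 1, 2, 2, 2, 2, 2), harmonized = TRUE)
  maps <- probabilistic_maps(list(pa, pb))
  mpm <- maximum_probability_map(maps)            # exceed_missing rule
  expect_true(all(mpm$data[6:8, 1, 1] == 0L))     # win 0.5 <= missing 0.5
  mpm_all <- maximum_probability_map(maps, rule = "always")
  expect_true(all(mpm_all$data[6:8, 1, 1] == 2L))
})

test_that("neighbor-vote smoothing removes speckle, conserves foreground and stops", {
  arr <- array(1L, c(6, 6, 6))
  arr[, , 4:6] <- 2L
  smooth0 <- smooth_mpm(label_volume(arr, space_tag = "template"))
  expect_identical(smooth0$data, arr)             # a slab split is a fixed point
  expect_identical(attr(smooth0, "iterations"), 0L)
  speck <- arr
  speck[3, 3, 1] <- 2L                            # isolated wrong voxel
  sm <- smooth_mpm(label_volume(speck, space_tag = "template"))
  expect_identical(sm$data, arr)
  expect_identical(sum(sm$data > 0L), sum(speck > 0L))
  # idempotence at the fixed point
  expect_identical(smooth_mpm(sm)$data, sm$data)
})

test_that("the group pipeline recovers planted labels in the smoothed map", {
  coh <- small_cohort()
  sims <- cohort_similarities(coh)
  res <- suppressWarnings(group_pipeline(sims, coh$seeds, 3, seed_rng = 4))
  expect_true(all(vapply(res$subjects, `[[`, logical(1), "harmonized")))
  lab <- res$mpm_smoothed$data[
    cbpkit:::.coords_to_index(coh$seeds$coords, coh$seeds$reference_shape)]
  expect_gte(mclust::adjustedRandIndex(lab[lab > 0], coh$true_labels[lab > 0]),
             0.9)
})
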