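test_that("uncertainty mask is the union minus the intersection of the atlases", {
  set.seed(31)
  labs <- lapply(1:5, function(i) random_mask(c(5, 5, 5)))
  got <- boundary_uncertainty_mask(labs)
  u <- labs[[1]] | labs[[2]] | labs[[3]] | labs[[4]] | labs[[5]]
  i <- labs[[1]] & labs[[2]] & labs[[3]] & labs[[4]] & labs[[5]]
  expect_identical(got, u & !i)
})

test_that("majority vote equals the per-voxel modal label for odd and even panels", {
  set.seed(32)
  for (n in c(3, 4, 5, 6)) for (rule in c("background", "foreground")) {
    labs <- lapply(seq_len(n), function(i) random_mask(c(4, 4, 4)))
    fused <- majority_vote(labs, tie_rule = rule)
    stack <- simplify2array(lapply(labs, function(x) array(as.integer(x), dim(x))))
    want <- apply(stack, 1:3, oracle_vote, tie_rule = rule)
    expect_identical(fused, array(as.integer(want), c(4, 4, 4)),
                     info = paste("n =", n, "rule =", rule))
  }
})

test_that("unanimous voxels are copied unchanged outside the uncertainty mask", {
  set.seed(33)
  base <- random_mask(c(5, 5, 5))
  labs <- lapply(1:4, function(i) base)
  labs[[1]][1, 1, 1] <- !labs[[1]][1, 1, 1]   # one disputed voxel
  fused <- majority_vote(labs)
  mask <- boundary_uncertainty_mask(labs)
  expect_identical(fused[!mask], array(as.integer(base), dim(base))[!mask])
})

test_that("box sums match an explicit cubic-window loop", {
  set.seed(34)
  arr <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  for (r in 0:2) {
    got <- cbpkit:::.box_sum(arr, r)
    want <- array(0, dim(arr))
    d <- dim(arr)
    for (i in 1:d[1]) for (j in 1:d[2]) for (l in 1:d[3])
      want[i, j, l] <- sum(arr[max(1, i - r):min(d[1], i + r),
                               max(1, j - r):min(d[2], j + r),
                               max(1, l - r):min(d[3], l + r)])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("joint fusion with identical atlas intensities reduces to majority voting", {
  set.seed(35)
  target <- array(rnorm(125, 50, 10), c(5, 5, 5))
  atl <- lapply(1:5, function(i)
    list(intensity = target + 7, label = random_mask(c(5, 5, 5))))
  jlf <- joint_label_fusion(list(atlases = atl, target_intensity = target))
  mv <- majority_vote(lapply(atl, `[[`, "label"))
  expect_identical(jlf, mv)
})

test_that("an atlas whose intensities match the target dominates the fused label", {
  set.seed(36)
  truth <- array(0L, c(7, 7, 7)); truth[2:6, 2:6, 2:6] <- 1L
  target <- ifelse(truth == 1L, 100, 20) + rnorm(343, sd = 1)
  dim(target) <- c(7, 7, 7)
  # one faithful atlas vs three sharing the same wrong label
  wrong <- truth; wrong[2:6, 2:6, 2] <- 0L
  mk <- function(lab) list(intensity = ifelse(lab == 1L, 100, 20) +
                             array(rnorm(343, sd = 1), c(7, 7, 7)),
                           label = lab)
  atl <- list(mk(truth), mk(wrong), mk(wrong), mk(wrong))
  jlf <- joint_label_fusion(list(atlases = atl, target_intensity = target))
  mv <- majority_vote(lapply(atl, `[[`, "label"))
  expect_gt(overlap_metrics(jlf, truth)$dsc, overlap_metrics(mv, truth)$dsc)
})

test_that("single-atlas fusion copies that atlas", {
  set.seed(37)
  lab <- random_mask(c(4, 4, 4))
  out <- joint_label_fusion(list(
    atlases = list(list(intensity = array(rnorm(64), c(4, 4, 4)), label = lab)),
    target_intensity = array(rnorm(64), c(4, 4, 4))))
  expect_identical(out, array(as.integer(lab), dim(lab)))
})

test_that("leave-one-out fusion is perfect on an identical cohort", {
  spec <- phantom_spec(grid_shape = c(16L, 16L, 16L), radii = c(5, 6, 5),
                       boundary_jitter_sd = 0, intensity_noise_sd = 0)
  coh <- generate_atlas_cohort(spec, 4)
  for (f in c("mv", "jlf")) {
    res <- loo_fusion_protocol(coh, f)
    expect_equal(res$metrics$dsc, rep(1, 4), info = f)
    expect_equal(res$metrics$masd_mm, rep(0, 4), info = f)
  }
  expect_error(loo_fusion_protocol(coh[1:2]), "at least 3")
})
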