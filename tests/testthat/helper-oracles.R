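# Independent brute-force oracles used across the test files. These are
# deliberately naive (loops, set operations, exhaustive enumeration) so
# they share no code path with the package implementations they check.

# Overlap metrics by direct set counting on logical arrays.
oracle_overlap <- function(seg, ref) {
  s <- as.logical(seg); r <- as.logical(ref)
  tp <- sum(s & r); fp <- sum(s & !r); fn <- sum(!s & r); tn <- sum(!s & !r)
  list(dsc = 2 * tp / (2 * tp + fp + fn),
       specificity = tn / (tn + fp),
       sensitivity = tp / (tp + fn))
}

# Boundary voxels of a binary mask: foreground voxels with at least one
# face neighbor outside the mask (off-grid counts as outside).
oracle_boundary <- function(mask) {
  d <- dim(mask)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
    if (!mask[i, j, l]) next
    nb <- rbind(c(i - 1, j, l), c(i + 1, j, l), c(i, j - 1, l),
                c(i, j + 1, l), c(i, j, l - 1), c(i, j, l + 1))
    on_bd <- FALSE
    for (q in 1:6) {
      p <- nb[q, ]
      if (any(p < 1) || any(p > d) || !mask[p[1], p[2], p[3]]) on_bd <- TRUE
    }
    if (on_bd) out <- rbind(out, c(i, j, l))
  }
  out
}

# Symmetric mean / max boundary distance by explicit per-point minimization.
oracle_surface_distances <- function(seg, ref, spacing = c(1, 1, 1)) {
  bs <- oracle_boundary(seg); br <- oracle_boundary(ref)
  one <- function(p, B) {
    min(sqrt(((B[, 1] - p[1]) * spacing[1])^2 +
             ((B[, 2] - p[2]) * spacing[2])^2 +
             ((B[, 3] - p[3]) * spacing[3])^2))
  }
  d_sr <- apply(bs, 1, one, B = br)
  d_rs <- apply(br, 1, one, B = bs)
  list(masd = (mean(d_sr) + mean(d_rs)) / 2, max_sd = max(d_sr, d_rs))
}

# Exhaustive linear assignment: best permutation by full enumeration.
oracle_lsap <- function(cost) {
  n <- nrow(cost)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ,
                 drop = FALSE]
  tot <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  list(min = min(tot),
       argmin = perms[which.min(tot), ])
}

# Entropy (bits) and mutual information of two label vectors by direct
# probability sums.
oracle_entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
oracle_label_mi <- function(l1, l2) {
  n <- length(l1)
  mi <- 0
  for (a in unique(l1)) for (b in unique(l2)) {
    pab <- sum(l1 == a & l2 == b) / n
    if (pab > 0) mi <- mi + pab * log2(pab / ((sum(l1 == a) / n) * (sum(l2 == b) / n)))
  }
  h1 <- oracle_entropy_bits(as.numeric(table(l1)) / n)
  h2 <- oracle_entropy_bits(as.numeric(table(l2)) / n)
  list(mi = mi, h1 = h1, h2 = h2)
}

# Mean silhouette by per-voxel loops on a dissimilarity matrix.
oracle_silhouette <- function(d, labels) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(c)
      mean(d[i, labels == c]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Per-voxel binary vote: strict majority wins, exact ties fall to the rule.
oracle_vote <- function(labs, tie_rule = "background") {
  v <- sum(labs); n <- length(labs)
  if (2 * v > n) return(1L)
  if (2 * v < n) return(0L)
  if (tie_rule == "foreground") 1L else 0L
}

# A small random binary mask with at least one foreground voxel.
random_mask <- function(shape, p = 0.3) {
  repeat {
    m <- array(stats::runif(prod(shape)) < p, shape)
    if (any(m)) return(m)
  }
}

# A small deterministic planted cohort for fast tests.
small_cohort <- function(seed = 5L, n_subjects = 4L) {
  generate_cohort(planted_cohort_spec(
    n_subjects = n_subjects, n_seed_voxels = 96L, roi_shape = c(8L, 4L, 3L),
    true_k = 3L, n_targets = 120L, n_samples = 4000L, rng_seed = seed))
}

cohort_similarities <- function(coh) {
  lapply(coh$subjects, function(s) cross_correlation(threshold_counts(s)))
}
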