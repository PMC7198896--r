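.partition_entropy_bits <- function(labels) {
  p <- table(labels) / length(labels)
  .entropy_bits(as.numeric(p))
}

.partition_mi_bits <- function(l1, l2) {
  pj <- table(l1, l2) / length(l1)
  h1 <- .entropy_bits(rowSums(pj))
  h2 <- .entropy_bits(colSums(pj))
  h12 <- .entropy_bits(as.numeric(pj))
  list(mi = max(h1 + h2 - h12, 0), h1 = h1, h2 = h2)
}

.labels_of <- function(p) {
  if (inherits(p, "cbp_parcellation")) p$labels else as.integer(p)
}

#' Agreement indices between two parcellations
#'
#' Consistency-across-parcellations indices on a shared voxel support:
#' cluster-matched mean Dice coefficient (the second partition is
#' harmonized to the first by maximum-overlap assignment before
#' cluster-wise Dice is averaged), Cramer's V of the label contingency
#' table, normalized mutual information `2I/(H1+H2)`, and variation of
#' information `H1 + H2 - 2I`. Entropies are in bits. All indices are
#' invariant to consistent relabeling of either partition.
#'
#' @param p1,p2 [parcellation()]s or integer label vectors over the same
#'   voxels in the same order.
#' @return Named list `dice`, `cramers_v`, `nmi`, `vi` (class
#'   `cbp_partition_agreement`). `dice` is `NA` when the partitions have
#'   different numbers of clusters (no one-to-one matching exists).
#' @export
partition_agreement <- function(p1, p2) {
  l1 <- .labels_of(p1); l2 <- .labels_of(p2)
  if (length(l1) != length(l2))
    stop("support mismatch: partitions label different numbers of voxels")
  n <- length(l1)
  k1 <- max(l1); k2 <- max(l2)
  ent <- .partition_mi_bits(l1, l2)
  vi <- ent$h1 + ent$h2 - 2 * ent$mi
  nmi <- if (ent$h1 + ent$h2 == 0) 1 else 2 * ent$mi / (ent$h1 + ent$h2)
  # Cramer's V from the chi-square of the contingency table
  tab <- table(factor(l1, 1:k1), factor(l2, 1:k2))
  cv <- if (min(k1, k2) == 1L) {
    if (k1 == k2) 1 else 0          # a single-cluster partition
  } else {
    e <- outer(rowSums(tab), colSums(tab)) / n
    chi2 <- sum((tab - e)^2 / e, na.rm = TRUE)
    sqrt(chi2 / (n * (min(k1, k2) - 1)))
  }
  dice <- if (k1 == k2) {
    ov <- as.matrix(tab)             # rows l1, cols l2
    perm <- .solve_lsap_min(max(ov) - t(ov))  # assign l2 clusters to l1 labels
    l2h <- perm[l2]
    mean(vapply(seq_len(k1), function(c) {
      a <- sum(l1 == c); b <- sum(l2h == c); i <- sum(l1 == c & l2h == c)
      if (a + b == 0) 1 else 2 * i / (a + b)
    }, numeric(1)))
  } else NA_real_
  structure(list(dice = dice, cramers_v = cv, nmi = nmi, vi = max(vi, 0)),
            class = "cbp_partition_agreement")
}

#' @export
print.cbp_partition_agreement <- function(x, ...) {
  cat("<cbp_partition_agreement> dice=", signif(x$dice, 4),
      " V=", signif(x$cramers_v, 4), " nmi=", signif(x$nmi, 4),
      " vi=", signif(x$vi, 4), " bits\n", sep = "")
  invisible(x)
}

#' Mean silhouette value of a parcellation
#'
#' Dissimilarity is `1 - similarity`. For each voxel, `a` is its mean
#' dissimilarity to its own cluster (excluding itself) and `b` the
#' smallest mean dissimilarity to any other cluster; the silhouette is
#' `(b - a) / max(a, b)`. Voxels in singleton clusters get silhouette 0
#' (with a message).
#'
#' @param sim a [similarity_matrix()].
#' @param p a [parcellation()] (or label vector) over the same voxels,
#'   with k >= 2.
#' @return Mean silhouette in [-1, 1].
#' @export
silhouette_mean <- function(sim, p) {
  stopifnot(inherits(sim, "cbp_similarity"))
  labels <- .labels_of(p)
  n <- nrow(sim$values)
  stopifnot(length(labels) == n)
  k <- max(labels)
  if (k < 2L) stop("silhouette needs k >= 2")
  d <- 1 - sim$values
  sizes <- tabulate(labels, k)
  if (any(sizes == 1L))
    message("silhouette: ", sum(sizes == 1L),
            " singleton cluster(s); their voxels score 0")
  # mean dissimilarity from every voxel to every cluster
  member <- outer(labels, seq_len(k), `==`) * 1
  sums <- d %*% member
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- labels[i]
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- sums[i, ci] / (sizes[ci] - 1)
    b <- min((sums[i, -ci] / sizes[-ci]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Sizes of the 6-connected components of a logical mask, via igraph.
.component_sizes_6 <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(integer(0))
  d <- dim(mask)
  pos <- arrayInd(idx, d)
  edges <- integer(0)
  for (ax in 1:3) {
    nb <- pos
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= d[ax]
    nb_idx <- (nb[, 1] - 1L) + d[1] * ((nb[, 2] - 1L) + d[2] * (nb[, 3] - 1L)) + 1L
    m <- match(nb_idx, idx)
    keep <- ok & !is.na(m)
    edges <- c(edges, rbind(which(keep), m[keep]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  igraph::components(g)$csize
}

#' Spatial continuity index of a parcellation
#'
#' Mean over clusters of the fraction of a cluster's voxels lying in its
#' largest 6-connected component: 1 iff every cluster is spatially
#' contiguous, decreasing as clusters fragment.
#'
#' @param p a [parcellation()] with seed coordinates.
#' @return Value in (0, 1].
#' @export
continuity_index <- function(p) {
  stopifnot(inherits(p, "cbp_parcellation"), !is.null(p$seeds))
  vol <- parcellation_to_volume(p)
  fracs <- vapply(seq_len(p$k), function(c) {
    cs <- .component_sizes_6(vol$data == c)
    if (!length(cs)) stop("empty cluster ", c)
    max(cs) / sum(cs)
  }, numeric(1))
  mean(fracs)
}

#' Hierarchy index between a k- and a (k+1)-cluster solution
#'
#' The fraction of voxels consistent with the best many-to-one mapping
#' from the k+1 clusters onto the k clusters (each finer cluster maps to
#' the coarser cluster it overlaps most): 1 iff the k+1 solution is a
#' perfect split of one k-cluster.
#'
#' @param p_k,p_k1 [parcellation()]s (or label vectors) on the same
#'   support; `p_k1` must have exactly one more cluster than `p_k`.
#' @return Value in [0, 1].
#' @export
hierarchy_index <- function(p_k, p_k1) {
  lk <- .labels_of(p_k); lk1 <- .labels_of(p_k1)
  if (length(lk) != length(lk1)) stop("support mismatch")
  if (max(lk1) != max(lk) + 1L)
    stop("p_k1 must have exactly one more cluster than p_k (",
         max(lk), " vs ", max(lk1), ")")
  tab <- table(lk1, lk)
  sum(apply(tab, 1, max)) / length(lk)
}

# k x k cluster face-adjacency matrix of a painted label volume.
.cluster_adjacency <- function(arr, k) {
  d <- dim(arr)
  adj <- matrix(FALSE, k, k)
  for (ax in 1:3) {
    ia <- switch(ax, arr[-d[1], , , drop = FALSE],
                 arr[, -d[2], , drop = FALSE], arr[, , -d[3], drop = FALSE])
    ib <- switch(ax, arr[-1, , , drop = FALSE],
                 arr[, -1, , drop = FALSE], arr[, , -1, drop = FALSE])
    sel <- ia > 0L & ib > 0L & ia != ib
    if (any(sel)) {
      pr <- unique(cbind(as.vector(ia)[sel], as.vector(ib)[sel]))
      adj[pr] <- TRUE
      adj[pr[, 2:1, drop = FALSE]] <- TRUE
    }
  }
  diag(adj) <- FALSE
  adj
}

#' Topological distance between hemispheric parcellations
#'
#' Normalized Hamming distance between the cluster-adjacency matrices of
#' the two hemispheres after mirroring the right across the midline and
#' harmonizing its labels to the left (clusters are adjacent when they
#' share at least one face-neighboring voxel pair): 0 iff the two
#' adjacency graphs are identical under the harmonized labeling.
#'
#' @param left_mpm,right_mpm [parcellation()]s with seed coordinates and
#'   the same k (typically derived from the two hemispheres' MPMs).
#' @param flip_axis midline axis (default 1).
#' @return Value in [0, 1]: differing unordered adjacency pairs over
#'   k(k-1)/2, counted symmetrically as `sum |A_L - A_R| / (k (k - 1))`.
#' @export
topological_distance <- function(left_mpm, right_mpm, flip_axis = 1L) {
  stopifnot(inherits(left_mpm, "cbp_parcellation"),
            inherits(right_mpm, "cbp_parcellation"))
  if (left_mpm$k != right_mpm$k) stop("k mismatch between hemispheres")
  k <- left_mpm$k
  if (k == 1L) return(0)
  right_m <- mirror_parcellation(right_mpm, flip_axis)
  right_h <- harmonize_labels(right_m, left_mpm)
  a_l <- .cluster_adjacency(parcellation_to_volume(left_mpm)$data, k)
  a_r <- .cluster_adjacency(parcellation_to_volume(right_h)$data, k)
  sum(abs(a_l - a_r)) / (k * (k - 1))
}

#' Resampled consistency curves over k
#'
#' Repeatedly splits the cohort (leave-one-out: each repetition holds
#' one subject out against the rest; split-half: random disjoint
#' halves), runs the group pipeline on each part for every k in 2..K,
#' and scores the agreement between the two parts' maximum probability
#' maps with [partition_agreement()]. Agreement is computed on the
#' voxels both parts assign. Fully reproducible given `seed_rng`; for
#' leave-one-out the number of repetitions is capped at the number of
#' subjects (with a message).
#'
#' @param cohort_sims list of per-subject [similarity_matrix()]s on a
#'   common template-space voxel set (at least 4 subjects).
#' @param seeds the common [voxel_coords()] seed list.
#' @param K maximum number of clusters.
#' @param scheme `"split_half"` or `"loo"`.
#' @param repetitions number of resampling repetitions (> 0).
#' @param seed_rng integer RNG seed.
#' @param threshold group-matrix threshold.
#' @return Object of class `cbp_validity_curve`: a long-format data.frame
#'   (`k`, `index`, `scheme`, `mean`, `sd`, `repetitions`) with the
#'   per-repetition values attached as attribute `"raw"`.
#' @export
resample_consistency <- function(cohort_sims, seeds, K,
                                 scheme = c("split_half", "loo"),
                                 repetitions = 50L, seed_rng = 1L,
                                 threshold = 0) {
  scheme <- match.arg(scheme)
  n <- length(cohort_sims)
  if (n < 4L) stop("resampling needs at least 4 subjects")
  if (repetitions < 1L) stop("repetitions must be positive")
  if (K < 2L) stop("K must be >= 2")
  if (scheme == "loo" && repetitions > n) {
    message("leave-one-out: capping repetitions at n = ", n)
    repetitions <- n
  }
  # each subject's sweep is deterministic and shared by all repetitions
  sweeps <- lapply(seq_len(n), function(s)
    parcellate_sweep(cohort_sims[[s]], K, seed_rng = seed_rng + s,
                     seeds = seeds, space_tag = "template"))
  part_mpm_labels <- function(members, k, rep_seed) {
    subj <- lapply(members, function(s) sweeps[[s]]$by_k[[as.character(k)]])
    res <- group_pipeline(cohort_sims[members], seeds, k,
                          threshold = threshold, seed_rng = rep_seed,
                          subject_parcellations = subj)
    arr <- res$mpm_smoothed$data
    arr[.coords_to_index(seeds$coords, seeds$reference_shape)]
  }
  indices <- c("dice", "cramers_v", "nmi", "vi")
  raw <- array(NA_real_, c(repetitions, K - 1L, length(indices)),
               dimnames = list(NULL, as.character(2:K), indices))
  splits <- .with_seed(seed_rng, lapply(seq_len(repetitions), function(r) {
    if (scheme == "loo") {
      held <- ((r - 1L) %% n) + 1L
      list(a = held, b = setdiff(seq_len(n), held))
    } else {
      a <- sort(sample(n, floor(n / 2)))
      list(a = a, b = setdiff(seq_len(n), a))
    }
  }))
  for (r in seq_len(repetitions)) {
    sp <- splits[[r]]
    for (k in 2:K) {
      la <- part_mpm_labels(sp$a, k, seed_rng + 1000L * r)
      lb <- part_mpm_labels(sp$b, k, seed_rng + 1000L * r + 500L)
      both <- la > 0L & lb > 0L
      if (sum(both) < 2L) next
      ag <- partition_agreement(la[both], lb[both])
      raw[r, as.character(k), ] <- unlist(ag)[indices]
    }
  }
  curve <- do.call(rbind, lapply(indices, function(ix)
    data.frame(k = 2:K, index = ix, scheme = scheme,
               mean = apply(raw[, , ix, drop = FALSE], 2, mean, na.rm = TRUE),
               sd = apply(raw[, , ix, drop = FALSE], 2, stats::sd, na.rm = TRUE),
               repetitions = repetitions)))
  rownames(curve) <- NULL
  structure(curve, class = c("cbp_validity_curve", "data.frame"), raw = raw)
}

#' Write a validity curve as long-format TSV
#'
#' @param curve a `cbp_validity_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validity_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
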