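#' Parcellation of a seed-voxel set
#'
#' Integer cluster labels (1..k) over an ordered seed-voxel list.
#'
#' @param seeds a [voxel_coords()] list (or `NULL` for abstract seeds).
#' @param labels integer vector of labels in 1..k, one per seed.
#' @param k number of clusters (every label 1..k must occur).
#' @param space_tag `"native"` or `"template"`.
#' @param harmonized logical: whether labels follow a group-level
#'   labeling scheme (set by [harmonize_labels()]).
#' @return Object of class `cbp_parcellation`.
#' @export
parcellation <- function(seeds, labels, k = max(labels),
                         space_tag = c("native", "template"),
                         harmonized = FALSE) {
  space_tag <- match.arg(space_tag)
  labels <- as.integer(labels)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (!all(labels %in% seq_len(k)))
    stop("labels must all lie in 1..k")
  if (!all(seq_len(k) %in% labels))
    stop("every label 1..k must occur at least once")
  if (!is.null(seeds)) {
    stopifnot(inherits(seeds, "cbp_coords"), nrow(seeds$coords) == length(labels))
  }
  structure(list(seeds = seeds, labels = labels, k = k,
                 space_tag = space_tag, harmonized = harmonized),
            class = "cbp_parcellation")
}

#' @export
print.cbp_parcellation <- function(x, ...) {
  cat("<cbp_parcellation> ", length(x$labels), " seed voxels, k=", x$k,
      ", space ", x$space_tag,
      if (x$harmonized) ", harmonized" else "", "\n", sep = "")
  cat("  cluster sizes: ", paste(tabulate(x$labels, x$k), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Paint a parcellation into a label volume
#'
#' @param p a [parcellation()] with seed coordinates.
#' @param spacing voxel spacing of the output volume.
#' @return A [label_volume()] with cluster labels at the seed voxels and
#'   0 elsewhere.
#' @export
parcellation_to_volume <- function(p, spacing = c(1, 1, 1)) {
  stopifnot(inherits(p, "cbp_parcellation"), !is.null(p$seeds))
  arr <- array(0L, p$seeds$reference_shape)
  arr[.coords_to_index(p$seeds$coords, p$seeds$reference_shape)] <- p$labels
  label_volume(arr, spacing = spacing, space_tag = p$space_tag)
}

# Spectral embedding: normalized-cuts (Ng-Jordan-Weiss) eigenvectors of
# the affinity built from a similarity matrix.
.spectral_embedding <- function(sim, n_vec,
                                affinity = c("clip", "shift")) {
  affinity <- match.arg(affinity)
  S <- sim$values
  A <- switch(affinity, clip = pmax(S, 0), shift = (S + 1) / 2)
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected",
                                           diag = FALSE)
  n_comp <- igraph::components(g)$no
  d <- rowSums(A)
  d[d == 0] <- 1e-12
  dm <- 1 / sqrt(d)
  U <- A * (dm %o% dm)
  ev <- eigen(U, symmetric = TRUE)
  list(vectors = ev$vectors[, seq_len(n_vec), drop = FALSE],
       values = ev$values, n_components = n_comp)
}

.kmeans_labels <- function(emb, k, seed_rng, nstart = 50L, restarts = 10L) {
  n <- nrow(emb)
  X <- emb
  rn <- sqrt(rowSums(X^2))
  rn[rn == 0] <- 1
  X <- X / rn                        # row-normalized embedding
  for (attempt in seq_len(restarts)) {
    km <- .with_seed(seed_rng + attempt - 1L,
                     stats::kmeans(X, centers = k, nstart = nstart,
                                   iter.max = 100))
    sizes <- tabulate(km$cluster, k)
    if (all(sizes >= 2L) || k == n || all(sizes >= 1L) && k >= n - 1L)
      return(km$cluster)
    if (all(sizes >= 1L) && attempt == restarts) {
      warning("k-means produced a singleton cluster after ", restarts,
              " re-seeded restarts; accepting")
      return(km$cluster)
    }
  }
  stop("k-means failed to produce ", k, " non-empty clusters after ",
       restarts, " re-seeded restarts")
}

#' Spectral parcellation of a similarity matrix
#'
#' Normalized-cuts spectral clustering: negative correlations are clipped
#' to 0 to form the affinity (alternatively shifted to [0, 1]), the first
#' k eigenvectors of the normalized affinity are row-normalized, and
#' k-means (50 restarts, seeded) assigns the labels. Deterministic given
#' `seed_rng`.
#'
#' @param sim a [similarity_matrix()].
#' @param k number of clusters, 2..n_seeds.
#' @param seed_rng integer RNG seed for the k-means stage.
#' @param seeds optional [voxel_coords()] to attach to the result.
#' @param affinity `"clip"` (default) or `"shift"`.
#' @param space_tag space tag for the resulting parcellation.
#' @return A [parcellation()].
#' @export
spectral_parcellate <- function(sim, k, seed_rng = 1L, seeds = NULL,
                                affinity = c("clip", "shift"),
                                space_tag = "native") {
  stopifnot(inherits(sim, "cbp_similarity"))
  n <- nrow(sim$values)
  if (k < 2L || k > n) stop("k must be in 2..n_seeds (n_seeds = ", n, ")")
  emb <- .spectral_embedding(sim, k, affinity)
  if (emb$n_components > k)
    stop("affinity graph has ", emb$n_components,
         " connected components, more than k = ", k)
  labels <- .kmeans_labels(emb$vectors, k, seed_rng)
  parcellation(seeds, labels, k, space_tag = space_tag)
}

#' Parcellation sweep over k = 2..K
#'
#' Computes the spectral embedding once (K eigenvectors) and reuses its
#' leading columns for every k.
#'
#' @inheritParams spectral_parcellate
#' @param K maximum number of clusters.
#' @return Object of class `cbp_sweep`: a list with `by_k` (named list of
#'   [parcellation()]s for k = 2..K) and `K`.
#' @export
parcellate_sweep <- function(sim, K, seed_rng = 1L, seeds = NULL,
                             affinity = c("clip", "shift"),
                             space_tag = "native") {
  stopifnot(inherits(sim, "cbp_similarity"))
  n <- nrow(sim$values)
  if (K < 2L || K > n) stop("K must be in 2..n_seeds (n_seeds = ", n, ")")
  emb <- .spectral_embedding(sim, K, affinity)
  by_k <- list()
  for (k in 2:K) {
    if (emb$n_components > k)
      stop("affinity graph has ", emb$n_components,
           " connected components, more than k = ", k)
    labels <- .kmeans_labels(emb$vectors[, seq_len(k), drop = FALSE], k, seed_rng)
    by_k[[as.character(k)]] <- parcellation(seeds, labels, k,
                                            space_tag = space_tag)
  }
  structure(list(by_k = by_k, K = as.integer(K)), class = "cbp_sweep")
}

#' @export
print.cbp_sweep <- function(x, ...) {
  cat("<cbp_sweep> k = 2..", x$K, ", ",
      length(x$by_k[[1]]$labels), " seed voxels\n", sep = "")
  invisible(x)
}
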