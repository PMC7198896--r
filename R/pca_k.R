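#' Eigen-spectrum of a connectivity matrix
#'
#' PCA of the seed-voxel covariance (or correlation, if standardized)
#' with seed voxels as variables and target voxels as observations: the
#' number of strong components estimates the number of distinct
#' connectivity patterns, hence subregions, in the seed mask. The
#' decomposition runs through the singular values of the centered data
#' matrix, avoiding the explicit seed-by-seed cross-product.
#'
#' @param x a [connectivity_matrix()] or a plain seeds x targets matrix
#'   with at least 2 seed rows.
#' @param standardize if `TRUE` (default) seed profiles are scaled to
#'   unit variance (correlation PCA), the form required by the Kaiser
#'   criterion; constant profiles are then an error.
#' @return Object of class `cbp_spectrum`: `eigenvalues` (descending,
#'   length = number of seeds, zero-padded past the data rank),
#'   `variance_fraction`, `cumulative`, `standardized`, `total_variance`,
#'   `n_seeds`, `n_targets`.
#' @export
connectivity_pca <- function(x, standardize = TRUE) {
  m <- if (inherits(x, "cbp_connectivity")) x$counts else as.matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 seed rows")
  X <- t(m)                                # observations = targets
  n_obs <- nrow(X); p <- ncol(X)
  if (n_obs < 2L) stop("need at least 2 target observations")
  sds <- apply(X, 2, stats::sd)
  if (standardize && any(sds == 0))
    stop("constant seed profile(s) at row(s) ",
         paste(utils::head(which(sds == 0), 5), collapse = ", "),
         ": correlation PCA undefined")
  Xc <- scale(X, center = TRUE, scale = if (standardize) sds else FALSE)
  sv <- svd(Xc, nu = 0, nv = 0)$d
  ev <- sv^2 / (n_obs - 1)
  ev <- c(ev, numeric(max(0L, p - length(ev))))[seq_len(p)]
  ev[ev < 0] <- 0
  total <- if (standardize) p else sum(apply(X, 2, stats::var))
  structure(list(eigenvalues = ev,
                 variance_fraction = ev / sum(ev),
                 cumulative = cumsum(ev / sum(ev)),
                 standardized = standardize,
                 total_variance = total,
                 n_seeds = p, n_targets = n_obs),
            class = "cbp_spectrum")
}

#' @export
print.cbp_spectrum <- function(x, ...) {
  cat("<cbp_spectrum> ", x$n_seeds, " seed variables, ", x$n_targets,
      " target observations", if (x$standardized) ", standardized", "\n",
      "  leading eigenvalues: ",
      paste(signif(utils::head(x$eigenvalues, 6), 4), collapse = " "),
      " ...\n", sep = "")
  invisible(x)
}

#' Number of components by cumulative explained variance
#'
#' Smallest k whose cumulative variance fraction reaches `tau`. The
#' customary threshold lies between 70 and 90%; values outside that band
#' are allowed but draw a warning.
#'
#' @param spec a `cbp_spectrum`.
#' @param tau cumulative-variance threshold (default 0.7).
#' @return Integer k.
#' @export
k_by_cumulative <- function(spec, tau = 0.7) {
  stopifnot(inherits(spec, "cbp_spectrum"))
  if (!length(spec$eigenvalues)) stop("empty spectrum")
  if (tau < 0.7 || tau > 0.9)
    warning("cumulative-variance threshold ", tau,
            " is outside the customary 70-90% band")
  as.integer(which(spec$cumulative >= tau)[1])
}

#' Number of components by the Kaiser criterion
#'
#' Count of eigenvalues strictly greater than 1. Requires a standardized
#' (correlation-based) spectrum, since the unit threshold presumes
#' unit-variance variables.
#'
#' @param spec a `cbp_spectrum` with `standardized = TRUE`.
#' @return Integer k.
#' @export
k_by_kaiser <- function(spec) {
  stopifnot(inherits(spec, "cbp_spectrum"))
  if (!isTRUE(spec$standardized))
    stop("Kaiser criterion requires a standardized (correlation) spectrum")
  sum(spec$eigenvalues > 1)
}

#' Number of components by the scree elbow
#'
#' The spectrum is truncated to the leading components carrying 99% of
#' the variance (dropping the near-zero eigenvalues that reflect rank
#' limits of the data rather than structure). A power curve
#' `lambda_j ~ a * j^(-b)` is then fitted by least squares on the
#' log-log scale over the retained range as the null model: when it
#' describes the whole profile (coefficient of determination above
#' `null_r2`, i.e. the spectrum is one unbroken power curve with no
#' principal/residual break), there is no elbow and the result is 1 with
#' attribute `no_elbow = TRUE`. Otherwise the elbow is, by default, the
#' index of the largest drop between consecutive log eigenvalues (the
#' break between the principal components and the residual power-law
#' tail); the `"chord"` alternative takes the point of the normalized
#' log-eigenvalue profile farthest from the chord joining its ends and
#' returns the index just before it.
#'
#' @param spec a `cbp_spectrum` with at least 4 positive eigenvalues.
#' @param method `"log_gap"` (default) or `"chord"`.
#' @param null_r2 log-log fit quality above which the spectrum counts as
#'   elbow-free (default 0.95).
#' @return Integer k; attributes `no_elbow` and `fit` (a, b of the
#'   power-curve null fit).
#' @export
k_by_scree <- function(spec, method = c("log_gap", "chord"),
                       null_r2 = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "cbp_spectrum"))
  ev <- spec$eigenvalues
  ev <- ev[ev > .Machine$double.eps * max(ev)]
  if (length(ev) < 4L) stop("scree test needs at least 4 positive eigenvalues")
  # drop the rank-limit plunge: keep the leading 99%-variance components
  p99 <- which(cumsum(ev) / sum(ev) >= 0.99)[1]
  ev <- ev[seq_len(max(p99, 4L))]
  p <- length(ev)
  lev <- log(ev)
  lj <- log(seq_len(p))
  fit <- stats::lm.fit(cbind(1, lj), lev)$coefficients
  resid <- lev - (fit[1] + fit[2] * lj)
  r2 <- 1 - sum(resid^2) / sum((lev - mean(lev))^2)
  fit_attr <- c(a = unname(exp(fit[1])), b = unname(-fit[2]))
  if (is.finite(r2) && r2 > null_r2) {
    out <- 1L
    attr(out, "no_elbow") <- TRUE
    attr(out, "fit") <- fit_attr
    return(out)
  }
  out <- switch(method,
    log_gap = as.integer(which.min(diff(lev))),
    chord = {
      x <- (seq_len(p) - 1) / (p - 1)
      y <- (lev - lev[p]) / (lev[1] - lev[p])
      max(as.integer(which.max(abs(x + y - 1))) - 1L, 1L)
    })
  attr(out, "no_elbow") <- FALSE
  attr(out, "fit") <- fit_attr
  out
}

#' Recommend a cluster-number range from per-subject spectra
#'
#' Applies the cumulative-variance, Kaiser and scree criteria to each
#' subject's spectrum; the per-subject scree estimates are averaged and
#' the recommended range is `[floor(mean), ceiling(mean)]`, intersected
#' with `[2, k_max]`.
#'
#' @param per_subject_spectra list of `cbp_spectrum` objects.
#' @param tau cumulative-variance threshold.
#' @param k_max upper bound for the recommended range (default `Inf`).
#' @return Object of class `cbp_k_recommendation`: `table` (data.frame
#'   subject / k_cumulative / k_kaiser / k_scree), `group_mean` (mean
#'   scree k), `recommended_range` (integer vector).
#' @export
recommend_k <- function(per_subject_spectra, tau = 0.7, k_max = Inf) {
  stopifnot(length(per_subject_spectra) >= 1L)
  tab <- do.call(rbind, lapply(seq_along(per_subject_spectra), function(s) {
    sp <- per_subject_spectra[[s]]
    data.frame(subject = s,
               k_cumulative = k_by_cumulative(sp, tau),
               k_kaiser = k_by_kaiser(sp),
               k_scree = as.integer(k_by_scree(sp)))
  }))
  gm <- mean(tab$k_scree)
  lo <- max(2, floor(gm))
  hi <- min(max(lo, ceiling(gm)), k_max)
  lo <- min(lo, hi)
  structure(list(table = tab, group_mean = gm,
                 recommended_range = seq.int(lo, hi)),
            class = "cbp_k_recommendation")
}

#' @export
print.cbp_k_recommendation <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("mean scree k = ", signif(x$group_mean, 4), "; recommended k in [",
      min(x$recommended_range), ", ", max(x$recommended_range), "]\n",
      sep = "")
  invisible(x)
}
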