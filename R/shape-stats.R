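#' Principal component analysis of shape
#'
#' Eigendecomposition of a shape covariance matrix with scores for a set of
#' aligned specimens.  Axis signs follow the convention that the
#' largest-magnitude loading of each eigenvector is positive.
#'
#' @param cov a `covariance_bundle`.
#' @param scores_for optional `aligned_set` whose (centred) coordinates are
#'   projected on the eigenvectors.
#' @return object of class `shape_pca`: `eigenvalues` (descending, clamped
#'   at 0), `eigenvectors` (3L x p), `scores` (N x p or NULL),
#'   `percent_variance`, `center`.
#' @export
shape_pca <- function(cov, scores_for = NULL) {
  S <- cov$S
  if (!all(is.finite(S))) stop("non-finite covariance")
  eig <- eigen(S, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  pct <- if (sum(vals) > 0) 100 * vals / sum(vals) else vals
  scores <- NULL; center <- NULL
  if (!is.null(scores_for)) {
    X <- scores_for$shape_coords
    center <- colMeans(X)
    scores <- sweep(X, 2, center) %*% vecs
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  }
  structure(list(eigenvalues = vals, eigenvectors = vecs, scores = scores,
                 percent_variance = pct, center = center),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- min(5, length(x$eigenvalues))
  cat("shape_pca:", length(x$eigenvalues), "axes; first", k, "explain",
      paste(sprintf("%.1f%%", x$percent_variance[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Relative eigenvalue variance (integration coefficient)
#'
#' The variance of the covariance-matrix eigenvalues scaled by the squared
#' mean eigenvalue and the number of variables:
#' `v_rel = (sum((lambda - lbar)^2) / p) / (lbar^2 * (p - 1))` with
#' `lbar = sum(lambda) / p`.  Equals 0 for an isotropic spectrum and 1 when
#' all variation lies on a single axis.  Eigenvalue vectors shorter than
#' `p_vars` are zero-padded.
#'
#' @param eigenvalues non-negative eigenvalues.
#' @param p_vars number of variables p (default: length of `eigenvalues`).
#' @param group optional label carried through.
#' @return object of class `integration_value` with `v_rel`, `p_vars`,
#'   `group`.
#' @export
integration_vrel <- function(eigenvalues, p_vars = length(eigenvalues),
                             group = NA_character_) {
  lam <- eigenvalues
  if (any(lam < -1e-12 * max(abs(lam)))) stop("negative eigenvalues")
  lam <- pmax(lam, 0)
  if (sum(lam) == 0) stop("zero total variance")
  if (p_vars < length(lam)) stop("p_vars smaller than the number of eigenvalues")
  lam <- c(lam, rep(0, p_vars - length(lam)))
  p <- p_vars
  lbar <- sum(lam) / p
  v <- (sum((lam - lbar)^2) / p) / (lbar^2 * (p - 1))
  structure(list(v_rel = v, p_vars = p, group = group),
            class = "integration_value")
}

#' @export
print.integration_value <- function(x, ...) {
  cat("integration v_rel =", signif(x$v_rel, 6), "( p =", x$p_vars, ")\n")
  invisible(x)
}

#' Multivariate regression of shape on size with a permutation test
#'
#' Regresses shape coordinates on log10 centroid size (optionally after
#' within-species centring of both, the "pooled by species" variant) and
#' reports the percentage of shape variation predicted by size together with
#' a permutation p-value.  Permutations shuffle the size values (within
#' species under pooling); the p-value uses the add-one estimator
#' `(1 + #[perm >= obs]) / (n_perm + 1)`.
#'
#' @param aligned an `aligned_set`.
#' @param size per-specimen sizes (default: the aligned set's centroid
#'   sizes).
#' @param pooled_by `"none"` or `"species"`.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed RNG seed.
#' @param log_size logical, regress on log10(size) (default TRUE).
#' @return object of class `allometry_result`: `coefficients` (3L vector),
#'   `percent_predicted`, `permutation_p`, `n_permutations`.
#' @export
allometric_regression <- function(aligned, size = aligned$centroid_sizes,
                                  pooled_by = c("none", "species"),
                                  n_perm = 999, seed = 1, log_size = TRUE) {
  pooled_by <- match.arg(pooled_by)
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (any(size <= 0)) stop("sizes must be positive")
  X <- aligned$shape_coords
  x <- if (log_size) log10(size) else size
  species <- aligned$species
  if (pooled_by == "species") {
    for (sp in unique(species)) {
      i <- species == sp
      X[i, ] <- sweep(X[i, , drop = FALSE], 2, colMeans(X[i, , drop = FALSE]))
      x[i] <- x[i] - mean(x[i])
    }
  } else {
    X <- sweep(X, 2, colMeans(X))
    x <- x - mean(x)
  }
  ssx <- sum(x^2)
  if (ssx < .Machine$double.eps * length(x)) stop("size is constant")
  ss_total <- sum(X^2)
  pct <- function(xv) {
    b <- crossprod(X, xv) / sum(xv^2)     # 3L x 1
    100 * sum(xv^2) * sum(b^2) / ss_total
  }
  obs <- pct(x)
  b_obs <- as.vector(crossprod(X, x) / ssx)
  set.seed(seed)
  count <- 0L
  for (r in seq_len(n_perm)) {
    xp <- if (pooled_by == "species") {
      xs <- x
      for (sp in unique(species)) {
        i <- which(species == sp)
        xs[i] <- x[sample(i)]
      }
      xs
    } else x[sample(length(x))]
    if (pct(xp) >= obs) count <- count + 1L
  }
  structure(list(coefficients = b_obs,
                 percent_predicted = obs,
                 permutation_p = (1 + count) / (n_perm + 1),
                 n_permutations = n_perm),
            class = "allometry_result")
}

#' @export
print.allometry_result <- function(x, ...) {
  cat(sprintf("allometry: %.3f%% of shape predicted by size (P = %.4g, %d permutations)\n",
              x$percent_predicted, x$permutation_p, x$n_permutations))
  invisible(x)
}

#' Corolla tube length of a configuration
#'
#' Euclidean distance between two named landmarks (tube base and corolla
#' mouth) in raw, unscaled coordinates.
#'
#' @param config L x 3 matrix.
#' @param base_idx,mouth_idx landmark indices (1-based, distinct).
#' @return scalar distance.
#' @export
tube_length <- function(config, base_idx, mouth_idx) {
  if (base_idx == mouth_idx) stop("base and mouth landmarks must differ")
  config <- as.matrix(config)
  sqrt(sum((config[base_idx, ] - config[mouth_idx, ])^2))
}
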