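#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of landmarks to their
#' centroid: the standard geometric-morphometric size measure.  Invariant to
#' rotation and translation; scales linearly under isotropic scaling.
#'
#' @param config L x 3 numeric matrix.
#' @return positive scalar (0 with a warning for a degenerate configuration).
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 3) stop("need at least 3 landmarks")
  if (!all(is.finite(config))) stop("non-finite coordinates")
  cen <- colMeans(config)
  cs <- sqrt(sum(sweep(config, 2, cen)^2))
  if (cs == 0) warning("degenerate configuration: all landmarks identical")
  cs
}

# Rotation taking a centred configuration onto its principal axes with a
# deterministic sign convention (largest-|coordinate| positive per axis,
# determinant +1).
consensus_principal_axes <- function(config) {
  ev <- eigen(crossprod(config), symmetric = TRUE)
  R <- ev$vectors
  proj <- config %*% R
  for (j in 1:3) if (proj[which.max(abs(proj[, j])), j] < 0) R[, j] <- -R[, j]
  if (det(R) < 0) R[, 3] <- -R[, 3]
  R
}

# Optimal proper rotation (det +1) of X onto Y, both centred.
opa_rotation <- function(X, Y) {
  M <- crossprod(Y, X)            # 3 x 3
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  sv$v %*% D %*% t(sv$u)          # X %*% R approximates Y
}

#' Generalized Procrustes alignment
#'
#' Full Procrustes superimposition: each configuration is centred, scaled to
#' unit centroid size, and iteratively rotated (proper rotations only) onto
#' the running consensus until the consensus stabilises, followed by an
#' orthogonal projection onto the tangent space at the consensus.
#'
#' @param specimens a [specimen_set()].
#' @param tol convergence tolerance on the RMS consensus change
#'   (default 1e-10).
#' @param max_iter maximum number of iterations (default 1000).
#' @param project_tangent logical; project onto the tangent space at the
#'   consensus after convergence (default TRUE).
#' @return an object of class `aligned_set`: list with `shape_coords`
#'   (N x 3L matrix, landmark-major xyz interleaved), `centroid_sizes`,
#'   `consensus` (L x 3, unit centroid size), `iterations`, plus the
#'   metadata of the input specimen set.
#' @export
gpa_align <- function(specimens, tol = 1e-10, max_iter = 1000,
                      project_tangent = TRUE) {
  stopifnot(inherits(specimens, "specimen_set"))
  N <- n_specimens(specimens); L <- n_landmarks(specimens)
  if (N < 2) stop("need at least 2 specimens")
  cs <- numeric(N)
  arr <- array(NA_real_, c(L, 3, N))
  for (i in seq_len(N)) {
    X <- specimens$coords[, , i]
    cen <- colMeans(X)
    X <- sweep(X, 2, cen)
    s <- sqrt(sum(X^2))
    if (s == 0) stop("degenerate configuration for specimen ",
                     specimens$specimen_id[i])
    cs[i] <- s
    arr[, , i] <- X / s
  }
  consensus <- arr[, , 1]
  change <- Inf; iter <- 0
  while (change > tol && iter < max_iter) {
    iter <- iter + 1
    for (i in seq_len(N)) {
      R <- opa_rotation(arr[, , i], consensus)
      arr[, , i] <- arr[, , i] %*% R
    }
    new_consensus <- apply(arr, c(1, 2), mean)
    ncs <- sqrt(sum(sweep(new_consensus, 2, colMeans(new_consensus))^2))
    new_consensus <- sweep(new_consensus, 2, colMeans(new_consensus)) / ncs
    change <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
  }
  if (change > tol)
    stop("GPA did not converge in ", max_iter,
         " iterations (last change ", signif(change, 4), ")")
  # canonical orientation: principal axes of the consensus, signs fixed,
  # proper rotation; makes the output deterministic under arbitrary rigid
  # motion of the inputs
  Rc <- consensus_principal_axes(consensus)
  consensus <- consensus %*% Rc
  for (i in seq_len(N)) arr[, , i] <- arr[, , i] %*% Rc
  flat <- t(apply(arr, 3, flatten_config))
  cvec <- flatten_config(consensus)
  if (project_tangent) {
    # orthogonal projection of the aligned shapes onto the tangent plane at
    # the consensus: deviations orthogonal to the consensus direction
    proj <- as.vector(flat %*% cvec) # N inner products (|c| = 1)
    flat <- flat - (proj - 1) %o% cvec
  }
  structure(list(shape_coords = flat,
                 centroid_sizes = cs,
                 consensus = consensus,
                 iterations = iter,
                 specimen_id = specimens$specimen_id,
                 species = specimens$species,
                 landmark_labels = specimens$landmark_labels,
                 syndrome_map = specimens$syndrome_map),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat("aligned_set:", nrow(x$shape_coords), "specimens,",
      length(x$landmark_labels), "landmarks, converged in",
      x$iterations, "iterations\n")
  invisible(x)
}

#' Flatten / unflatten a landmark configuration
#'
#' `flatten_config` turns an L x 3 matrix into a 3L vector with xyz
#' interleaved per landmark (x1,y1,z1,x2,...); `unflatten_config` inverts it.
#'
#' @param config L x 3 matrix.
#' @return numeric vector of length 3L.
#' @export
flatten_config <- function(config) as.vector(t(config))

#' @rdname flatten_config
#' @param v numeric vector of length 3L.
#' @return L x 3 matrix.
#' @export
unflatten_config <- function(v) matrix(v, ncol = 3, byrow = TRUE)

# column indices of the shape matrix belonging to a set of landmarks
landmark_columns <- function(landmarks) {
  as.vector(vapply(landmarks, function(l) (3 * (l - 1)) + 1:3, numeric(3)))
}

#' Extract the symmetric component of shape variation
#'
#' For object symmetry: each specimen is mirrored across `mirror_axis` and
#' its paired landmarks swapped; originals and mirrored copies are jointly
#' re-superimposed and each specimen's symmetric component is the average of
#' itself and its relabelled reflection.
#'
#' @param specimens a [specimen_set()].
#' @param pairing two-column integer matrix of paired landmark indices; every
#'   landmark not listed is treated as medial (on the symmetry plane).
#' @param mirror_axis which coordinate is negated (`"x"`, `"y"` or `"z"`).
#' @param ... passed to [gpa_align()].
#' @return an `aligned_set` of the symmetric components.
#' @export
symmetric_component <- function(specimens, pairing, mirror_axis = c("y", "x", "z"),
                                ...) {
  mirror_axis <- match.arg(mirror_axis)
  stopifnot(inherits(specimens, "specimen_set"))
  L <- n_landmarks(specimens); N <- n_specimens(specimens)
  pairing <- as.matrix(pairing)
  if (ncol(pairing) != 2) stop("pairing must be a 2-column matrix")
  perm <- seq_len(L)
  perm[pairing[, 1]] <- pairing[, 2]
  perm[pairing[, 2]] <- pairing[, 1]
  if (anyDuplicated(c(pairing)) || !identical(sort(perm), seq_len(L)))
    stop("pairing is not a valid involution on the landmarks")
  ax <- match(mirror_axis, c("x", "y", "z"))
  both <- array(NA_real_, c(L, 3, 2 * N))
  both[, , seq_len(N)] <- specimens$coords
  for (i in seq_len(N)) {
    M <- specimens$coords[, , i]
    M[, ax] <- -M[, ax]
    both[, , N + i] <- M[perm, ]
  }
  ss <- specimen_set(both,
                     c(specimens$specimen_id,
                       paste0(specimens$specimen_id, "_mirror")),
                     rep(specimens$species, 2),
                     specimens$landmark_labels,
                     specimens$syndrome_map)
  al <- gpa_align(ss, ...)
  sym <- (al$shape_coords[seq_len(N), , drop = FALSE] +
          al$shape_coords[N + seq_len(N), , drop = FALSE]) / 2
  structure(list(shape_coords = sym,
                 centroid_sizes = al$centroid_sizes[seq_len(N)],
                 consensus = al$consensus,
                 iterations = al$iterations,
                 specimen_id = specimens$specimen_id,
                 species = specimens$species,
                 landmark_labels = specimens$landmark_labels,
                 syndrome_map = specimens$syndrome_map),
            class = "aligned_set")
}

#' Covariance matrix of shape coordinates
#'
#' `group_by = "none"`: ordinary covariance (divisor N - 1).
#' `group_by = "species"`: within-species centred cross-products summed over
#' species and divided by the pooled degrees of freedom sum(n_i - 1);
#' species means are removed, so among-species differences do not enter.
#'
#' @param aligned an `aligned_set`.
#' @param group_by `"none"` or `"species"`.
#' @param subset optional logical or integer index of specimens to retain.
#' @return an object of class `covariance_bundle`: list with `S` (3L x 3L),
#'   `grouping`, `df`, `n_landmarks`.
#' @export
pooled_covariance <- function(aligned, group_by = c("none", "species"),
                              subset = NULL) {
  group_by <- match.arg(group_by)
  X <- aligned$shape_coords
  species <- aligned$species
  if (!is.null(subset)) {
    X <- X[subset, , drop = FALSE]
    species <- species[subset]
  }
  if (group_by == "none") {
    if (nrow(X) < 2) stop("need at least 2 specimens")
    S <- stats::cov(X)
    df <- nrow(X) - 1L
  } else {
    counts <- table(species)
    singletons <- names(counts)[counts < 2]
    if (length(singletons)) {
      warning("dropping species with a single specimen: ",
              paste(singletons, collapse = ", "))
      keep <- !(species %in% singletons)
      X <- X[keep, , drop = FALSE]
      species <- species[keep]
    }
    if (!nrow(X)) stop("no species with >= 2 specimens left")
    cp <- matrix(0, ncol(X), ncol(X))
    df <- 0L
    for (sp in unique(species)) {
      Xi <- X[species == sp, , drop = FALSE]
      Xi <- sweep(Xi, 2, colMeans(Xi))
      cp <- cp + crossprod(Xi)
      df <- df + nrow(Xi) - 1L
    }
    S <- cp / df
  }
  S <- (S + t(S)) / 2
  structure(list(S = S,
                 grouping = if (group_by == "none") "total" else "pooled_by_species",
                 df = df,
                 n_landmarks = ncol(X) / 3),
            class = "covariance_bundle")
}

#' Wrap an existing matrix as a covariance bundle
#' @param S symmetric positive-semidefinite matrix (3 columns per landmark).
#' @param grouping provenance label.
#' @param df degrees of freedom used to estimate `S`.
#' @return a `covariance_bundle`.
#' @export
covariance_bundle <- function(S, grouping = "total", df = NA_integer_) {
  S <- as.matrix(S)
  if (!isSymmetric(S, tol = 1e-8)) stop("S must be symmetric")
  S <- (S + t(S)) / 2
  structure(list(S = S, grouping = grouping, df = df,
                 n_landmarks = nrow(S) / 3),
            class = "covariance_bundle")
}

#' @export
print.covariance_bundle <- function(x, ...) {
  cat("covariance_bundle:", nrow(x$S), "variables (", x$n_landmarks,
      "landmarks ),", x$grouping, ", df =", x$df, "\n")
  invisible(x)
}

#' Total Procrustes variance of an aligned sample
#'
#' Sum of squared deviations of the aligned shapes from their sample mean,
#' divided by N - 1; equals the trace of the total covariance matrix.
#'
#' @param aligned an `aligned_set`.
#' @return scalar.
#' @export
procrustes_variance <- function(aligned) {
  X <- sweep(aligned$shape_coords, 2, colMeans(aligned$shape_coords))
  sum(X^2) / (nrow(X) - 1)
}
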