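#' RV coefficient between two landmark sets
#'
#' Escoufier's matrix correlation
#' `RV = tr(S_AB S_BA) / sqrt(tr(S_AA^2) tr(S_BB^2))`, a multivariate
#' generalization of the squared Pearson correlation.  Each landmark
#' contributes its three coordinate variables as a block.
#'
#' @param cov a `covariance_bundle` over 3L shape variables.
#' @param setA,setB disjoint non-empty landmark index sets (1-based).
#' @return RV in `[0, 1]`.
#' @export
rv_coefficient <- function(cov, setA, setB) {
  if (!length(setA) || !length(setB)) stop("empty landmark set")
  if (length(intersect(setA, setB))) stop("landmark sets must be disjoint")
  S <- cov$S
  a <- landmark_columns(setA); b <- landmark_columns(setB)
  Saa <- S[a, a, drop = FALSE]; Sbb <- S[b, b, drop = FALSE]
  Sab <- S[a, b, drop = FALSE]
  den <- sqrt(sum(Saa^2) * sum(Sbb^2))
  if (den == 0) stop("zero within-block variance")
  sum(Sab^2) / den
}

#' Multi-set RV coefficient of a partition
#'
#' For K = 2 modules this is the pairwise RV; for K > 2 it is the arithmetic
#' mean of the pairwise RV over all K(K-1)/2 module pairs.
#'
#' @param cov a `covariance_bundle`.
#' @param partition a [partition_hypothesis()] (or integer assignment).
#' @return scalar RV.
#' @export
multiset_rv <- function(cov, partition) {
  g <- if (inherits(partition, "partition_hypothesis")) partition$assignment
       else as.integer(partition)
  EL <- landmark_block_sumsq(cov$S)
  rv_from_blocks(EL, g)
}

# L x L matrix of sums of squared covariance entries per 3 x 3 landmark
# block; since S is symmetric, tr(S_AB S_BA) is the sum of EL over A x B.
landmark_block_sumsq <- function(S) {
  L <- nrow(S) / 3
  idx <- rep(seq_len(L), each = 3)
  E <- S * S
  t(rowsum(t(rowsum(E, idx)), idx))
}

# Multi-set RV from the precomputed block matrix and an assignment vector.
rv_from_blocks <- function(EL, g) {
  K <- max(g)
  G <- matrix(0, nrow(EL), K)
  G[cbind(seq_along(g), g)] <- 1
  M <- crossprod(G, EL %*% G)            # K x K block sums
  d <- diag(M)
  if (any(d == 0)) stop("zero within-block variance")
  tot <- 0; np <- 0L
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    tot <- tot + M[i, j] / sqrt(d[i] * d[j])
    np <- np + 1L
  }
  tot / np
}

#' Number of distinct random partitions with given module sizes
#'
#' Counts assignments of L landmarks to unlabelled modules of the given
#' sizes: `L! / (prod(sizes!) * prod(multiplicity!))` where multiplicities
#' count modules sharing a size.
#'
#' @param module_sizes integer vector summing to L.
#' @return numeric count (may overflow to Inf for large L).
#' @export
count_partitions <- function(module_sizes) {
  L <- sum(module_sizes)
  mult <- table(module_sizes)
  total <- exp(lgamma(L + 1) - sum(lgamma(module_sizes + 1)) -
                 sum(lgamma(as.integer(mult) + 1)))
  # the count is an integer; clean up log-gamma round-off where exact
  if (total < 2^52) round(total) else total
}

#' Generate random landmark partitions
#'
#' `mode = "sample"`: partitions drawn uniformly among all assignments of L
#' landmarks to unlabelled modules of the given sizes (random shuffle then
#' split; with replacement across the stream).  `mode = "exhaustive"`: every
#' distinct partition exactly once (refused above `cap`).
#'
#' @param L number of landmarks.
#' @param module_sizes sizes of the modules (must sum to L).
#' @param n number of sampled partitions (ignored for exhaustive).
#' @param mode `"sample"` or `"exhaustive"`.
#' @param seed RNG seed for sampling.
#' @param cap refusal threshold for exhaustive enumeration (default 1e6).
#' @return integer matrix, one row per partition, entries are module ids.
#' @export
random_partitions <- function(L, module_sizes, n = 1000,
                              mode = c("sample", "exhaustive"), seed = 1,
                              cap = 1e6) {
  mode <- match.arg(mode)
  module_sizes <- as.integer(module_sizes)
  if (sum(module_sizes) != L) stop("module sizes must sum to L")
  if (mode == "sample") {
    set.seed(seed)
    g0 <- rep(seq_along(module_sizes), module_sizes)
    out <- matrix(0L, n, L)
    for (r in seq_len(n)) out[r, ] <- g0[order(sample.int(L))]
    return(out)
  }
  total <- count_partitions(module_sizes)
  if (total > cap)
    stop("exhaustive enumeration refused: ", format(total, digits = 4),
         " partitions exceed the cap of ", cap)
  enumerate_partitions(L, module_sizes)
}

# All distinct partitions of 1..L into unlabelled modules of given sizes.
# Modules are generated in order of non-increasing size; among consecutive
# modules of equal size the minima must increase, which removes label
# permutations of indistinguishable modules exactly once.
enumerate_partitions <- function(L, sizes) {
  sizes <- sort(sizes, decreasing = TRUE)
  out <- list()
  rec <- function(remaining, sizes_left, labels, mod_id, prev_size, prev_min) {
    if (!length(sizes_left)) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    s <- sizes_left[1]
    choices <- if (s < length(remaining))
      utils::combn(remaining, s, simplify = FALSE)
    else list(remaining)
    for (grp in choices) {
      if (s == prev_size && grp[1] <= prev_min) next
      lab2 <- labels
      lab2[grp] <- mod_id
      rec(setdiff(remaining, grp), sizes_left[-1], lab2, mod_id + 1L,
          s, grp[1])
    }
  }
  rec(seq_len(L), sizes, integer(L), 1L, -1L, -1L)
  do.call(rbind, out)
}

#' RV-coefficient modularity test against random partitions
#'
#' Evaluates the multi-set RV of a hypothesis and of `n_partitions` null
#' partitions with identical module sizes, and reports the observed RV, the
#' minimum null RV, and the proportion of null partitions with strictly
#' lower RV (ties count as not lower).  Low proportions support the
#' hypothesis: few random partitions divide the flower into more independent
#' parts.  When the number of distinct partitions does not exceed
#' `n_partitions`, exhaustive enumeration is used instead of sampling.
#'
#' @param cov a `covariance_bundle`.
#' @param hypothesis a [partition_hypothesis()].
#' @param n_partitions number of null partitions (default 1e5).
#' @param seed RNG seed.
#' @param exhaustive_cap cap for the automatic exhaustive switch.
#' @return object of class `modularity_result` with fields `hypothesis`,
#'   `rv_observed`, `rv_min_null`, `proportion_lower`,
#'   `n_partitions_evaluated`, `exhaustive`, `seed`.
#' @export
modularity_test <- function(cov, hypothesis, n_partitions = 1e5, seed = 1,
                            exhaustive_cap = 1e6) {
  stopifnot(inherits(hypothesis, "partition_hypothesis"))
  g <- hypothesis$assignment
  L <- length(g)
  if (3 * L != nrow(cov$S))
    stop("hypothesis has ", L, " landmarks but covariance has ",
         nrow(cov$S) / 3)
  sizes <- tabulate(g)
  EL <- landmark_block_sumsq(cov$S)
  rv_obs <- rv_from_blocks(EL, g)
  total <- count_partitions(sizes)
  exhaustive <- is.finite(total) && total <= n_partitions && total <= exhaustive_cap
  if (exhaustive) {
    parts <- enumerate_partitions(L, sizes)
  } else {
    parts <- random_partitions(L, sizes, n = n_partitions, mode = "sample",
                               seed = seed)
  }
  nv <- nrow(parts)
  rvs <- numeric(nv)
  for (r in seq_len(nv)) rvs[r] <- rv_from_blocks(EL, parts[r, ])
  structure(list(hypothesis = hypothesis$name,
                 rv_observed = rv_obs,
                 rv_min_null = min(rvs),
                 proportion_lower = sum(rvs < rv_obs) / nv,
                 n_partitions_evaluated = nv,
                 exhaustive = exhaustive,
                 seed = seed),
            class = "modularity_result")
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf("modularity '%s': RV = %.4f, lowest null RV = %.4f, proportion lower = %.3g (%d partitions%s)\n",
              x$hypothesis, x$rv_observed, x$rv_min_null, x$proportion_lower,
              x$n_partitions_evaluated,
              if (x$exhaustive) ", exhaustive" else ""))
  invisible(x)
}
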