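# Equal-rates (ER) Markov transition probabilities for k states:
# diagonal 1/k + (1 - 1/k) e^{-k q t}, off-diagonal (1/k)(1 - e^{-k q t}).
mk_er_P <- function(q, t, k) {
  e <- exp(-k * q * t)
  M <- matrix((1 - e) / k, k, k)
  diag(M) <- 1 / k + (1 - 1 / k) * e
  M
}

postorder_internal <- function(tree) {
  ntip <- ape::Ntip(tree)
  h <- tree_node_heights(tree)
  ord <- order(h[tree$edge[, 1]], decreasing = TRUE)  # deepest parents first
  tree$edge[ord, , drop = FALSE]
}

tip_state_matrix <- function(tree, tip_states, states) {
  ntip <- ape::Ntip(tree)
  x <- tip_states[tree$tip.label]
  if (anyNA(x)) stop("tip state missing for: ",
                     paste(tree$tip.label[is.na(x)], collapse = ", "))
  M <- matrix(0, ntip + tree$Nnode, length(states))
  M[cbind(seq_len(ntip), match(as.character(x), states))] <- 1
  M
}

# conditional likelihoods F[node, state] by pruning; returns list(F, logscale)
mk_prune <- function(tree, q, tipM, k) {
  ntip <- ape::Ntip(tree)
  FF <- tipM
  FF[(ntip + 1):nrow(FF), ] <- 1
  edges <- postorder_internal(tree)
  lens <- tree$edge.length[match(paste(edges[, 1], edges[, 2]),
                                 paste(tree$edge[, 1], tree$edge[, 2]))]
  logscale <- 0
  done <- logical(nrow(FF))
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1]; ch <- edges[i, 2]
    P <- mk_er_P(q, lens[i], k)
    FF[p, ] <- FF[p, ] * as.vector(P %*% FF[ch, ])
    m <- max(FF[p, ])
    if (m > 0 && m < 1e-100) { FF[p, ] <- FF[p, ] / m; logscale <- logscale + log(m) }
  }
  list(F = FF, logscale = logscale)
}

#' Fit the equal-rates Mk model of discrete character evolution
#'
#' Single-rate Markov model over k unordered states; likelihood computed by
#' post-order pruning with the closed-form ER transition matrix, a uniform
#' root prior, and the rate estimated by bounded one-dimensional maximum
#' likelihood.
#'
#' @param tree ultrametric `phylo`.
#' @param tip_states named character vector (names = tip labels).
#' @param states optional state set (default: observed states, sorted).
#' @return object of class `mk_fit`: `q` (per-Myr rate), `logL`, `states`,
#'   `tree`, `tip_states`.
#' @export
mk_er_fit <- function(tree, tip_states, states = NULL) {
  tip_states <- stats::setNames(as.character(tip_states), names(tip_states))
  if (is.null(states)) states <- sort(unique(tip_states))
  k <- length(states)
  tipM <- tip_state_matrix(tree, tip_states, states)
  if (length(unique(tip_states[tree$tip.label])) < 2) {
    warning("single observed state: rate estimated at the q = 0 boundary")
    return(structure(list(q = 0, logL = log(1 / k), states = states,
                          tree = tree, tip_states = tip_states),
                     class = "mk_fit"))
  }
  ntip <- ape::Ntip(tree)
  loglik <- function(q) {
    pr <- mk_prune(tree, q, tipM, k)
    log(sum(pr$F[ntip + 1, ] / k)) + pr$logscale
  }
  depth <- tree_depth(tree)
  op <- stats::optimize(function(lq) -loglik(exp(lq)),
                        c(log(1e-8 / depth), log(100 / depth)), tol = 1e-10)
  structure(list(q = exp(op$minimum), logL = -op$objective, states = states,
                 tree = tree, tip_states = tip_states,
                 loglik_fun = loglik),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("mk_fit (ER, %d states): q = %.5g, logL = %.4f\n",
              length(x$states), x$q, x$logL))
  invisible(x)
}

#' Marginal (empirical Bayes) ancestral state probabilities
#'
#' Combines the post-order conditional likelihoods with a pre-order pass at
#' the fitted rate; each internal node's marginal is proportional to the
#' product of the information below and above it.
#'
#' @param fit an `mk_fit`.
#' @return matrix (internal nodes x states) of probabilities summing to 1
#'   per row; rownames are ape node ids.
#' @export
marginal_states <- function(fit) {
  tree <- fit$tree; states <- fit$states; k <- length(states)
  q <- fit$q
  ntip <- ape::Ntip(tree)
  tipM <- tip_state_matrix(tree, fit$tip_states, states)
  pr <- mk_prune(tree, q, tipM, k)
  FF <- pr$F
  nn <- ntip + tree$Nnode
  G <- matrix(0, nn, k)
  G[ntip + 1, ] <- 1 / k
  h <- tree_node_heights(tree)
  ord <- order(h[tree$edge[, 1]])       # preorder: parents first
  # partial products: for node u with children c1..cm,
  # down(u -> ci) = G[u,] * prod_{j != i} P(t_cj) F[cj,]
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  for (u in unique(tree$edge[ord, 1])) {
    eids <- children[[as.character(u)]]
    msgs <- lapply(eids, function(e)
      as.vector(mk_er_P(q, tree$edge.length[e], k) %*% FF[tree$edge[e, 2], ]))
    for (j in seq_along(eids)) {
      e <- eids[j]; v <- tree$edge[e, 2]
      other <- Reduce(`*`, msgs[-j], rep(1, k))
      G[v, ] <- as.vector(t(mk_er_P(q, tree$edge.length[e], k)) %*%
                            (G[u, ] * other))
    }
  }
  nodes <- ntip + seq_len(tree$Nnode)
  M <- FF[nodes, , drop = FALSE] * G[nodes, , drop = FALSE]
  M <- M / rowSums(M)
  dimnames(M) <- list(nodes, states)
  M
}

# R^n[a,b] for the uniformized ER jump chain (uniform off-diagonal, zero
# diagonal): eigenvalues 1 and -1/(k-1).
er_jump_power <- function(n, same, k) {
  lam <- (-1 / (k - 1))^n
  if (same) 1 / k + (1 - 1 / k) * lam else (1 - lam) / k
}

# sample a branch history conditional on endpoints by uniformization;
# Poisson terms are accumulated on the log scale so large q t is safe
sample_branch_history <- function(a, b, t, q, k, max_n = 100000) {
  mu <- (k - 1) * q
  if (mu * t == 0) {
    if (a != b) stop("zero-length branch with differing endpoint states")
    return(data.frame(regime = a, length = t))
  }
  logPab <- log(mk_er_P(q, t, k)[a, b])
  u <- stats::runif(1)
  cum <- 0; n <- -1
  repeat {
    n <- n + 1
    lp <- -mu * t + n * log(mu * t) - lgamma(n + 1)
    jp <- er_jump_power(n, a == b, k)
    if (jp > 0) cum <- cum + exp(lp + log(jp) - logPab)
    if (u <= cum || n >= max_n) break
  }
  if (n >= max_n) stop("endpoint-conditioned simulation failed (too many jumps)")
  if (n == 0) return(data.frame(regime = a, length = t))
  times <- sort(stats::runif(n, 0, t))
  statesq <- integer(n + 1); statesq[1] <- a; statesq[n + 1] <- b
  if (n > 1) {
    for (j in 2:n) {
      prev <- statesq[j - 1]
      cand <- setdiff(seq_len(k), prev)   # no self-jumps in the ER chain
      wts <- vapply(cand, function(c2)
        er_jump_power(n - j + 1, c2 == b, k), numeric(1))
      statesq[j] <- cand[sample.int(length(cand), 1, prob = wts)]
    }
  }
  bounds <- c(0, times, t)
  segs <- data.frame(regime = statesq, length = diff(bounds))
  segs[segs$length > 0, , drop = FALSE]
}

#' Stochastic character mapping under the fitted ER model
#'
#' Samples complete character histories conditional on the tip states: node
#' states from their joint conditional distribution, branch histories from
#' the Markov process conditioned on both endpoints (by uniformization).
#' Node-state frequencies across draws are the usual pie-chart summary of
#' ancestral syndromes.
#'
#' @param fit an `mk_fit`.
#' @param n_draws number of maps (default 1000).
#' @param seed RNG seed.
#' @return object of class `stochastic_maps`: `node_frequencies` (internal
#'   nodes x states), `draws` (list of [paint_regimes()]-compatible
#'   paintings), `n_draws`, `seed`.
#' @export
stochastic_maps <- function(fit, n_draws = 1000, seed = 1) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  tree <- fit$tree; states <- fit$states; k <- length(states)
  q <- fit$q
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  tipM <- tip_state_matrix(tree, fit$tip_states, states)
  FF <- mk_prune(tree, q, tipM, k)$F
  h <- tree_node_heights(tree)
  ord <- order(h[tree$edge[, 1]])
  set.seed(seed)
  freq <- matrix(0, tree$Nnode, k,
                 dimnames = list(ntip + seq_len(tree$Nnode), states))
  draws <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    ns <- integer(nn)
    w <- FF[ntip + 1, ] / k
    ns[ntip + 1] <- sample.int(k, 1, prob = w)
    for (e in ord) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      Pt <- if (q > 0) mk_er_P(q, tree$edge.length[e], k) else diag(k)
      w <- Pt[ns[p], ] * FF[ch, ]
      ns[ch] <- if (sum(w) > 0) sample.int(k, 1, prob = w) else ns[p]
    }
    segs <- vector("list", nrow(tree$edge))
    for (e in seq_len(nrow(tree$edge))) {
      a <- ns[tree$edge[e, 1]]; b <- ns[tree$edge[e, 2]]
      segs[[e]] <- if (q > 0)
        sample_branch_history(a, b, tree$edge.length[e], q, k)
      else data.frame(regime = a, length = tree$edge.length[e])
      segs[[e]]$regime <- states[segs[[e]]$regime]
    }
    freq[cbind(seq_len(tree$Nnode), ns[ntip + seq_len(tree$Nnode)])] <-
      freq[cbind(seq_len(tree$Nnode), ns[ntip + seq_len(tree$Nnode)])] + 1
    draws[[d]] <- painting_from_segments(tree, segs, states,
                                         states[ns[ntip + 1]])
  }
  structure(list(node_frequencies = freq / n_draws, draws = draws,
                 n_draws = n_draws, seed = seed, states = states),
            class = "stochastic_maps")
}

#' @export
print.stochastic_maps <- function(x, ...) {
  cat("stochastic_maps:", x$n_draws, "draws over",
      length(x$states), "states\n")
  invisible(x)
}

#' Most probable marginal node states as a regime painting
#'
#' Convenience wrapper: fits the ER model, takes each internal node's
#' highest-marginal state and each tip's observed state, and paints the
#' branches (each branch takes its parent node's state).
#'
#' @param tree ultrametric `phylo`.
#' @param tip_states named character vector.
#' @param mode branch-painting convention, see [paint_regimes()]; the
#'   default `"child"` lets observed tip states paint their terminal
#'   branches so every observed regime is identifiable.
#' @return a [paint_regimes()] object.
#' @export
paint_from_marginals <- function(tree, tip_states, mode = "child") {
  fit <- mk_er_fit(tree, tip_states)
  M <- marginal_states(fit)
  ntip <- ape::Ntip(tree)
  node_states <- c(as.character(tip_states[tree$tip.label]),
                   fit$states[max.col(M, ties.method = "first")])
  paint_regimes(tree, node_states, regimes = fit$states, mode = mode)
}
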