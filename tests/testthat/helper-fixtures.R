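# Small fixtures shared across tests; everything is generated in code.

# random proper rotation matrix
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# tiny specimen set: n copies of a base configuration + noise
toy_specimens <- function(n = 4, L = 6, species = NULL, noise = 0.05,
                          seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(L * 3), L, 3)
  coords <- array(NA_real_, c(L, 3, n))
  for (i in seq_len(n)) coords[, , i] <- base + matrix(rnorm(L * 3, 0, noise), L, 3)
  if (is.null(species)) species <- rep("spA", n)
  specimen_set(coords, paste0("s", seq_len(n)), species)
}

# random PSD covariance over L landmark blocks (3L variables)
random_landmark_cov <- function(L, seed = 1) {
  set.seed(seed)
  p <- 3 * L
  A <- matrix(rnorm(p * p), p)
  covariance_bundle(crossprod(A) / p, df = p)
}

# brute-force multiset RV straight from the definition
brute_multiset_rv <- function(S, assignment) {
  cols <- function(lms) as.vector(vapply(lms, function(l) 3 * (l - 1) + 1:3,
                                         numeric(3)))
  K <- max(assignment)
  pairs <- utils::combn(K, 2)
  vals <- apply(pairs, 2, function(pr) {
    a <- cols(which(assignment == pr[1])); b <- cols(which(assignment == pr[2]))
    Sab <- S[a, b, drop = FALSE]
    sum(diag(Sab %*% t(Sab))) /
      sqrt(sum(diag(S[a, a] %*% S[a, a])) * sum(diag(S[b, b] %*% S[b, b])))
  })
  mean(vals)
}

# share of total branch time spent in each regime of a painting
regime_time_share <- function(painting) {
  tot <- numeric(length(painting$regimes))
  for (sg in painting$edge_segments)
    for (i in seq_len(nrow(sg)))
      tot[sg$regime[i]] <- tot[sg$regime[i]] + sg$t1[i] - sg$t0[i]
  tot / sum(tot)
}

# simulate until every regime holds at least `min_share` of branch time
simulate_represented <- function(n_species, model, seed0, min_share = 0.25,
                                 states = c("A", "B"), birth_rate = 0.3,
                                 max_tries = 60) {
  for (k in seq_len(max_tries)) {
    sp <- synthetic_spec(n_species = n_species, seed = seed0 + k,
                         birth_rate = birth_rate)
    tt <- simulate_tree_and_traits(sp, model, states = states)
    if (min(regime_time_share(tt$painting)) >= min_share) return(tt)
  }
  stop("no replicate with adequate regime representation")
}

# brute-force Mk-ER likelihood: enumerate every internal-state combination
brute_mk_loglik <- function(tree, q, tip_states, states) {
  k <- length(states)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  tipidx <- match(tip_states[tree$tip.label], states)
  internal <- (ntip + 1):nn
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    assign <- integer(nn)
    assign[seq_len(ntip)] <- tipidx
    assign[internal] <- combos[r, ]
    pr <- 1 / k
    for (e in seq_len(nrow(tree$edge))) {
      P <- floramorph:::mk_er_P(q, tree$edge.length[e], k)
      pr <- pr * P[assign[tree$edge[e, 1]], assign[tree$edge[e, 2]]]
    }
    total <- total + pr
  }
  log(total)
}
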