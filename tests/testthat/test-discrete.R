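
test_that("pruning likelihood equals brute-force enumeration on small trees", {
  set.seed(1)
  tree <- ape::rphylo(5, 0.5, 0)
  states <- c("a", "b", "c")
  tips <- setNames(sample(states, 5, replace = TRUE), tree$tip.label)
  tips[1:2] <- c("a", "b")               # guarantee 2 observed states
  fit <- mk_er_fit(tree, tips, states)
  for (q in c(0.01, 0.2, 1)) {
    ll <- fit$loglik_fun(q)
    expect_equal(ll, brute_mk_loglik(tree, q, tips, states), tolerance = 1e-10)
  }
})

test_that("two-tip closed form and degenerate limits hold", {
  tree <- ape::read.tree(text = "(A:1,B:1);")
  tips <- c(A = "x", B = "y")
  fit <- mk_er_fit(tree, tips)
  q <- 0.3; k <- 2
  P <- floramorph:::mk_er_P(q, 1, k)
  manual <- log(sum(0.5 * P[, 1] * P[, 2]))  # root sum over states
  expect_equal(fit$loglik_fun(q), manual, tolerance = 1e-12)
  # monomorphic tips: boundary fit at q = 0
  expect_warning(f0 <- mk_er_fit(tree, c(A = "x", B = "x"),
                                 states = c("x", "y")), "single observed")
  expect_equal(f0$q, 0)
  # infinitely long branches: every state equally likely
  tree2 <- ape::read.tree(text = "(A:1e9,B:1e9);")
  f2 <- mk_er_fit(tree2, tips)
  expect_equal(f2$loglik_fun(1), 2 * log(1 / 2), tolerance = 1e-6)
})

test_that("marginal probabilities equal enumeration posteriors and respect
           symmetry", {
  tree <- ape::read.tree(text = "(A:1,B:1);")
  fit <- mk_er_fit(tree, c(A = "x", B = "y"))
  M <- marginal_states(fit)
  expect_equal(as.vector(M), c(0.5, 0.5), tolerance = 1e-9)
  # 5-tip tree: marginals match normalized joint likelihoods per node state
  set.seed(2)
  tree5 <- ape::rphylo(5, 0.5, 0)
  states <- c("a", "b")
  tips <- setNames(c("a", "a", "b", "b", "a"), tree5$tip.label)
  fit5 <- mk_er_fit(tree5, tips, states)
  M5 <- marginal_states(fit5)
  k <- 2; ntip <- 5; nn <- ntip + tree5$Nnode
  internal <- (ntip + 1):nn
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  post <- matrix(0, length(internal), k)
  tipidx <- match(tips[tree5$tip.label], states)
  for (r in seq_len(nrow(combos))) {
    assign <- c(tipidx, combos[r, ])
    pr <- 1 / k
    for (e in seq_len(nrow(tree5$edge))) {
      P <- floramorph:::mk_er_P(fit5$q, tree5$edge.length[e], k)
      pr <- pr * P[assign[tree5$edge[e, 1]], assign[tree5$edge[e, 2]]]
    }
    for (j in seq_along(internal))
      post[j, combos[r, j]] <- post[j, combos[r, j]] + pr
  }
  post <- post / rowSums(post)
  expect_equal(unname(M5), post, tolerance = 1e-10)
  # a cherry with matching tips pulls its node above the uniform prior
  cherry <- ape::getMRCA(tree5, names(tips)[tips == "a"][1:2])
  if (all(tips[ape::extract.clade(tree5, cherry)$tip.label] == "a"))
    expect_gt(M5[as.character(cherry), "a"], 0.5)
})

test_that("rate and likelihood agree with an independent Mk implementation", {
  skip_if_not_installed("phytools")
  # phylogenetically structured tip states so the rate is well identified
  tree <- ape::rphylo(12, 0.4, 0)
  h <- floramorph:::sim_mk_history(tree, q = 0.04, c("g", "b", "l"),
                                   seed = 3)
  tips <- setNames(h$node_states[1:12], tree$tip.label)
  if (length(unique(tips)) < 2) tips[1] <- setdiff(c("g", "b"), tips[1])[1]
  fit <- mk_er_fit(tree, tips)
  ref <- phytools::fitMk(tree, tips, model = "ER", pi = "equal")
  expect_equal(fit$logL, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$q), unname(ref$rates), tolerance = 1e-2)
})

test_that("stochastic maps are seed-deterministic, collapse at q = 0, and
           their node frequencies track the marginals", {
  set.seed(4)
  tree <- ape::rphylo(10, 0.4, 0)
  tips <- setNames(rep(c("x", "y"), 5), tree$tip.label)
  fit <- mk_er_fit(tree, tips)
  m1 <- stochastic_maps(fit, n_draws = 30, seed = 5)
  m2 <- stochastic_maps(fit, n_draws = 30, seed = 5)
  expect_equal(m1$node_frequencies, m2$node_frequencies)
  # frequencies approach marginal probabilities (3 binomial SE, 400 draws)
  m <- stochastic_maps(fit, n_draws = 400, seed = 6)
  M <- marginal_states(fit)
  se <- sqrt(pmax(M * (1 - M), 1e-6) / 400)
  expect_true(all(abs(m$node_frequencies - M) <= 3 * se + 0.02))
  # monomorphic tips at the q = 0 boundary give the constant history
  suppressWarnings(f0 <- mk_er_fit(tree, setNames(rep("x", 10),
                                                  tree$tip.label),
                                   states = c("x", "y")))
  m0 <- stochastic_maps(f0, n_draws = 5, seed = 1)
  expect_true(all(m0$node_frequencies[, "x"] == 1))
})

test_that("draw segments tile every branch and expected transition counts
           rise with the rate", {
  set.seed(7)
  tree <- ape::rphylo(6, 0.5, 0)
  tips <- setNames(rep(c("x", "y"), 3), tree$tip.label)
  fit <- mk_er_fit(tree, tips)
  maps <- stochastic_maps(fit, n_draws = 20, seed = 2)
  for (d in maps$draws[1:3]) {
    lens <- vapply(seq_along(d$edge_segments), function(e)
      sum(d$edge_segments[[e]]$t1 - d$edge_segments[[e]]$t0), numeric(1))
    expect_equal(lens, tree$edge.length, tolerance = 1e-8)
  }
  # transitions per unconditional history increase with q
  n_trans <- function(q, reps = 200) {
    mean(vapply(seq_len(reps), function(i) {
      h <- floramorph:::sim_mk_history(tree, q, c("x", "y"), seed = 1000 + i)
      sum(vapply(h$segments, nrow, integer(1)) - 1)
    }, numeric(1)))
  }
  expect_lt(n_trans(0.02), n_trans(0.2))
})
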