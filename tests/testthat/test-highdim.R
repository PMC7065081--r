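test_that("phylogenetic covariance matrices match closed forms and limits", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_covariance("BM", NULL, tree)
  expect_equal(C, rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)),
               ignore_attr = TRUE)
  C_ou <- phylo_covariance("OU", 1e-8, tree)
  expect_equal(C_ou, C, tolerance = 1e-6, ignore_attr = TRUE)
  C_eb <- phylo_covariance("EB", 0, tree)
  expect_equal(C_eb, C, tolerance = 1e-12, ignore_attr = TRUE)
  r <- -0.4
  C_eb2 <- phylo_covariance("EB", r, tree)
  expect_equal(diag(C_eb2), rep((exp(2 * r) - 1) / r, 3), tolerance = 1e-12)
  expect_error(phylo_covariance("OU", -1, tree), "alpha")
  expect_error(phylo_covariance("EB", 1, tree), "r <= 0")
})

test_that("penalized fit with p = 1 and lambda = 0 reproduces the univariate
           GLS likelihood path", {
  sim <- simulate_tree_and_traits(synthetic_spec(n_species = 12, seed = 4),
                                  "BM1", states = "A")
  tr <- sim$tree
  y <- sim$tip_traits
  Y <- matrix(y, ncol = 1, dimnames = list(names(y), "trait"))
  pf <- penalized_fit(Y, tr, "BM", lambda_grid = 0, method = "ML")
  fu <- fit_model("BM1", sim$painting, y)
  expect_equal(pf$logL, fu$logL, tolerance = 1e-8)
  # and for OU at a fixed pull, against the concentrated likelihood
  a <- 0.5 / tree_depth(tr)
  pf_ou <- penalized_fit(Y, tr, "OU", lambda_grid = 0, fixed_parameter = a,
                         method = "ML")
  C <- phylo_covariance("OU", a, tr)
  ch <- chol(C)
  one <- backsolve(ch, rep(1, 12), transpose = TRUE)
  yt <- backsolve(ch, as.numeric(y[tr$tip.label]), transpose = TRUE)
  mu <- sum(one * yt) / sum(one^2)
  s2 <- sum((yt - mu * one)^2) / 12
  direct <- model_loglik("OU1", list(sigma2 = s2, alpha = a, theta = mu),
                         sim$painting, y)
  expect_equal(pf_ou$logL, direct, tolerance = 1e-8)
})

test_that("full shrinkage keeps the penalized likelihood finite when traits
           outnumber species", {
  set.seed(5)
  sim <- simulate_tree_and_traits(synthetic_spec(n_species = 10, seed = 5),
                                  "BM1", states = "A")
  Y <- matrix(rnorm(10 * 25), 10, 25, dimnames = list(sim$tree$tip.label, NULL))
  pf <- penalized_fit(Y, sim$tree, "BM", lambda_grid = 1)
  expect_true(is.finite(pf$logL))
  expect_equal(pf$lambda, 1)
  expect_true(all(abs(pf$R[upper.tri(pf$R)]) < 1e-12))
  expect_error(penalized_fit(Y[1:2, ], ape::keep.tip(sim$tree,
                             sim$tree$tip.label[1:2]), "BM"), "at least 3")
})

test_that("GIC model choice is invariant to adding a constant to all traits", {
  set.seed(6)
  sim <- simulate_tree_and_traits(synthetic_spec(n_species = 12, seed = 6),
                                  "BM1", states = "A")
  tr <- sim$tree
  C <- phylo_covariance("BM", NULL, tr)
  Y <- t(chol(C)) %*% matrix(rnorm(12 * 8), 12, 8)
  rownames(Y) <- tr$tip.label
  g1 <- vapply(c("BM", "OU"), function(m) penalized_fit(Y, tr, m)$GIC,
               numeric(1))
  g2 <- vapply(c("BM", "OU"), function(m)
    penalized_fit(Y + 11.3, tr, m)$GIC, numeric(1))
  expect_equal(g1 - min(g1), g2 - min(g2), tolerance = 1e-6)
})

test_that("ancestral reconstruction matches GLS closed forms on two-tip
           trees and returns observed values at the tips", {
  # symmetric two-tip tree: root reconstruction is the plain tip mean
  tr <- ape::read.tree(text = "(A:1,B:1);")
  Y <- matrix(c(1, 3, -2, 4), 2, 2, dimnames = list(c("A", "B"), NULL))
  f <- penalized_fit(Y, tr, "BM", lambda_grid = 1, method = "ML")
  anc <- ancestral_shapes(f)
  expect_equal(as.vector(anc$estimates), c(2, 1), tolerance = 1e-12)
  # unequal branches 1 and 3: root = (3 yA + yB) / 4
  tr2 <- ape::read.tree(text = "(A:1,B:3);")
  y <- c(A = 1, B = 5)
  Y2 <- matrix(y, ncol = 1, dimnames = list(names(y), NULL))
  f2 <- penalized_fit(Y2, tr2, "BM", lambda_grid = 1, method = "ML")
  anc2 <- ancestral_shapes(f2)
  expect_equal(unname(anc2$estimates[1, 1]), (3 * 1 + 5) / 4,
               tolerance = 1e-12)
  # tip "reconstructions" equal the observed data (BLUP property)
  anc_tips <- ancestral_shapes(f2, nodes = 1:2)
  expect_equal(as.vector(anc_tips$estimates), as.vector(y), tolerance = 1e-8)
  expect_error(ancestral_shapes(f2, nodes = 99), "node id")
})

test_that("reconstruction error beats a permuted-tip baseline on simulated
           histories", {
  sim <- simulate_tree_and_traits(synthetic_spec(n_species = 50, seed = 7,
                                                 birth_rate = 0.3), "BM1")
  Y <- matrix(sim$tip_traits, ncol = 1,
              dimnames = list(names(sim$tip_traits), NULL))
  f <- penalized_fit(Y, sim$tree, "BM", lambda_grid = 0, method = "ML")
  anc <- ancestral_shapes(f)
  err <- mean((anc$estimates[, 1] - sim$node_traits)^2)
  set.seed(77)
  base <- mean(replicate(20, {
    Yp <- Y; rownames(Yp) <- sample(rownames(Y))
    fp <- penalized_fit(Yp, sim$tree, "BM", lambda_grid = 0, method = "ML")
    mean((ancestral_shapes(fp)$estimates[, 1] - sim$node_traits)^2)
  }))
  expect_lt(err, base)
})

test_that("TPS interpolates landmarks exactly, reproduces affine maps, and
           is the identity for identical configurations", {
  set.seed(8)
  S <- matrix(rnorm(33 * 3), 33, 3)
  pts0 <- matrix(rnorm(60), 20, 3)
  w <- tps_warp(S, S, points = pts0)
  expect_equal(w[, ], pts0, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(tps_warp(S, S)[, ], S, tolerance = 1e-10, ignore_attr = TRUE)
  # affine target: warp coefficients vanish, points map affinely
  A <- matrix(rnorm(9), 3) + diag(3); b <- rnorm(3)
  Tg <- S %*% A + matrix(b, 33, 3, byrow = TRUE)
  pts <- matrix(rnorm(45), 15, 3)
  wa <- tps_warp(S, Tg, pts)
  expect_lt(attr(wa, "bending_energy"), 1e-8)
  expect_equal(wa[, ], pts %*% A + matrix(b, 15, 3, byrow = TRUE),
               tolerance = 1e-8, ignore_attr = TRUE)
  # random target: source landmarks land exactly on targets
  Tg2 <- S + 0.2 * matrix(rnorm(99), 33, 3)
  w2 <- tps_warp(S, Tg2)
  expect_lt(max(abs(w2[, ] - Tg2)), 1e-8)
  expect_error(tps_warp(S[1:4, ], Tg2[1:4, ]), "at least 5")
})
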