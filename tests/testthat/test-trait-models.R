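two_tip_painting <- function(t = 1, states = "A") {
  tree <- ape::read.tree(text = sprintf("(A:%g,B:%g);", t, t))
  paint_regimes(tree, rep(states[1], 3), regimes = states)
}

test_that("regime paintings tile branches and conserve branch time", {
  set.seed(1)
  tree <- ape::rphylo(4, 0.5, 0)
  ns <- c(rep("x", 4), "x", "y", "y")
  p <- paint_regimes(tree, ns, regimes = c("x", "y"))
  lens <- vapply(seq_along(p$edge_segments), function(e)
    sum(p$edge_segments[[e]]$t1 - p$edge_segments[[e]]$t0), numeric(1))
  expect_equal(lens, tree$edge.length, tolerance = 1e-12)
  expect_error(paint_regimes(tree, c(rep("x", 6), "z"),
                             regimes = c("x", "y")), "unknown regime")
})

test_that("BM log-likelihood matches the closed-form bivariate normal on a
           two-tip tree", {
  p <- two_tip_painting(t = 1.5)
  y <- c(A = 0.3, B = -0.9)
  s2 <- 0.7; z0 <- 0.1
  ll <- model_loglik("BM1", list(sigma2 = s2, z0 = z0), p, y)
  V <- diag(rep(1.5 * s2, 2))
  direct <- -0.5 * (2 * log(2 * pi) + determinant(V)$modulus[1] +
                      t(y - z0) %*% solve(V, y - z0))
  expect_equal(ll, as.numeric(direct), tolerance = 1e-10)
})

test_that("OU collapses to BM as the pull vanishes; equal-parameter regime
           models collapse to their global versions", {
  sim <- simulate_tree_and_traits(synthetic_spec(n_species = 10, seed = 2),
                                  "BM1", states = c("A", "B"))
  p <- sim$painting; y <- sim$tip_traits
  ll_bm <- model_loglik("BM1", list(sigma2 = 0.8, z0 = 0.2), p, y)
  ll_ou <- model_loglik("OU1", list(sigma2 = 0.8, alpha = 1e-9, theta = 0.2),
                        p, y)
  expect_equal(ll_ou, ll_bm, tolerance = 1e-4)
  ll_bms <- model_loglik("BMS", list(sigma2 = c(0.8, 0.8), z0 = 0.2), p, y)
  expect_equal(ll_bms, ll_bm, tolerance = 1e-10)
  a <- 0.3
  ll_ou1 <- model_loglik("OU1", list(sigma2 = 1, alpha = a, theta = 0.5), p, y)
  ll_oum <- model_loglik("OUM", list(sigma2 = 1, alpha = a,
                                     theta = c(0.5, 0.5)), p, y)
  ll_oumv <- model_loglik("OUMV", list(sigma2 = c(1, 1), alpha = a,
                                       theta = c(0.5, 0.5)), p, y)
  expect_equal(ll_oum, ll_ou1, tolerance = 1e-10)
  expect_equal(ll_oumv, ll_ou1, tolerance = 1e-10)
})

test_that("likelihood equals the explicit GLS quadratic form and is
           invariant to tip ordering", {
  sim <- simulate_tree_and_traits(synthetic_spec(n_species = 8, seed = 3),
                                  "OUM", states = c("A", "B"))
  p <- sim$painting; y <- sim$tip_traits
  pars <- list(sigma2 = 0.02, alpha = 0.12, theta = c(-1, 2))
  ll <- model_loglik("OUM", pars, p, y)
  st <- floramorph:::painting_structure(p)
  vm <- floramorph:::regime_vcv_mean(st, rep(pars$sigma2, 2),
                                     alpha = pars$alpha, theta = pars$theta)
  yv <- as.numeric(y[p$tree$tip.label])
  direct <- -0.5 * (length(yv) * log(2 * pi) +
                      determinant(vm$V)$modulus[1] +
                      t(yv - vm$mean) %*% solve(vm$V, yv - vm$mean))
  expect_equal(ll, as.numeric(direct), tolerance = 1e-8)
  expect_equal(model_loglik("OUM", pars, p, rev(y)), ll, tolerance = 1e-12)
  # V is symmetric positive definite
  expect_true(isSymmetric(vm$V, tol = 1e-12))
  expect_gt(min(eigen(vm$V, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("AICc arithmetic and Akaike weights are exact", {
  expect_equal(aicc(10, 3, 19), -12.4)
  f1 <- structure(list(model = "m1", logL = 10, k = 3, n = 19, AICc = -12.4,
                       hessian_ok = TRUE, trait = 1:3), class = "model_fit")
  f2 <- f1; f2$model <- "m2"
  tab <- model_table(list(f1, f2))
  expect_equal(tab$AICc_weight, c(0.5, 0.5))
  f3 <- f1; f3$model <- "m3"; f3$hessian_ok <- FALSE
  tab2 <- model_table(list(f1, f2, f3))
  expect_true(is.na(tab2$AICc_weight[tab2$model == "m3"]))
  expect_equal(sum(tab2$AICc_weight, na.rm = TRUE), 1, tolerance = 1e-9)
  f4 <- f1; f4$trait <- 4:6
  expect_error(model_table(list(f1, f4)), "identical trait data")
})

test_that("BM rate is recovered from simulated data", {
  ok <- 0L
  for (r in 1:8) {
    sim <- simulate_tree_and_traits(synthetic_spec(n_species = 60,
                                                   seed = 500 + r,
                                                   birth_rate = 0.3), "BM1")
    f <- fit_model("BM1", sim$painting, sim$tip_traits)
    ok <- ok + (abs(f$parameters$sigma2 - 1) < 0.25)
  }
  expect_gte(ok, 6L)
})

test_that("single-regime paintings make BMS and OUM equal BM1 and OU1 at
           the optimum", {
  sim <- simulate_tree_and_traits(synthetic_spec(n_species = 12, seed = 6),
                                  "BM1", states = "A")
  p <- sim$painting; y <- sim$tip_traits
  f_bm <- fit_model("BM1", p, y)
  f_bms <- fit_model("BMS", p, y, starts = 3)
  expect_equal(f_bms$logL, f_bm$logL, tolerance = 1e-6)
})

test_that("non-ultrametric trees are rejected for regime models", {
  tree <- ape::read.tree(text = "((A:1,B:2):1,C:2);")
  p <- paint_regimes(tree, rep("x", 5), regimes = "x")
  expect_error(model_loglik("OU1", list(sigma2 = 1, alpha = 1, theta = 0),
                            p, c(A = 1, B = 0, C = 2)),
               "ultrametric")
})
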