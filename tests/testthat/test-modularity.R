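test_that("RV coefficient: duplicated block gives 1, independence gives 0,
           single-variable case is squared Pearson", {
  set.seed(1)
  A <- crossprod(matrix(rnorm(9), 3))      # one landmark's 3x3 covariance
  S <- rbind(cbind(A, A), cbind(A, A))     # landmark 2 duplicates landmark 1
  expect_equal(rv_coefficient(covariance_bundle(S), 1, 2), 1, tolerance = 1e-12)
  S0 <- rbind(cbind(A, matrix(0, 3, 3)), cbind(matrix(0, 3, 3), 2 * A))
  expect_equal(rv_coefficient(covariance_bundle(S0), 1, 2), 0)
  # only x-coordinates vary, correlation 0.5 -> RV = 0.25
  S1 <- matrix(0, 6, 6)
  S1[1, 1] <- S1[4, 4] <- 1; S1[1, 4] <- S1[4, 1] <- 0.5
  expect_equal(rv_coefficient(covariance_bundle(S1), 1, 2), 0.25)
  expect_error(rv_coefficient(covariance_bundle(S1), 1, 1), "disjoint")
})

test_that("multiset RV equals the brute-force mean of pairwise RVs", {
  for (seed in 1:5) {
    cb <- random_landmark_cov(L = 7, seed = seed)
    g <- sample(rep(1:3, length.out = 7))
    expect_equal(multiset_rv(cb, g), brute_multiset_rv(cb$S, g),
                 tolerance = 1e-12)
  }
  # K = 2 reduces exactly to the pairwise coefficient
  cb <- random_landmark_cov(L = 6, seed = 9)
  g <- c(1, 1, 1, 2, 2, 2)
  expect_equal(multiset_rv(cb, g),
               rv_coefficient(cb, 1:3, 4:6), tolerance = 1e-14)
})

test_that("RV is symmetric and invariant to within-block rotations and
           scalings", {
  cb <- random_landmark_cov(L = 6, seed = 4)
  expect_equal(rv_coefficient(cb, 1:3, 4:6), rv_coefficient(cb, 4:6, 1:3))
  rv0 <- rv_coefficient(cb, 1:3, 4:6)
  expect_gte(rv0, 0); expect_lte(rv0, 1)
  set.seed(5)
  for (r in 1:3) {
    QA <- qr.Q(qr(matrix(rnorm(81), 9)))
    QB <- qr.Q(qr(matrix(rnorm(81), 9)))
    Tm <- as.matrix(Matrix::bdiag(3 * QA, 0.2 * QB))
    S2 <- Tm %*% cb$S %*% t(Tm)
    expect_equal(rv_coefficient(covariance_bundle(S2), 1:3, 4:6), rv0,
                 tolerance = 1e-10)
  }
})

test_that("partition enumeration counts unlabelled partitions exactly", {
  expect_equal(nrow(random_partitions(6, c(3, 3), mode = "exhaustive")), 10)
  expect_equal(nrow(random_partitions(4, c(2, 2), mode = "exhaustive")), 3)
  expect_equal(nrow(random_partitions(5, c(2, 2, 1), mode = "exhaustive")), 15)
  p <- random_partitions(6, c(3, 3), mode = "exhaustive")
  expect_equal(anyDuplicated(apply(p, 1, paste, collapse = "")), 0L)
  expect_equal(count_partitions(c(3, 3)), 10, tolerance = 1e-9)
  expect_error(random_partitions(30, c(15, 15), mode = "exhaustive", cap = 100),
               "refused")
})

test_that("sampled partitions are deterministic given the seed and preserve
           module sizes", {
  a <- random_partitions(12, c(4, 4, 4), n = 50, seed = 7)
  b <- random_partitions(12, c(4, 4, 4), n = 50, seed = 7)
  expect_identical(a, b)
  expect_true(all(apply(a, 1, function(g) all(tabulate(g) == c(4, 4, 4)))))
})

test_that("modularity test on a planted block-diagonal covariance puts the
           true partition at the null floor", {
  set.seed(6)
  blocks <- lapply(1:2, function(i) {
    A <- matrix(rnorm(81), 9); crossprod(A) / 9
  })
  S <- as.matrix(Matrix::bdiag(blocks))
  cb <- covariance_bundle(S, df = 50)
  hyp <- partition_hypothesis("truth", rep(1:2, each = 3))
  res <- modularity_test(cb, hyp, n_partitions = 100, seed = 1)
  expect_true(res$exhaustive)
  expect_equal(res$n_partitions_evaluated, 10)
  expect_equal(res$proportion_lower, 0)
  expect_equal(res$rv_observed, 0)
})

test_that("sampled and exhaustive null proportions agree within 3 SE", {
  cb <- random_landmark_cov(L = 8, seed = 11)
  hyp <- partition_hypothesis("h", rep(1:2, each = 4))
  ex <- modularity_test(cb, hyp, n_partitions = 35, seed = 1)  # 35 = C(8,4)/2
  expect_true(ex$exhaustive)
  sa <- modularity_test(cb, hyp, n_partitions = 4000, seed = 2,
                        exhaustive_cap = 1)
  expect_false(sa$exhaustive)
  se <- sqrt(ex$proportion_lower * (1 - ex$proportion_lower) / 4000)
  expect_lt(abs(sa$proportion_lower - ex$proportion_lower), 3 * se + 1e-12)
})
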