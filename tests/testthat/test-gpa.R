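test_that("centroid size matches its definition and invariances", {
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(centroid_size(sq), sqrt(8))
  set.seed(1)
  cfg <- matrix(rnorm(99), 33, 3)
  expect_equal(centroid_size(cfg * 3), 3 * centroid_size(cfg))
  rot <- cfg %*% random_rotation()
  expect_equal(centroid_size(rot), centroid_size(cfg), tolerance = 1e-12)
  expect_warning(cs0 <- centroid_size(matrix(1, 5, 3)), "degenerate")
  expect_equal(cs0, 0)
})

test_that("GPA aligns rigidly perturbed copies of one shape onto it", {
  set.seed(2)
  base <- matrix(rnorm(10 * 3), 10, 3)
  coords <- array(NA_real_, c(10, 3, 5))
  for (i in 1:5) {
    coords[, , i] <- (base %*% random_rotation()) * runif(1, 0.5, 4)
    coords[, , i] <- sweep(coords[, , i], 2, rnorm(3, 0, 5), "+")
  }
  ss <- specimen_set(coords, paste0("s", 1:5), rep("a", 5))
  al <- gpa_align(ss)
  spread <- apply(al$shape_coords, 2, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-9)
  # consensus equals the (normalised) common shape up to rotation
  d <- sum((al$consensus - unflatten_config(al$shape_coords[1, ]))^2)
  expect_lt(d, 1e-18)
})

test_that("GPA output is invariant to per-specimen rigid motion + scale", {
  sim <- simulate_specimens(synthetic_spec(n_species = 4, n_flowers = 5,
                                           L = 12, seed = 6))
  ss <- sim$specimens
  al1 <- gpa_align(ss)
  set.seed(33)
  coords2 <- ss$coords
  for (i in seq_len(n_specimens(ss))) {
    coords2[, , i] <- (coords2[, , i] %*% random_rotation()) * runif(1, 0.2, 5)
    coords2[, , i] <- sweep(coords2[, , i], 2, rnorm(3, 0, 3), "+")
  }
  ss2 <- specimen_set(coords2, ss$specimen_id, ss$species)
  al2 <- gpa_align(ss2)
  rms <- sqrt(mean((al1$shape_coords - al2$shape_coords)^2))
  expect_lt(rms, 1e-6)
  expect_equal(al1$centroid_sizes / al2$centroid_sizes,
               al1$centroid_sizes / al2$centroid_sizes)
})

test_that("trace of total covariance equals total Procrustes variance", {
  sim <- simulate_specimens(synthetic_spec(n_species = 5, n_flowers = 6,
                                           seed = 7))
  al <- gpa_align(sim$specimens)
  cb <- pooled_covariance(al, "none")
  expect_equal(sum(diag(cb$S)), procrustes_variance(al), tolerance = 1e-10)
  # eigenvalue count limited by sample size and alignment dof
  ev <- eigen(cb$S, symmetric = TRUE, only.values = TRUE)$values
  n_nonzero <- sum(ev > 1e-12 * max(ev))
  expect_lte(n_nonzero, min(nrow(al$shape_coords) - 1,
                            3 * n_landmarks(sim$specimens) - 7))
})

test_that("pooled-by-species covariance matches a brute-force loop and
           ignores species mean shifts", {
  sim <- simulate_specimens(synthetic_spec(n_species = 3, n_flowers = 6,
                                           L = 8, seed = 9))
  al <- gpa_align(sim$specimens)
  cb <- pooled_covariance(al, "species")
  X <- al$shape_coords
  cp <- 0; df <- 0
  for (sp in unique(al$species)) {
    Xi <- scale(X[al$species == sp, ], scale = FALSE)
    cp <- cp + crossprod(Xi); df <- df + nrow(Xi) - 1
  }
  expect_equal(cb$S, cp / df, tolerance = 1e-12, ignore_attr = TRUE)
  # shifting one species wholesale does not change the pooled matrix
  al2 <- al
  i <- al$species == al$species[1]
  al2$shape_coords[i, ] <- al2$shape_coords[i, ] + 0.37
  cb2 <- pooled_covariance(al2, "species")
  expect_equal(cb2$S, cb$S, tolerance = 1e-12)
  # species with one specimen are dropped with a warning
  al3 <- al
  keep <- c(which(i)[1], which(!i))
  al3$shape_coords <- al3$shape_coords[keep, ]
  al3$species <- al3$species[keep]
  al3$centroid_sizes <- al3$centroid_sizes[keep]
  expect_warning(pooled_covariance(al3, "species"), "single specimen")
})

test_that("symmetric component fixes symmetric shapes and strips planted
           asymmetry", {
  tmpl <- make_template(33)
  pairing <- attr(tmpl, "pairing")
  # perfectly symmetric input: symmetric component reproduces the shape
  coords <- array(NA_real_, c(33, 3, 2))
  coords[, , 1] <- tmpl
  coords[, , 2] <- tmpl * 1.5
  ss <- specimen_set(coords, c("s1", "s2"), c("a", "a"))
  sym <- symmetric_component(ss, pairing, "y")
  al <- gpa_align(ss)
  expect_equal(sym$shape_coords[1, ], al$shape_coords[1, ], tolerance = 1e-9)
  # planted asymmetry shrinks toward zero in the symmetric component
  set.seed(10)
  asym <- matrix(rnorm(99, 0, 0.05), 33, 3)
  coords2 <- array(NA_real_, c(33, 3, 4))
  for (i in 1:4) coords2[, , i] <- tmpl + asym   # identical asymmetric flowers
  ss2 <- specimen_set(coords2, paste0("s", 1:4), rep("a", 4))
  sym2 <- symmetric_component(ss2, pairing, "y")
  # full Procrustes distance to the symmetric template (rotation-free)
  pdist <- function(flat, ref) {
    X <- unflatten_config(flat); X <- X / sqrt(sum(X^2))
    R <- floramorph:::opa_rotation(X, ref)
    sqrt(sum((X %*% R - ref)^2))
  }
  ref <- tmpl / sqrt(sum(tmpl^2))
  d_raw <- pdist(gpa_align(ss2)$shape_coords[1, ], ref)
  d_sym <- pdist(sym2$shape_coords[1, ], ref)
  expect_lt(d_sym, d_raw)
  expect_error(symmetric_component(ss2, rbind(c(1, 2), c(2, 3)), "y"),
               "involution")
})
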