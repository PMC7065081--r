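#' Deterministic urn-shaped flower landmark template
#'
#' Builds an idealised ericoid flower as labelled 3D points: a corolla tube
#' of stacked rings (widest ring, narrow mouth ring), sepal tips, petal-lobe
#' meeting points, anther tips, and the gynoecium (ovary/style transition
#' and stigma).  The template is bilaterally symmetric about the xz-plane
#' and normalised to unit centroid size.  Attributes carry the anatomical
#' roles, the default module maps for the four modularity hypotheses, the
#' mirror pairing, and tube base/mouth indices.
#'
#' @param L number of landmarks (default 33; minimum 8).  For `L != 33`
#'   points are taken from the canonical 33 in role order.
#' @return L x 3 matrix with attributes `roles`, `pairing`, `partitions`,
#'   `tube_base`, `tube_mouth`.
#' @export
make_template <- function(L = 33) {
  if (L < 8) stop("need at least 8 landmarks")
  ring <- function(n, radius, z, phase = 0) {
    ang <- phase + 2 * pi * (seq_len(n) - 1) / n
    cbind(radius * cos(ang), radius * sin(ang), z)
  }
  pts <- rbind(
    c(0, 0, 0),                       # 1  corolla/tube base
    ring(4, 0.85, 0.12),              # 2-5   sepal tips
    ring(8, 0.55, 0.35),              # 6-13  widest corolla ring
    ring(8, 0.18, 0.90),              # 14-21 corolla mouth (narrowest)
    ring(4, 0.28, 1.02),              # 22-25 petal lobe meeting points
    ring(6, 0.22, 0.80),              # 26-31 anther tips
    c(0, 0, 0.25),                    # 32 ovary/style transition
    c(0, 0, 0.98))                    # 33 stigma
  roles <- c("base", rep("sepal", 4), rep("petal", 8), rep("mouth", 8),
             rep("lobe", 4), rep("stamen", 6), "ovary", "stigma")
  keep <- seq_len(min(L, 33))
  pts <- pts[keep, , drop = FALSE]
  roles <- roles[keep]
  pts <- sweep(pts, 2, colMeans(pts))
  pts <- pts / sqrt(sum(pts^2))
  # mirror pairing about y -> -y: ring points at angle a pair with -a
  pair_of <- integer(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    tgt <- pts[i, ] * c(1, -1, 1)
    d <- colSums((t(pts) - tgt)^2)
    pair_of[i] <- which.min(d)
  }
  pairing <- unique(t(apply(cbind(seq_len(nrow(pts)), pair_of), 1, sort)))
  pairing <- pairing[pairing[, 1] != pairing[, 2], , drop = FALSE]
  partitions <- if (L == 33) default_partitions(roles) else NULL
  structure(pts,
            roles = roles, pairing = pairing, partitions = partitions,
            tube_base = 1L, tube_mouth = if (L >= 22) 22L else 2L,
            dimnames = list(paste0("lm", keep), c("x", "y", "z")))
}

# The four canonical hypotheses over the 33-landmark template.
default_partitions <- function(roles) {
  corolla <- roles %in% c("base", "petal", "mouth", "lobe")
  attraction <- ifelse(roles %in% c("sepal") | corolla, 1L, 2L)
  developmental <- ifelse(roles == "sepal", 1L,
                   ifelse(corolla, 2L,
                   ifelse(roles == "stamen", 3L, 4L)))
  functional1 <- ifelse(roles %in% c("mouth", "stamen"), 1L,     # deposition
                 ifelse(roles %in% c("lobe", "stigma"), 2L, 3L)) # receipt/rest
  functional2 <- ifelse(roles == "mouth", 1L,                    # restriction
                 ifelse(roles %in% c("ovary", "stigma"), 2L, 3L))
  list(attraction_reproduction =
         partition_hypothesis("attraction_reproduction", attraction),
       developmental = partition_hypothesis("developmental", developmental),
       functional1 = partition_hypothesis("functional1", functional1),
       functional2 = partition_hypothesis("functional2", functional2))
}

#' Default synthetic study specification
#'
#' Mirrors the study design the generator emulates: 19 species with about
#' 10 flowers each, 33 landmarks, and syndrome frequencies of 12 generalist,
#' 4 bird, 2 long-proboscid-fly and 1 wind species.  Noise has planted
#' block-modular covariance (within-module correlation `rho_w`, between
#' `rho_b`, per the developmental modules by default), an allometric
#' component, syndrome-specific tube deformations, and every flower is
#' re-expressed under a random rigid motion and scale so alignment is
#' exercised.
#'
#' @param n_species,n_flowers,L design sizes.
#' @param rho_w,rho_b within/between-module noise correlations
#'   (`rho_w > rho_b >= 0`).
#' @param noise_scale per-coordinate noise standard deviation.
#' @param species_scale standard deviation of the species-mean displacement.
#' @param allometry_strength coefficient of the planted allometric vector.
#' @param birth_rate pure-birth speciation rate for the chronogram.
#' @param q_mk syndrome transition rate used when regimes are evolved.
#' @param seed RNG seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_species = 19, n_flowers = 10, L = 33,
                           rho_w = 0.6, rho_b = 0.1,
                           noise_scale = 0.012, species_scale = 0.02,
                           allometry_strength = 0.08,
                           birth_rate = 0.15, q_mk = 0.05, seed = 1) {
  if (!(rho_w > rho_b && rho_b >= 0)) stop("need rho_w > rho_b >= 0")
  structure(list(n_species = n_species, n_flowers = n_flowers, L = L,
                 rho_w = rho_w, rho_b = rho_b, noise_scale = noise_scale,
                 species_scale = species_scale,
                 allometry_strength = allometry_strength,
                 birth_rate = birth_rate, q_mk = q_mk, seed = seed),
            class = "synthetic_spec")
}

# block correlation matrix over 3L variables from a landmark-level module
# assignment
block_correlation <- function(assignment, rho_w, rho_b) {
  g <- rep(assignment, each = 3)
  p <- length(g)
  R <- matrix(rho_b, p, p)
  same <- outer(g, g, "==")
  R[same] <- rho_w
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("requested correlation structure is not PSD")
  R
}

syndrome_frequencies <- function(n_species) {
  base <- c(generalist = 12, bird = 4, lpf = 2, wind = 1)
  if (n_species == 19) return(rep(names(base), base))
  prop <- round(base / sum(base) * n_species)
  prop[prop == 0] <- 1
  while (sum(prop) > n_species) prop[which.max(prop)] <- prop[which.max(prop)] - 1
  while (sum(prop) < n_species) prop[1] <- prop[1] + 1
  rep(names(prop), prop)
}

# syndrome-specific template deformation: tube elongation/constriction
syndrome_deform <- function(template, syndrome) {
  z <- template[, 3] - min(template[, 3])
  zr <- z / max(z)
  el <- switch(syndrome, generalist = 1.0, bird = 1.7, lpf = 2.4, wind = 0.75)
  con <- switch(syndrome, generalist = 1.0, bird = 0.85, lpf = 0.6, wind = 1.15)
  out <- template
  out[, 3] <- template[, 3] * el
  radial <- 1 + (con - 1) * zr          # constrict progressively to the mouth
  out[, 1] <- template[, 1] * radial
  out[, 2] <- template[, 2] * radial
  out
}

#' Simulate a specimen set with planted structure
#'
#' Per species: mean = deformed template (syndrome) + species effect.  Per
#' flower: mean + allometric vector x (log centroid-size draw) + noise with
#' block-modular covariance; the configuration is then re-expressed under a
#' random rotation, translation and scale.  The returned truth record holds
#' every planted quantity.
#'
#' @param spec a [synthetic_spec()].
#' @param module_truth landmark assignment generating the noise blocks
#'   (default: the developmental partition of the template).
#' @param syndromes optional character vector (length `n_species`, or named
#'   by species) overriding the default syndrome assignment; used to keep
#'   syndromes coherent with a separately simulated phylogeny.
#' @return list with `specimens` (a [specimen_set()]) and `truth`.
#' @export
simulate_specimens <- function(spec, module_truth = NULL, syndromes = NULL) {
  set.seed(spec$seed)
  tmpl <- make_template(spec$L)
  if (is.null(module_truth)) {
    parts <- attr(tmpl, "partitions")
    module_truth <- if (!is.null(parts)) parts$developmental$assignment
                    else rep(seq_len(4), length.out = spec$L)[order(seq_len(spec$L))]
  }
  R <- block_correlation(module_truth, spec$rho_w, spec$rho_b)
  cR <- chol(R)
  species <- sprintf("sp%02d", seq_len(spec$n_species))
  if (is.null(syndromes)) {
    syndromes <- syndrome_frequencies(spec$n_species)
  } else if (!is.null(names(syndromes))) {
    syndromes <- as.character(syndromes[species])
  } else syndromes <- as.character(syndromes)
  if (length(syndromes) != spec$n_species || anyNA(syndromes))
    stop("syndromes must cover every species")
  allo_dir <- stats::rnorm(3 * spec$L)
  allo_dir <- allo_dir / sqrt(sum(allo_dir^2))
  allo_vec <- spec$allometry_strength * allo_dir
  coords <- array(NA_real_, c(spec$L, 3, spec$n_species * spec$n_flowers))
  ids <- character(spec$n_species * spec$n_flowers)
  spvec <- character(spec$n_species * spec$n_flowers)
  true_logcs <- numeric(spec$n_species * spec$n_flowers)
  species_means <- list()
  idx <- 0L
  for (s in seq_len(spec$n_species)) {
    base <- syndrome_deform(tmpl, syndromes[s])
    sp_effect <- matrix(stats::rnorm(spec$L * 3, 0, spec$species_scale),
                        spec$L, 3)
    mean_cfg <- base + sp_effect
    species_means[[species[s]]] <- mean_cfg
    for (f in seq_len(spec$n_flowers)) {
      idx <- idx + 1L
      logcs <- stats::rnorm(1, 0, 0.15)
      noise <- as.vector(crossprod(cR, stats::rnorm(3 * spec$L))) *
        spec$noise_scale
      shape <- flatten_config(mean_cfg) + allo_vec * logcs + noise
      cfg <- unflatten_config(shape)
      # random rigid motion + a scale tied to the planted size draw, so the
      # observed centroid size carries the allometric signal
      Qr <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
      if (det(Qr) < 0) Qr[, 1] <- -Qr[, 1]
      size_factor <- switch(syndromes[s], generalist = 1, bird = 1.6,
                            lpf = 1.4, wind = 0.8)
      scale <- exp(logcs) * 10 * size_factor
      cfg <- (cfg %*% Qr) * scale
      cfg <- sweep(cfg, 2, stats::rnorm(3, 0, 10), "+")
      coords[, , idx] <- cfg
      ids[idx] <- sprintf("%s_f%02d", species[s], f)
      spvec[idx] <- species[s]
      true_logcs[idx] <- logcs
    }
  }
  smap <- data.frame(species = species, syndrome = syndromes,
                     status = "observed", stringsAsFactors = FALSE)
  specimens <- specimen_set(coords, ids, spvec,
                            rownames(tmpl), smap)
  list(specimens = specimens,
       truth = list(spec = spec, template = tmpl,
                    module_truth = module_truth,
                    partitions = attr(tmpl, "partitions"),
                    pairing = attr(tmpl, "pairing"),
                    tube_base = attr(tmpl, "tube_base"),
                    tube_mouth = attr(tmpl, "tube_mouth"),
                    allometry_vector = allo_vec,
                    log_centroid_size = true_logcs,
                    species_means = species_means,
                    syndromes = stats::setNames(syndromes, species)))
}

# unconditional ER history simulation on a tree (Gillespie per branch)
sim_mk_history <- function(tree, q, states, root_state = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(states)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  ns <- integer(nn)
  ns[ntip + 1] <- if (is.null(root_state)) sample.int(k, 1)
                  else match(root_state, states)
  h <- tree_node_heights(tree)
  ord <- order(h[tree$edge[, 1]])
  segs <- vector("list", nrow(tree$edge))
  for (e in ord) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    s <- ns[p]; pos <- 0
    reg <- integer(0); len <- numeric(0)
    repeat {
      w <- if (q > 0 && k > 1) stats::rexp(1, (k - 1) * q) else Inf
      if (pos + w >= t) {
        reg <- c(reg, s); len <- c(len, t - pos)
        break
      }
      reg <- c(reg, s); len <- c(len, w)
      pos <- pos + w
      cand <- setdiff(seq_len(k), s)
      s <- cand[sample.int(length(cand), 1)]
    }
    segs[[e]] <- data.frame(regime = states[reg], length = len)
    ns[ch] <- s
  }
  list(node_states = states[ns], segments = segs,
       painting = painting_from_segments(tree, segs, states,
                                         states[ns[ntip + 1]]))
}

# segment-wise exact trait simulation along a painting; returns node values
# (matrix nodes x nrep)
sim_trait_on_painting <- function(painting, model, params, nrep = 1,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- painting$tree
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  K <- length(painting$regimes)
  sigma2 <- rep_len(params$sigma2, K)
  alpha <- params$alpha %||% 0
  theta <- if (!is.null(params$theta)) rep_len(params$theta, K) else NULL
  x <- matrix(NA_real_, nn, nrep)
  root_val <- if (!is.null(params$z0)) params$z0
              else theta[painting$root_regime]
  x[ntip + 1, ] <- root_val
  h <- tree_node_heights(tree)
  ord <- order(h[tree$edge[, 1]])
  for (e in ord) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    v <- x[p, ]
    sg <- painting$edge_segments[[e]]
    for (i in seq_len(nrow(sg))) {
      dt <- sg$t1[i] - sg$t0[i]
      k <- sg$regime[i]
      if (alpha > 0) {
        e1 <- exp(-alpha * dt)
        v <- v * e1 + theta[k] * (1 - e1) +
          stats::rnorm(nrep, 0, sqrt(sigma2[k] * (1 - e1^2) / (2 * alpha)))
      } else {
        v <- v + stats::rnorm(nrep, 0, sqrt(sigma2[k] * dt))
      }
    }
    x[ch, ] <- v
  }
  rownames(x) <- c(tree$tip.label, ntip + seq_len(tree$Nnode))
  x
}

#' Simulate a chronogram, regime history and tip traits
#'
#' Generates a pure-birth ultrametric tree, evolves pollination-syndrome
#' regimes along it under the ER Markov model, and simulates a continuous
#' trait branch-wise under the requested model using exact segment
#' transitions.  Internal-node trait values are recorded so reconstruction
#' error can be scored.
#'
#' @param spec a [synthetic_spec()].
#' @param trait_model `"BM1"`, `"BMS"`, `"OU1"`, `"OUM"` or `"OUMV"`.
#' @param trait_params parameter list (see [model_loglik()]).
#' @param states regime labels (default the four syndromes).
#' @return list with `tree`, `painting`, `node_states`, `tip_traits`,
#'   `node_traits`, `params`.
#' @export
simulate_tree_and_traits <- function(spec, trait_model = "OUM",
                                     trait_params = NULL,
                                     states = c("generalist", "bird",
                                                "lpf", "wind")) {
  if (spec$n_species < 4) stop("need at least 4 species")
  set.seed(spec$seed)
  tree <- ape::rphylo(spec$n_species, birth = spec$birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%02d", seq_len(spec$n_species))
  hist <- sim_mk_history(tree, spec$q_mk, states, root_state = states[1])
  if (is.null(trait_params)) {
    trait_params <- switch(trait_model,
      BM1 = list(sigma2 = 1, z0 = 0),
      BMS = list(sigma2 = seq_along(states), z0 = 0),
      OU1 = list(sigma2 = 1, alpha = 2 / tree_depth(tree), theta = 0),
      # strong-selection regimes: stationary SD sqrt(sigma2 / 2 alpha) = 1/4,
      # so adjacent optima sit many stationary SDs apart (well separated)
      OUM = list(sigma2 = 0.25 / tree_depth(tree),
                 alpha = 2 / tree_depth(tree),
                 theta = seq(0, 3, length.out = length(states))),
      OUMV = list(sigma2 = 0.25 * (1 + seq_along(states)) /
                    (2 * tree_depth(tree)),
                  alpha = 2 / tree_depth(tree),
                  theta = seq(0, 3, length.out = length(states))))
  }
  x <- sim_trait_on_painting(hist$painting, trait_model, trait_params)
  ntip <- ape::Ntip(tree)
  list(tree = tree, painting = hist$painting,
       node_states = hist$node_states,
       tip_traits = stats::setNames(x[seq_len(ntip), 1], tree$tip.label),
       node_traits = x[(ntip + 1):nrow(x), 1],
       params = trait_params, model = trait_model)
}
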