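#' Paint selective regimes onto a chronogram
#'
#' A regime painting assigns a categorical regime (here: pollination
#' syndrome) to every branch segment of a time-calibrated tree; it defines
#' which rate/optimum parameters apply where in the regime-dependent
#' evolutionary models.  In node-state mode each branch inherits the state
#' of its parent node as a single segment.
#'
#' @param tree ultrametric `phylo` tree.
#' @param node_states character vector of regime labels for all nodes (ape
#'   ids 1..Ntip+Nnode: tips first), or for internal nodes only (length
#'   Nnode), in which case tip branches still take the parent's state.
#' @param regimes optional explicit regime level set.
#' @param mode `"parent"` (default): each branch takes the state of its
#'   parent node; `"child"`: each branch takes the state of the node it
#'   subtends, so observed tip states paint their terminal branches.
#' @return object of class `regime_painting`: `tree`, `regimes` (levels),
#'   `edge_segments` (list over rows of `tree$edge`; each a data.frame with
#'   `regime` (integer level index), `t0`, `t1` heights from the root),
#'   `root_regime`, `node_states`.
#' @export
paint_regimes <- function(tree, node_states, regimes = NULL,
                          mode = c("parent", "child")) {
  mode <- match.arg(mode)
  ntip <- ape::Ntip(tree); nnode <- tree$Nnode
  if (length(node_states) == nnode)
    node_states <- c(rep(NA_character_, ntip), as.character(node_states))
  if (length(node_states) != ntip + nnode)
    stop("node_states must cover internal nodes or all nodes")
  if (is.null(regimes)) regimes <- sort(unique(stats::na.omit(node_states)))
  bad <- setdiff(stats::na.omit(node_states), regimes)
  if (length(bad)) stop("unknown regime label(s): ", paste(bad, collapse = ", "))
  h <- tree_node_heights(tree)
  segs <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    st <- node_states[if (mode == "parent") p else c]
    if (is.na(st)) stop("no state for node ", if (mode == "parent") p else c)
    segs[[e]] <- data.frame(regime = match(st, regimes),
                            t0 = h[p], t1 = h[c])
  }
  root <- ntip + 1L
  structure(list(tree = tree, regimes = regimes, edge_segments = segs,
                 root_regime = match(node_states[root], regimes),
                 node_states = node_states),
            class = "regime_painting")
}

# Painting built from explicit per-edge segment tables (e.g. a stochastic
# map draw).  segments: list parallel to tree$edge rows; each a data.frame
# with columns regime (label), length, ordered rootward to tipward.
painting_from_segments <- function(tree, segments, regimes, root_regime) {
  h <- tree_node_heights(tree)
  segs <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    sg <- segments[[e]]
    len <- sum(sg$length)
    el <- tree$edge.length[e]
    if (abs(len - el) > 1e-8 * max(el, 1))
      stop("segments do not tile edge ", e)
    t0 <- h[p] + c(0, cumsum(sg$length))[seq_len(nrow(sg))]
    segs[[e]] <- data.frame(regime = match(as.character(sg$regime), regimes),
                            t0 = t0, t1 = t0 + sg$length)
  }
  structure(list(tree = tree, regimes = regimes, edge_segments = segs,
                 root_regime = match(root_regime, regimes),
                 node_states = NULL),
            class = "regime_painting")
}

#' @export
print.regime_painting <- function(x, ...) {
  lens <- vapply(seq_along(x$edge_segments), function(e) {
    sg <- x$edge_segments[[e]]
    tapply(sg$t1 - sg$t0, factor(x$regimes[sg$regime], levels = x$regimes), sum)
  }, numeric(length(x$regimes)))
  tot <- rowSums(matrix(unlist(lens), nrow = length(x$regimes)), na.rm = TRUE)
  cat("regime_painting over", length(x$regimes), "regimes; branch time per regime:",
      paste(sprintf("%s=%.3g", x$regimes, tot), collapse = ", "), "\n")
  invisible(x)
}

# --- internal machinery -----------------------------------------------------

# Static traversal structure reused across likelihood evaluations.
painting_structure <- function(painting) {
  tree <- painting$tree
  ntip <- ape::Ntip(tree)
  h <- tree_node_heights(tree)
  Tdepth <- max(h[seq_len(ntip)])
  if (diff(range(h[seq_len(ntip)])) > 1e-6 * Tdepth)
    stop("tree must be ultrametric for regime models")
  mr <- ape::mrca(tree)                 # ntip x ntip node ids
  # preorder edge ordering (parents before children)
  pre <- order(h[tree$edge[, 1]])
  list(ntip = ntip, h = h, T = Tdepth, mrca = mr, preorder = pre,
       edge = tree$edge, segs = painting$edge_segments,
       K = length(painting$regimes), root_regime = painting$root_regime)
}

# V matrix and mean vector for a regime model.
# sigma2: per-regime vector (recycled); alpha: scalar (0 => BM);
# theta: per-regime vector (OU) or NULL; z0: root value (BM) or NULL.
regime_vcv_mean <- function(st, sigma2, alpha = 0, theta = NULL, z0 = NULL) {
  nn <- length(st$h)
  sigma2 <- rep_len(sigma2, st$K)
  P <- numeric(nn)                      # accumulated variance root -> node
  W <- if (!is.null(theta)) matrix(0, nn, st$K) else NULL
  for (e in st$preorder) {
    p <- st$edge[e, 1]; ch <- st$edge[e, 2]
    sg <- st$segs[[e]]
    if (alpha > 0) {
      contrib <- sum(sigma2[sg$regime] *
                       (exp(-2 * alpha * (st$T - sg$t1)) -
                        exp(-2 * alpha * (st$T - sg$t0))) / (2 * alpha))
    } else {
      contrib <- sum(sigma2[sg$regime] * (sg$t1 - sg$t0))
    }
    P[ch] <- P[p] + contrib
    if (!is.null(W)) {
      W[ch, ] <- W[p, ]
      wseg <- exp(-alpha * (st$T - sg$t1)) - exp(-alpha * (st$T - sg$t0))
      for (i in seq_len(nrow(sg)))
        W[ch, sg$regime[i]] <- W[ch, sg$regime[i]] + wseg[i]
    }
  }
  tips <- seq_len(st$ntip)
  V <- matrix(P[st$mrca], st$ntip, st$ntip)
  diag(V) <- P[tips]
  if (!is.null(theta)) {
    Wt <- W[tips, , drop = FALSE]
    Wt[, st$root_regime] <- Wt[, st$root_regime] + exp(-alpha * st$T)
    mu <- as.vector(Wt %*% rep_len(theta, st$K))
    list(V = V, mean = mu, design = Wt)
  } else {
    list(V = V, mean = rep(z0 %||% 0, st$ntip), design = NULL)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mvn_loglik <- function(y, mu, V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) stop("singular (non-PD) trait covariance matrix")
  r <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
}

# GLS estimate of linear mean coefficients given V (X: design matrix).
gls_mean <- function(y, X, V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) stop("singular (non-PD) trait covariance matrix")
  yt <- backsolve(ch, y, transpose = TRUE)
  Xt <- backsolve(ch, X, transpose = TRUE)
  fit <- qr.solve(Xt, yt)
  list(beta = as.vector(fit), rss = sum((yt - Xt %*% fit)^2),
       logdet = 2 * sum(log(diag(ch))), Xt = Xt)
}

order_trait <- function(trait, tree) {
  if (!is.null(names(trait))) {
    missing <- setdiff(tree$tip.label, names(trait))
    if (length(missing))
      stop("trait missing for tip(s): ", paste(missing, collapse = ", "))
    trait <- trait[tree$tip.label]
  } else if (length(trait) != ape::Ntip(tree))
    stop("trait must have one value per tip")
  as.numeric(trait)
}

#' Log-likelihood of a univariate regime-dependent trait model
#'
#' Multivariate-normal likelihood with mean vector and covariance built by
#' per-branch-segment integration: under Brownian motion
#' `V_ij = sum over shared root-to-MRCA segments of sigma2(seg) * length`;
#' under an Ornstein-Uhlenbeck process with single pull `alpha`,
#' `V_ij = sum over shared segments of
#'   sigma2(seg) (e^{-2 a (T - t1)} - e^{-2 a (T - t0)}) / (2 a)`
#' and the tip expectation is the path-weighted combination of regime optima
#' with the residual weight `e^{-a T}` on the root regime's optimum.
#'
#' @param model one of `"BM1"`, `"BMS"`, `"OU1"`, `"OUM"`, `"OUMV"`.
#' @param params list with elements as required by the model: `sigma2`
#'   (scalar, or per-regime for BMS/OUMV), `z0` (BM root value), `alpha`
#'   (OU), `theta` (scalar for OU1, per-regime for OUM/OUMV).
#' @param painting a [paint_regimes()] object.
#' @param trait named numeric vector of tip values.
#' @return log-likelihood (scalar).
#' @export
model_loglik <- function(model, params, painting, trait) {
  model <- match.arg(model, c("BM1", "BMS", "OU1", "OUM", "OUMV"))
  st <- painting_structure(painting)
  y <- order_trait(trait, painting$tree)
  K <- st$K
  is_ou <- model %in% c("OU1", "OUM", "OUMV")
  if (is_ou && (is.null(params$alpha) || params$alpha <= 0))
    stop("OU models need alpha > 0")
  sigma2 <- switch(model,
    BM1 = rep(params$sigma2[1], K),
    OU1 = rep(params$sigma2[1], K),
    OUM = rep(params$sigma2[1], K),
    BMS = rep_len(params$sigma2, K),
    OUMV = rep_len(params$sigma2, K))
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  if (is_ou) {
    theta <- if (model == "OU1") rep(params$theta[1], K)
             else rep_len(params$theta, K)
    vm <- regime_vcv_mean(st, sigma2, alpha = params$alpha, theta = theta)
  } else {
    vm <- regime_vcv_mean(st, sigma2, alpha = 0, z0 = params$z0)
  }
  mvn_loglik(y, vm$mean, vm$V)
}

#' Small-sample corrected AIC
#' @param logL log-likelihood.
#' @param k number of free parameters.
#' @param n number of observations.
#' @return AICc value.
#' @export
aicc <- function(logL, k, n) -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)

model_param_count <- function(model, K) {
  switch(model, BM1 = 2L, BMS = 1L + K, OU1 = 3L, OUM = 2L + K,
         OUMV = 1L + 2L * K)
}

#' Fit a univariate trait-evolution model by maximum likelihood
#'
#' Rates and the pull parameter are optimised on the log scale with
#' multi-start bounded quasi-Newton search; the phylogenetic mean (BM) and
#' regime optima (OU) are profiled out by generalized least squares at each
#' evaluation.  `alpha` is bounded in `[1e-8, 100] / depth`.  A numerical
#' Hessian of the negative log-likelihood over all natural parameters is
#' computed at the optimum; `hessian_ok` is FALSE when it has a
#' non-positive eigenvalue (the model is then too rich for the data and
#' should be excluded from weight tables).
#'
#' @param model `"BM1"`, `"BMS"`, `"OU1"`, `"OUM"` or `"OUMV"`.
#' @param painting a [paint_regimes()] object.
#' @param trait named numeric tip values.
#' @param starts number of random restarts (default 10).
#' @param seed RNG seed for the restarts.
#' @return object of class `model_fit`: `model`, `parameters` (named list),
#'   `logL`, `k`, `n`, `AICc`, `hessian_ok`, `hessian_eigen`,
#'   `convergence`.
#' @export
fit_model <- function(model, painting, trait, starts = 10, seed = 1) {
  model <- match.arg(model, c("BM1", "BMS", "OU1", "OUM", "OUMV"))
  st <- painting_structure(painting)
  y <- order_trait(trait, painting$tree)
  n <- st$ntip; K <- st$K
  k <- model_param_count(model, K)
  if (n <= k + 1) stop("too few tips (", n, ") for ", k, " parameters")
  depth <- st$T
  la_lo <- log(1e-8 / depth); la_hi <- log(100 / depth)
  set.seed(seed)

  gls_profile <- function(V, design = NULL) {
    X <- if (is.null(design)) matrix(1, n, 1) else design
    # a regime can carry zero weight on every root-to-tip path (e.g. one
    # appearing only at tips); its optimum is unidentifiable and is pinned
    # to the weight-averaged optimum, leaving the likelihood unchanged
    live <- colSums(abs(X)) > 1e-12
    g <- gls_mean(y, X[, live, drop = FALSE], V)
    beta <- numeric(ncol(X))
    beta[live] <- g$beta
    if (any(!live)) beta[!live] <- sum(colSums(X[, live, drop = FALSE]) * g$beta) / n
    s2 <- g$rss / n                          # profiled global scale (ML)
    logL <- -0.5 * (n * log(2 * pi) + g$logdet + n * log(s2) + n)
    list(logL = logL, beta = beta, scale = s2)
  }

  eval_model <- function(par) {
    # par: transformed free parameters, model specific; returns
    # list(logL, parameters)
    switch(model,
      BM1 = {
        vm <- regime_vcv_mean(st, rep(1, K), alpha = 0, z0 = 0)
        pr <- gls_profile(vm$V)
        list(logL = pr$logL,
             parameters = list(sigma2 = pr$scale, z0 = pr$beta))
      },
      BMS = {
        s <- exp(par)                        # relative rates per regime
        vm <- regime_vcv_mean(st, s, alpha = 0, z0 = 0)
        pr <- gls_profile(vm$V)
        list(logL = pr$logL,
             parameters = list(sigma2 = s * pr$scale, z0 = pr$beta))
      },
      OU1 = {
        a <- exp(par[1])
        vm <- regime_vcv_mean(st, rep(1, K), alpha = a, theta = rep(0, K))
        ones <- matrix(1, n, 1)              # OU1 weights sum to 1
        pr <- gls_profile(vm$V, ones)
        list(logL = pr$logL,
             parameters = list(sigma2 = pr$scale, alpha = a,
                               theta = pr$beta))
      },
      OUM = {
        a <- exp(par[1])
        vm <- regime_vcv_mean(st, rep(1, K), alpha = a, theta = rep(0, K))
        pr <- gls_profile(vm$V, vm$design)
        list(logL = pr$logL,
             parameters = list(sigma2 = pr$scale, alpha = a,
                               theta = pr$beta))
      },
      OUMV = {
        a <- exp(par[1]); s <- exp(par[-1])
        vm <- regime_vcv_mean(st, s, alpha = a, theta = rep(0, K))
        pr <- gls_profile(vm$V, vm$design)
        list(logL = pr$logL,
             parameters = list(sigma2 = s * pr$scale, alpha = a,
                               theta = pr$beta))
      })
  }
  nfree <- switch(model, BM1 = 0L, BMS = K, OU1 = 1L, OUM = 1L, OUMV = K + 1L)
  objective <- function(par) {
    v <- tryCatch(eval_model(par)$logL, error = function(e) -Inf)
    if (!is.finite(v)) 1e10 else -v
  }
  if (nfree == 0L) {
    best <- list(par = numeric(0), value = objective(numeric(0)),
                 convergence = 0L)
  } else {
    lower <- c(if (model %in% c("OU1", "OUM", "OUMV")) la_lo,
               rep(log(1e-10), if (model %in% c("BMS", "OUMV")) K else 0))
    upper <- c(if (model %in% c("OU1", "OUM", "OUMV")) la_hi,
               rep(log(1e10), if (model %in% c("BMS", "OUMV")) K else 0))
    base_start <- c(if (model %in% c("OU1", "OUM", "OUMV")) log(2 / depth),
                    rep(log(max(stats::var(y), 1e-8)),
                        if (model %in% c("BMS", "OUMV")) K else 0))
    best <- NULL
    for (s in seq_len(max(1L, starts))) {
      p0 <- if (s == 1) base_start
            else pmin(pmax(base_start + stats::rnorm(nfree, 0, 1.5), lower), upper)
      op <- tryCatch(
        stats::optim(p0, objective, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 500)),
        error = function(e) NULL)
      if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
    }
    if (is.null(best) || best$value >= 1e10)
      stop("optimization failed on all ", starts, " starts for ", model)
  }
  res <- eval_model(best$par)
  pars <- res$parameters
  # numerical Hessian of -logL over the natural parameters
  natural <- natural_par_vector(model, pars, K)
  negll_nat <- function(v) {
    p <- natural_par_list(model, v, K)
    ll <- tryCatch(model_loglik(model, p, painting, y_named(y, painting$tree)),
                   error = function(e) NA_real_)
    if (!is.finite(ll)) 1e10 else -ll
  }
  H <- tryCatch(stats::optimHess(natural, negll_nat), error = function(e) NULL)
  hev <- if (!is.null(H)) eigen(H, symmetric = TRUE, only.values = TRUE)$values
         else NA_real_
  hok <- !is.null(H) && all(is.finite(hev)) && all(hev > 0)
  structure(list(model = model, parameters = pars, logL = res$logL,
                 k = k, n = n, AICc = aicc(res$logL, k, n),
                 hessian_ok = hok, hessian_eigen = hev,
                 convergence = best$convergence %||% 0L,
                 regimes = painting$regimes, seed = seed,
                 trait = stats::setNames(y, painting$tree$tip.label)),
            class = "model_fit")
}

y_named <- function(y, tree) stats::setNames(y, tree$tip.label)

natural_par_vector <- function(model, pars, K) {
  switch(model,
    BM1 = c(pars$sigma2, pars$z0),
    BMS = c(pars$sigma2, pars$z0),
    OU1 = c(pars$sigma2, pars$alpha, pars$theta),
    OUM = c(pars$sigma2, pars$alpha, pars$theta),
    OUMV = c(pars$sigma2, pars$alpha, pars$theta))
}

natural_par_list <- function(model, v, K) {
  switch(model,
    BM1 = list(sigma2 = v[1], z0 = v[2]),
    BMS = list(sigma2 = v[seq_len(K)], z0 = v[K + 1]),
    OU1 = list(sigma2 = v[1], alpha = v[2], theta = v[3]),
    OUM = list(sigma2 = v[1], alpha = v[2], theta = v[2 + seq_len(K)]),
    OUMV = list(sigma2 = v[seq_len(K)], alpha = v[K + 1],
                theta = v[K + 1 + seq_len(K)]))
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit %s: logL = %.4f, k = %d, AICc = %.4f, hessian_ok = %s\n",
              x$model, x$logL, x$k, x$AICc, x$hessian_ok))
  invisible(x)
}

#' Rank fitted models by AICc
#'
#' Fits whose Hessian diagnostics failed (`hessian_ok = FALSE`) are
#' excluded before the Akaike weights are computed, mirroring the exclusion
#' of over-parameterized models whose information matrix is not positive
#' definite.
#'
#' @param fits list of `model_fit` objects on the same trait data.
#' @return data.frame with `model`, `logL`, `k`, `AICc`, `delta_AICc`,
#'   `AICc_weight` (NA for excluded fits), `hessian_ok`, `best` flag.
#' @export
model_table <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits to compare")
  traits <- lapply(fits, function(f) f$trait)
  for (i in seq_along(traits)[-1])
    if (!isTRUE(all.equal(traits[[1]], traits[[i]])))
      stop("fits were not computed on identical trait data")
  df <- data.frame(model = vapply(fits, `[[`, "", "model"),
                   logL = vapply(fits, `[[`, 0, "logL"),
                   k = vapply(fits, function(f) as.numeric(f$k), 0),
                   AICc = vapply(fits, `[[`, 0, "AICc"),
                   hessian_ok = vapply(fits, `[[`, TRUE, "hessian_ok"))
  ok <- df$hessian_ok
  df$delta_AICc <- NA_real_; df$AICc_weight <- NA_real_
  if (any(ok)) {
    d <- df$AICc[ok] - min(df$AICc[ok])
    w <- exp(-d / 2); w <- w / sum(w)
    df$delta_AICc[ok] <- d
    df$AICc_weight[ok] <- w
  }
  df$best <- ok & df$AICc == suppressWarnings(min(df$AICc[ok]))
  df[order(df$AICc), ]
}
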