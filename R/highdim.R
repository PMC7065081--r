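#' Phylogenetic trait covariance matrix under BM, OU or EB
#'
#' For nodes `i, j` with MRCA at height `t_m` and patristic distance `d`:
#' BM gives `C_ij = t_m`; OU (pull `alpha`) gives
#' `C_ij = e^{-alpha d} (1 - e^{-2 alpha t_m}) / (2 alpha)`; EB (rate decay
#' `r <= 0`) accumulates exponentially decaying rates,
#' `C_ij = (e^{r t_m} - 1) / r`.
#'
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @param parameter `alpha > 0` for OU, `r <= 0` for EB, ignored for BM.
#' @param tree ultrametric `phylo`.
#' @param nodes optional vector of ape node ids (default: tips); the matrix
#'   is computed among these nodes.
#' @param nodes2 optional second node set for a rectangular cross-covariance.
#' @return covariance matrix.
#' @export
phylo_covariance <- function(model, parameter = NULL, tree,
                             nodes = seq_len(ape::Ntip(tree)),
                             nodes2 = NULL) {
  model <- match.arg(model, c("BM", "OU", "EB"))
  if (model == "OU" && (is.null(parameter) || parameter <= 0))
    stop("OU requires alpha > 0")
  if (model == "EB" && (is.null(parameter) || parameter > 0))
    stop("EB requires r <= 0")
  h <- tree_node_heights(tree)
  mr <- ape::mrca(tree, full = TRUE)
  n2 <- nodes2 %||% nodes
  tm <- matrix(h[mr[nodes, n2, drop = FALSE]], length(nodes), length(n2))
  # mrca(full=TRUE) leaves the diagonal as the node itself; handle pairs
  # where one node is an ancestor of the other the same way: mrca height is
  # already correct in both cases.
  d <- outer(h[nodes], h[n2], "+") - 2 * tm
  switch(model,
    BM = tm,
    OU = {
      a <- parameter
      exp(-a * d) * (1 - exp(-2 * a * tm)) / (2 * a)
    },
    EB = {
      r <- parameter
      if (r == 0) tm else (exp(r * tm) - 1) / r
    })
}

#' Penalized-likelihood fit of a multivariate evolutionary model
#'
#' Fits BM, OU or EB to an n x p species-mean trait matrix (p may exceed n)
#' under a matrix-normal model with ridge-regularised trait covariance
#' `R(lambda) = (1 - lambda) S_phylo + lambda diag(S_phylo)`, where
#' `S_phylo` is the phylogenetically centred ML covariance.  `lambda` is
#' chosen to maximise the leave-one-species-out cross-validated predictive
#' log-likelihood on a grid; the model parameter (`alpha` or `r`) is
#' optimised in an outer loop.  Model comparison uses a generalized
#' information criterion `GIC = -2 logL + 2 edf` with
#' `edf = (1 - lambda) p (p + 1) / 2 + lambda p + p + n_model_params`
#' (shrinkage-weighted covariance df plus mean and model parameters);
#' lower is better.
#'
#' @param Y n x p matrix of species-mean traits; rownames must match tips.
#' @param tree ultrametric `phylo` with n tips.
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @param lambda_grid shrinkage grid in `[0, 1]` (default 0 plus 20
#'   log-spaced points up to 1).
#' @param fixed_parameter optional fixed `alpha`/`r` (skips the outer
#'   optimisation).
#' @param method `"REML"` (default) maximises the restricted likelihood,
#'   which removes the small-sample upward bias of the pull-parameter
#'   estimate caused by profiling the mean; `"ML"` uses the ordinary
#'   profile likelihood (comparable with the univariate GLS fits).
#' @return object of class `multivariate_fit`: `model`, `parameter`,
#'   `lambda`, `R` (p x p), `mu` (length p), `logL` (penalized, at the
#'   chosen lambda), `GIC`, `cv_score`, `tree`, `Y`.
#' @export
penalized_fit <- function(Y, tree, model = c("BM", "OU", "EB"),
                          lambda_grid = c(0, 10^seq(-6, 0, length.out = 20)),
                          fixed_parameter = NULL,
                          method = c("REML", "ML")) {
  model <- match.arg(model)
  method <- match.arg(method)
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(Y)
  if (n < 3 && length(lambda_grid) > 1)
    stop("cross-validation needs at least 3 species")
  if (!is.null(rownames(Y))) {
    missing <- setdiff(tree$tip.label, rownames(Y))
    if (length(missing)) stop("Y missing species: ", paste(missing, collapse = ", "))
    Y <- Y[tree$tip.label, , drop = FALSE]
  } else if (n != ape::Ntip(tree)) stop("Y rows must match tree tips")

  depth <- tree_depth(tree)

  ndf <- if (method == "REML") n - 1 else n

  fit_at <- function(par) {
    C <- tryCatch(phylo_covariance(model, par, tree), error = function(e) NULL)
    if (is.null(C)) return(NULL)
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Ci1 <- backsolve(ch, backsolve(ch, matrix(1, n, 1), transpose = TRUE))
    mu <- as.vector(crossprod(Y, Ci1) / sum(Ci1))
    Z <- Y - tcrossprod(rep(1, n), mu)
    Zt <- backsolve(ch, Z, transpose = TRUE)    # C^{-1/2} Z
    S <- crossprod(Zt) / ndf                    # phylogenetically centred cov
    logdetC <- 2 * sum(log(diag(ch)))
    list(C = C, ch = ch, mu = mu, Z = Z, Zt = Zt, S = S, logdetC = logdetC,
         log_xCx = log(sum(Ci1)))
  }

  pen_loglik <- function(f, lambda) {
    R <- (1 - lambda) * f$S + lambda * diag(diag(f$S), p)
    chR <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(chR)) return(list(logL = -Inf))
    Q <- backsolve(chR, t(f$Zt), transpose = TRUE)  # R^{-1/2} Z' C^{-1/2}'
    logL <- if (method == "REML") {
      -0.5 * ((n - 1) * p * log(2 * pi) + p * f$logdetC + p * f$log_xCx +
                (n - 1) * 2 * sum(log(diag(chR))) + sum(Q^2))
    } else {
      -0.5 * (n * p * log(2 * pi) + p * f$logdetC +
                n * 2 * sum(log(diag(chR))) + sum(Q^2))
    }
    list(logL = logL, R = R, chR = chR)
  }

  # leave-one-species-out predictive log-likelihood over the whole lambda
  # grid; fold-level quantities do not depend on lambda and are reused
  cv_scores <- function(par) {
    C <- tryCatch(phylo_covariance(model, par, tree), error = function(e) NULL)
    if (is.null(C)) return(rep(-Inf, length(lambda_grid)))
    tot <- rep(0, length(lambda_grid))
    for (i in seq_len(n)) {
      Ct <- C[-i, -i, drop = FALSE]
      ch <- tryCatch(chol(Ct), error = function(e) NULL)
      if (is.null(ch)) return(rep(-Inf, length(lambda_grid)))
      Ci1 <- backsolve(ch, backsolve(ch, matrix(1, n - 1, 1), transpose = TRUE))
      mu <- as.vector(crossprod(Y[-i, , drop = FALSE], Ci1) / sum(Ci1))
      Z <- Y[-i, , drop = FALSE] - tcrossprod(rep(1, n - 1), mu)
      Zt <- backsolve(ch, Z, transpose = TRUE)
      S <- crossprod(Zt) / (n - 1)
      # conditional distribution of the held-out species' row
      k <- backsolve(ch, backsolve(ch, C[-i, i], transpose = TRUE))
      cmean <- mu + as.vector(crossprod(Z, k))
      cvar <- C[i, i] - sum(C[-i, i] * k)
      if (cvar <= 0) return(rep(-Inf, length(lambda_grid)))
      resid <- Y[i, ] - cmean
      dS <- diag(diag(S), p)
      for (l in seq_along(lambda_grid)) {
        lambda <- lambda_grid[l]
        R <- (1 - lambda) * S + lambda * dS
        chR <- tryCatch(chol(R), error = function(e) NULL)
        if (is.null(chR)) { tot[l] <- -Inf; next }
        r <- backsolve(chR, resid, transpose = TRUE)
        tot[l] <- tot[l] - 0.5 * (p * log(2 * pi) + p * log(cvar) +
                                    2 * sum(log(diag(chR))) + sum(r^2) / cvar)
      }
    }
    tot
  }

  choose_lambda <- function(par) {
    if (length(lambda_grid) == 1)        # nothing to select
      return(list(lambda = lambda_grid, score = NA_real_))
    scores <- cv_scores(par)
    best <- which.max(scores)
    list(lambda = lambda_grid[best], score = scores[best])
  }

  # outer objective: penalized log-likelihood at the CV-selected lambda for
  # this candidate parameter value
  outer_obj <- function(par) {
    sel <- choose_lambda(par)
    if (length(lambda_grid) > 1 && !is.finite(sel$score)) return(1e10)
    f <- fit_at(par)
    if (is.null(f)) return(1e10)
    ll <- pen_loglik(f, sel$lambda)$logL
    if (!is.finite(ll)) 1e10 else -ll
  }
  parameter <- switch(model,
    BM = NULL,
    OU = fixed_parameter %||%
      exp(stats::optimize(function(la) outer_obj(exp(la)),
                          c(log(1e-4 / depth), log(50 / depth)))$minimum),
    EB = fixed_parameter %||%
      -exp(stats::optimize(function(lr) outer_obj(-exp(lr)),
                           c(log(1e-6 / depth), log(10 / depth)))$minimum))
  sel <- choose_lambda(parameter)
  f <- fit_at(parameter)
  pl <- pen_loglik(f, sel$lambda)
  # Takeuchi-style effective cost of the model parameter: nu = K / J with
  # K the empirical variance of per-species score contributions and J the
  # observed information, both at the optimum.  Under a correctly specified
  # trait covariance nu ~ 1; when the shrunk R misses real trait
  # correlations the likelihood-ratio fluctuations are inflated and the
  # parameter must cost more than one unit.
  nu <- 1
  if (model != "BM") {
    row_ll <- function(par) {
      ff <- fit_at(par)
      if (is.null(ff)) return(NULL)
      R <- (1 - sel$lambda) * ff$S + sel$lambda * diag(diag(ff$S), p)
      chR <- tryCatch(chol(R), error = function(e) NULL)
      if (is.null(chR)) return(NULL)
      Q <- backsolve(chR, t(ff$Zt), transpose = TRUE)   # p x n
      d <- diag(ff$ch)
      -p * log(d) - 0.5 * colSums(Q^2) - sum(log(diag(chR))) -
        p / 2 * log(2 * pi)
    }
    h <- max(abs(parameter), 1e-3 / depth) * 1e-3
    l0 <- row_ll(parameter)
    lp <- row_ll(parameter + h); lm <- row_ll(parameter - h)
    if (!is.null(l0) && !is.null(lp) && !is.null(lm)) {
      Ui <- (lp - lm) / (2 * h)
      J <- -sum(lp + lm - 2 * l0) / h^2
      K <- sum((Ui - mean(Ui))^2) * n / (n - 1)
      if (is.finite(J) && J > 0 && is.finite(K))
        nu <- min(max(K / J, 1), 10)
    }
  }
  n_model_par <- if (model == "BM") 0 else nu
  mean_par <- if (method == "REML") 0 else p
  edf <- (1 - sel$lambda) * p * (p + 1) / 2 + sel$lambda * p +
    mean_par + n_model_par
  structure(list(model = model, parameter = parameter, lambda = sel$lambda,
                 R = pl$R, mu = f$mu, logL = pl$logL,
                 GIC = -2 * pl$logL + 2 * edf, edf = edf,
                 cv_score = sel$score, method = method, tree = tree, Y = Y),
            class = "multivariate_fit")
}

#' @export
print.multivariate_fit <- function(x, ...) {
  cat(sprintf("multivariate_fit %s: penalized logL = %.3f, GIC = %.3f, lambda = %.3g%s\n",
              x$model, x$logL, x$GIC, x$lambda,
              if (!is.null(x$parameter))
                sprintf(", parameter = %.4g", x$parameter) else ""))
  invisible(x)
}

#' Ancestral reconstruction of high-dimensional traits (shapes)
#'
#' Per-trait GLS/BLUP reconstruction at every internal node under the
#' fitted model's covariance function:
#' `anc = mu + C_anc,tips C^{-1} (Y - 1 mu')`.  Applied to flattened
#' Procrustes coordinates the rows back-fold to L x 3 ancestral
#' configurations; the root reconstruction equals the phylogenetic mean.
#'
#' @param fit a `multivariate_fit`.
#' @param nodes internal node ids (default: all internal nodes).
#' @return object of class `ancestral_shapes`: `estimates` (nodes x p
#'   matrix, rownames are node ids), `configurations` (list of L x 3
#'   matrices when p is divisible by 3), `nodes`.
#' @export
ancestral_shapes <- function(fit, nodes = NULL) {
  tree <- fit$tree
  ntip <- ape::Ntip(tree)
  if (is.null(nodes)) nodes <- ntip + seq_len(tree$Nnode)
  if (any(nodes > ntip + tree$Nnode)) stop("node id not in tree")
  C <- phylo_covariance(fit$model, fit$parameter, tree)
  Ca <- phylo_covariance(fit$model, fit$parameter, tree,
                         nodes = nodes, nodes2 = seq_len(ntip))
  Z <- fit$Y - tcrossprod(rep(1, ntip), fit$mu)
  est <- tcrossprod(rep(1, length(nodes)), fit$mu) + Ca %*% solve(C, Z)
  rownames(est) <- nodes
  cfgs <- if (ncol(est) %% 3 == 0)
    lapply(seq_len(nrow(est)), function(i) unflatten_config(est[i, ]))
  else NULL
  if (!is.null(cfgs)) names(cfgs) <- nodes
  structure(list(estimates = est, configurations = cfgs, nodes = nodes),
            class = "ancestral_shapes")
}

#' Thin-plate-spline warp of 3D points
#'
#' Solves the 3D TPS interpolation with kernel `U(r) = r` mapping every
#' source landmark exactly onto its target, and applies the resulting
#' deformation (affine part plus warp) to arbitrary query points, e.g. the
#' vertices of a surface model being distorted to an ancestral shape.
#'
#' @param source_landmarks,target_landmarks L x 3 matrices (L >= 5).
#' @param points M x 3 matrix of points to map (default: the source
#'   landmarks themselves).
#' @return M x 3 matrix of warped points; attributes `bending_energy` and
#'   `warp_coefficients`.
#' @export
tps_warp <- function(source_landmarks, target_landmarks,
                     points = source_landmarks) {
  S <- as.matrix(source_landmarks); Tg <- as.matrix(target_landmarks)
  if (nrow(S) < 5) stop("need at least 5 landmarks")
  if (!all(dim(S) == dim(Tg))) stop("source and target dimensions differ")
  L <- nrow(S)
  K <- as.matrix(stats::dist(S, diag = TRUE, upper = TRUE))
  P <- cbind(1, S)
  # null-space method: better conditioned than the bordered system.
  # W = Z y with Z an orthonormal basis of the null space of t(P), so the
  # side conditions t(P) W = 0 hold exactly.
  qrP <- qr(P)
  if (qrP$rank < 4) stop("singular TPS system (degenerate source landmarks)")
  Q <- qr.Q(qrP, complete = TRUE)
  Z <- Q[, 5:L, drop = FALSE]
  B <- crossprod(Z, K %*% Z)
  y <- tryCatch(solve(B, crossprod(Z, Tg)), error = function(e)
    stop("singular TPS system (degenerate source landmarks)"))
  y <- y + solve(B, crossprod(Z, Tg) - B %*% y)
  W <- Z %*% y
  Aff <- qr.coef(qrP, Tg - K %*% W)
  pts <- as.matrix(points)
  # per-coordinate differences: no cancellation for points near landmarks
  U <- sqrt(outer(pts[, 1], S[, 1], "-")^2 +
              outer(pts[, 2], S[, 2], "-")^2 +
              outer(pts[, 3], S[, 3], "-")^2)
  out <- cbind(1, pts) %*% Aff + U %*% W
  attr(out, "bending_energy") <- sum(diag(crossprod(W, K %*% W)))
  attr(out, "warp_coefficients") <- W
  out
}

#' Species-mean shape matrix from an aligned dataset
#'
#' Rows are species means of the Procrustes shape coordinates (the species
#' morphospace positions); rownames are species names, ready for
#' [penalized_fit()].
#'
#' @param aligned an `aligned_set`.
#' @return n_species x 3L matrix.
#' @export
species_mean_shapes <- function(aligned) {
  sp <- sort(unique(aligned$species))
  out <- t(vapply(sp, function(s)
    colMeans(aligned$shape_coords[aligned$species == s, , drop = FALSE]),
    numeric(ncol(aligned$shape_coords))))
  rownames(out) <- sp
  out
}
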